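# Shared fixtures, built in code at test time.

# a small scene that keeps renders fast while preserving all structure
test_scene <- function(...) {
  args <- utils::modifyList(
    list(height = 48L, width = 48L,
         fruit_center = c(24.5, 24.5), fruit_radius = 18,
         damage_center = c(20.5, 29.5), damage_radius = 5,
         damage_roughness = 1),
    list(...)
  )
  do.call(scene_spec, args)
}

render_test_sample <- function(label, seed = 1L, scene = test_scene(), ...) {
  render_sample(scene, make_class_spectrum(label, seed = seed), seed = seed + 100L,
                ...)
}

calibrated_test_sample <- function(label, seed = 1L, scene = test_scene(), ...) {
  s <- render_test_sample(label, seed, scene, ...)
  list(sample = s,
       refl = suppressWarnings(calibrate_reflectance(s$raw, s$white, s$dark)))
}

# exhaustive Otsu oracle: evaluate the between-class variance definition at
# every threshold t in 0..254 and take the argmax (lowest t on ties)
otsu_oracle <- function(values) {
  v <- as.integer(round(as.vector(values)))
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# brute-force GLCM oracle: enumerate every pixel pair at the offset
glcm_oracle <- function(q, dr, dc, symmetric = TRUE) {
  levels <- attr(q, "levels")
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- q[r, c]; b <- q[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

quantized_fixture <- function(values, levels) {
  q <- values
  attr(q, "levels") <- levels
  q
}
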