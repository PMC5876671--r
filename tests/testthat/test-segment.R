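test_that("histogram equalization preserves order and flattens histograms", {
  const <- matrix(37L, 8, 8)
  expect_identical(equalize_hist(const), const)

  two <- matrix(c(10L, 20L), 10, 10)
  eq <- equalize_hist(two)
  expect_identical(length(unique(as.vector(eq))), 2L)
  expect_true(all(eq[two == 20] > eq[two == 10]))

  set.seed(2)
  img <- matrix(as.integer(pmin(pmax(rnorm(10000, 128, 20), 0), 255)), 100)
  eq2 <- equalize_hist(img)
  flat <- rep(length(img) / 64, 64)
  chisq <- function(x) {
    counts <- tabulate(findInterval(as.vector(x), seq(0, 256, length.out = 65),
                                    rightmost.closed = TRUE), 64)
    sum((counts - flat)^2 / flat)
  }
  expect_lt(chisq(eq2), chisq(img))
  # mapping monotone: sorted unique inputs map to sorted outputs
  u <- sort(unique(as.vector(img)))
  mapped <- eq2[match(u, img)]
  expect_true(all(diff(mapped) >= 0))
})

test_that("Otsu matches the exhaustive between-class-variance oracle", {
  set.seed(11)
  imgs <- c(
    lapply(1:6, function(i) matrix(sample(0:255, 400, TRUE), 20)),
    list(matrix(c(rep(0L, 200), rep(255L, 200)), 20),
         matrix(c(rep(50L, 360), rep(200L, 40)), 20),
         matrix(rep(c(3L, 4L), 200), 20))
  )
  for (img in imgs) {
    got <- otsu_threshold(img)
    expect_identical(got$threshold, otsu_oracle(img))
    expect_identical(got$mask, img > got$threshold)
  }
  half <- matrix(c(rep(0L, 200), rep(255L, 200)), 20)
  expect_equal(mean(otsu_threshold(half)$mask), 0.5)
  skew <- matrix(c(rep(50L, 360), rep(200L, 40)), 20)
  th <- otsu_threshold(skew)
  expect_true(th$threshold >= 50 && th$threshold < 200)
  expect_identical(sum(th$mask), 40L)
  expect_error(otsu_threshold(matrix(7L, 4, 4)), "constant")
})

test_that("Roberts stencils produce the hand-computed gradients", {
  expect_true(all(robert_edges(matrix(9L, 5, 5))$magnitude == 0))

  # vertical step 0 | 255: on the last dark column both diagonal stencils
  # straddle the step, Gx = -255 and Gy = +255, magnitude 255 * sqrt(2)
  step <- cbind(matrix(0L, 6, 3), matrix(255L, 6, 3))
  mag <- robert_edges(step)$magnitude
  expect_true(all(mag[1:5, 3] == 255 * sqrt(2)))
  expect_equal(max(mag), 255 * sqrt(2))
  expect_true(all(mag[, 1] == 0))

  # alternating 0/255 columns: every valid pixel has |Gx| = |Gy| = 255
  stripes <- matrix(rep(c(0L, 255L), each = 6), 6, 6)[, rep(1:2, 3)]
  mags <- robert_edges(stripes)$magnitude
  expect_equal(unique(as.vector(mags[1:5, 1:5])), 255 * sqrt(2))

  # a true diagonal checkerboard is invisible to the diagonal stencils
  board <- matrix(0L, 6, 6)
  board[(row(board) + col(board)) %% 2 == 0] <- 255L
  expect_true(all(robert_edges(board)$magnitude == 0))
  expect_error(robert_edges(matrix(1L, 1, 5)), "2x2")
})

test_that("fuzzy c-means separates well-spaced 1-D clusters crisply", {
  f <- fuzzy_cmeans(c(0, 0, 0, 100, 100, 100), c = 2)
  expect_equal(sort(f$centers[, 1]), c(0, 100), tolerance = 1e-3)
  expect_true(all(apply(f$membership, 1, max) >= 0.99))
  expect_true(all(abs(rowSums(f$membership) - 1) < 1e-12))
})

test_that("the FCM objective is non-increasing and runs are deterministic", {
  set.seed(9)
  vals <- c(rnorm(120, 10, 3), rnorm(80, 40, 4))
  f <- fuzzy_cmeans(vals, c = 2, m = 2)
  expect_true(all(diff(f$objective) <= 1e-9))
  f2 <- fuzzy_cmeans(vals, c = 2, m = 2)
  expect_identical(f$membership, f2$membership)
  expect_error(fuzzy_cmeans(vals, c = 2, m = 1), "fuzzifier")
})

test_that("coincident points get crisp membership and degenerate input stays sane", {
  f <- fuzzy_cmeans(c(0, 0, 0, 50), c = 2)
  at_zero <- which.min(f$centers[, 1])
  expect_equal(f$membership[1, at_zero], 1)
  # all-identical points: centers coincide on the single value
  f0 <- fuzzy_cmeans(rep(5, 6), c = 2)
  expect_equal(as.vector(f0$centers), c(5, 5), tolerance = 1e-6)
})

test_that("near-crisp FCM agrees with k-means on separated data", {
  set.seed(21)
  vals <- c(rnorm(100, 0, 1), rnorm(100, 30, 1))
  f <- fuzzy_cmeans(vals, c = 2, m = 1.05)
  km <- kmeans(vals, centers = sort(f$centers[, 1]))
  ours <- order(f$centers[, 1])[f$cluster] # relabel by center order
  theirs <- order(km$centers)[km$cluster]
  expect_identical(as.integer(ours), as.integer(theirs))
})

test_that("FCM agrees with the independent e1071 implementation", {
  skip_if_not_installed("e1071")
  set.seed(33)
  vals <- c(rnorm(150, 5, 2), rnorm(100, 25, 2))
  f <- fuzzy_cmeans(vals, c = 2, m = 2, tol = 1e-9, max_iter = 500)
  ref <- e1071::cmeans(matrix(vals), centers = matrix(sort(f$centers[, 1])),
                       m = 2, iter.max = 500)
  expect_equal(sort(f$centers[, 1]), sort(as.vector(ref$centers)),
               tolerance = 1e-3)
})

test_that("segmentation recovers bruises and stays quiet on fresh fruit", {
  cs1 <- calibrated_test_sample(3, seed = 15)
  g1 <- rescale_gray(band_plane(cs1$refl, 725))
  seg1 <- segment_damage(g1)
  expect_gte(mask_iou(seg1$damage_mask, cs1$sample$damage_mask), 0.5)
  expect_gte(mask_iou(seg1$fruit_mask, cs1$sample$fruit_mask), 0.9)

  cs0 <- calibrated_test_sample(0, seed = 16)
  seg0 <- segment_damage(rescale_gray(band_plane(cs0$refl, 725)))
  expect_lt(seg0$damage_fraction, 0.02)

  expect_error(segment_damage(matrix(0L, 20, 20)), "no fruit")
})

test_that("segmentation is robust to global affine intensity changes", {
  cs <- calibrated_test_sample(2, seed = 18)
  g <- rescale_gray(band_plane(cs$refl, 725))
  ga <- matrix(as.integer(round(0.8 * g + 20)), nrow(g))
  s1 <- segment_damage(g)
  s2 <- segment_damage(ga)
  expect_gte(mask_iou(s1$fruit_mask, s2$fruit_mask), 0.98)
  expect_gte(mask_iou(s1$damage_mask, s2$damage_mask), 0.85)
})

test_that("connected-component labels match a flood-fill oracle", {
  # independent BFS flood fill with 8-connectivity
  flood_label <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    nxt <- 0L
    for (start in which(mask)) {
      if (lab[start] > 0L) next
      nxt <- nxt + 1L
      queue <- start
      lab[start] <- nxt
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        r <- (cur - 1L) %% nr + 1L; c <- (cur - 1L) %/% nr + 1L
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- r + dr; c2 <- c + dc
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          if (mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- nxt
            queue <- c(queue, (c2 - 1L) * nr + r2)
          }
        }
      }
    }
    lab
  }
  set.seed(7)
  for (i in 1:5) {
    mask <- matrix(runif(400) < 0.4, 20)
    ours <- litchigrade:::label_components(mask)
    ref <- flood_label(mask)
    expect_identical(ours > 0, mask)
    expect_identical(max(ours), max(ref))
    # identical partitions: every pair of pixels co-labelled in one must be
    # co-labelled in the other
    fg <- which(mask)
    expect_identical(outer(ours[fg], ours[fg], "=="),
                     outer(ref[fg], ref[fg], "=="))
  }
})
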