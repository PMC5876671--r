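#' Histogram equalization of an 8-bit gray image
#'
#' Standard cumulative-histogram remapping to the full 0-255 range using
#' the classic `(cdf - cdf_min) / (1 - cdf_min)` normalization, which
#' leaves a constant image unchanged. The mapping is monotone
#' non-decreasing, so intensity order is preserved.
#'
#' @param image integer matrix with values in 0..255.
#' @return equalized integer matrix.
#' @export
equalize_hist <- function(image) {
  check_gray(image)
  counts <- tabulate(as.vector(image) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / sum(counts)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (cdf_min >= 1) return(image) # single gray level
  map <- as.integer(round(255 * (cdf - cdf_min) / (1 - cdf_min)))
  matrix(map[image + 1L], nrow(image), ncol(image))
}

check_gray <- function(image) {
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  if (any(image < 0 | image > 255)) {
    stop("gray image values must lie in 0..255", call. = FALSE)
  }
  invisible(TRUE)
}

#' Otsu threshold
#'
#' The threshold maximizing between-class variance over the 256-bin
#' histogram; ties are resolved to the lowest threshold. The foreground
#' mask is `value > threshold`.
#'
#' @param image integer matrix in 0..255, or a bare vector of masked
#'   values.
#' @return list with `threshold` (integer in 0..254) and, for matrix
#'   input, `mask` (logical foreground matrix).
#' @export
otsu_threshold <- function(image) {
  v <- as.vector(image)
  if (any(v < 0 | v > 255)) stop("values must lie in 0..255", call. = FALSE)
  v <- as.integer(round(v))
  if (length(unique(v)) < 2L) {
    stop("Otsu threshold undefined for a constant image", call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)                  # class probability for t = 0..255
  mu_t <- cumsum(p * levels)
  mu <- mu_t[256]
  # between-class variance for thresholds t = 0..254 (foreground > t)
  w0t <- w0[1:255]
  mu0t <- mu_t[1:255]
  sigma_b <- (mu * w0t - mu0t)^2 / (w0t * (1 - w0t))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_best <- which.max(sigma_b) - 1L # ties: which.max takes the first (lowest)
  out <- list(threshold = t_best)
  if (is.matrix(image)) out$mask <- image > t_best
  out
}

#' Roberts-operator edge detection
#'
#' Diagonal-difference gradients `Gx = I(r, c) - I(r+1, c+1)` and
#' `Gy = I(r, c+1) - I(r+1, c)` with magnitude `sqrt(Gx^2 + Gy^2)`,
#' evaluated on the (rows-1) x (cols-1) valid grid and zero-padded on the
#' last row/column. The binary edge map thresholds the min-max rescaled
#' magnitude with Otsu (all-FALSE when the magnitude is constant).
#'
#' @param image integer matrix in 0..255, at least 2 x 2.
#' @return list with `magnitude` (numeric matrix, same size as input) and
#'   `mask` (logical edge matrix).
#' @export
robert_edges <- function(image) {
  check_gray(image)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 2L || nc < 2L) stop("image must be at least 2x2", call. = FALSE)
  a <- image[-nr, -nc]; d <- image[-1, -1]
  b <- image[-nr, -1]; c_ <- image[-1, -nc]
  gx <- a - d
  gy <- b - c_
  mag <- matrix(0, nr, nc)
  mag[-nr, -nc] <- sqrt(gx^2 + gy^2)
  gray <- rescale_gray(mag)
  mask <- if (length(unique(as.vector(gray))) < 2L) {
    matrix(FALSE, nr, nc)
  } else {
    otsu_threshold(gray)$mask
  }
  list(magnitude = mag, mask = mask)
}

#' Fuzzy c-means clustering
#'
#' Alternating-update fuzzy c-means with fuzzifier `m`: memberships
#' `u_ik` proportional to `d_ik^(-2/(m-1))` and centers the
#' `u^m`-weighted means, iterated until the objective
#' `J = sum u^m d^2` changes by less than `tol`. Initial centers are the
#' evenly spaced marginal quantiles of the data (the 25th/75th percentiles
#' for c = 2), making the run deterministic; `seed` only matters for the
#' random fallback when quantile centers coincide. A point lying exactly on
#' a center receives crisp membership there.
#'
#' @param values numeric vector (1-D features) or pixels x d matrix.
#' @param c number of clusters (default 2).
#' @param m fuzzifier, > 1 (default 2).
#' @param tol objective-change stopping tolerance.
#' @param max_iter iteration cap.
#' @param seed integer seed for the fallback initialization.
#' @return an `fcm_state`: `centers` (c x d), `membership` (n x c,
#'   row-stochastic), `objective` (per-iteration trace), `iterations`,
#'   `cluster` (hard assignment).
#' @export
fuzzy_cmeans <- function(values, c = 2L, m = 2, tol = 1e-5, max_iter = 300L,
                         seed = 1L) {
  x <- if (is.null(dim(values))) matrix(as.numeric(values), ncol = 1) else as.matrix(values)
  n <- nrow(x)
  if (m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  if (n < c) stop("need at least c points", call. = FALSE)
  centers <- apply(x, 2, function(col) {
    stats::quantile(col, probs = (seq_len(c) - 0.5) / c, names = FALSE)
  })
  centers <- matrix(centers, nrow = c)
  if (anyDuplicated(centers)) {
    rng <- local_rng(seed)
    centers <- x[rng$sample_int(n, c), , drop = FALSE] +
      matrix(rng$rnorm(c * ncol(x), 0, 1e-8), c)
  }
  expo <- -2 / (m - 1)
  objective <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(seq_len(n), seq_len(c), function(i, k) {
      rowSums((x[i, , drop = FALSE] - centers[k, , drop = FALSE])^2)
    })
    zero_row <- rowSums(d2 < .Machine$double.eps) > 0
    pw <- d2^(expo / 2)
    u <- matrix(0, n, c)
    if (any(!zero_row)) {
      u[!zero_row, ] <- pw[!zero_row, , drop = FALSE] /
        rowSums(pw[!zero_row, , drop = FALSE])
    }
    if (any(zero_row)) { # crisp membership for points coincident with a center
      zr <- which(zero_row)
      u[cbind(zr, max.col(-d2[zr, , drop = FALSE]))] <- 1
    }
    um <- u^m
    objective <- c(objective, sum(um * d2))
    denom <- colSums(um)
    centers_new <- centers
    live <- denom > .Machine$double.eps
    centers_new[live, ] <- crossprod(um[, live, drop = FALSE], x) / denom[live]
    centers <- centers_new
    if (it > 1 && abs(objective[it] - objective[it - 1]) < tol) break
  }
  structure(list(
    centers = centers, membership = u, objective = objective,
    iterations = length(objective),
    cluster = max.col(u)
  ), class = "fcm_state")
}

# 8-connected component labelling, two-pass union-find
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc]) next
      nb <- integer(0)
      if (rr > 1 && labels[rr - 1, cc] > 0) nb <- c(nb, labels[rr - 1, cc])
      if (cc > 1) {
        if (labels[rr, cc - 1] > 0) nb <- c(nb, labels[rr, cc - 1])
        if (rr > 1 && labels[rr - 1, cc - 1] > 0) nb <- c(nb, labels[rr - 1, cc - 1])
        if (rr < nr && labels[rr + 1, cc - 1] > 0) nb <- c(nb, labels[rr + 1, cc - 1])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[rr, cc] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r0 <- min(roots)
        labels[rr, cc] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nxt == 0L) return(labels)
  # flatten
  roots <- vapply(seq_len(nxt), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  pos <- which(labels > 0)
  labels[pos] <- relabel[labels[pos]]
  labels
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# fill holes: inverse components not touching the border are holes
fill_holes <- function(mask) {
  inv <- !mask
  lab <- label_components(inv)
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_ids <- border_ids[border_ids > 0]
  hole <- inv & !matrix(lab %in% border_ids, nrow(lab), ncol(lab))
  mask | hole
}

#' Segment fruit and damage in a gray image
#'
#' The image-side localization chain: histogram equalization, Otsu
#' thresholding for fruit-versus-background, largest 8-connected component
#' with hole filling as the fruit disc, Roberts edges for the boundary, and
#' fuzzy c-means (c = 2) on the fruit-interior intensities of the original
#' image, with the lower-mean cluster as the bruise candidate. Before
#' clustering, the interior intensities are locally averaged and
#' flat-fielded (a quadratic illumination surface is removed) so pericarp
#' texture noise and curvature shading do not drown a shallow bruise.
#' Because 2-cluster fuzzy partitions always split, damage is only reported when
#' the dark cluster sits at least `min_contrast_frac` of the
#' fruit-to-background contrast below the bright cluster; the reported
#' damage mask is then the largest connected dark component. Fresh fruit
#' therefore yields an (almost) empty damage mask.
#'
#' @param image integer gray matrix in 0..255 (a single-band or PC-score
#'   image).
#' @param seed seed forwarded to the clustering fallback.
#' @param min_contrast_frac damage-contrast guard as a fraction of the
#'   fruit-background contrast (default 0.05). After flat-fielding, an
#'   undamaged pericarp leaves only residual texture noise (cluster
#'   separation of a few gray levels), while any real bruise separates by
#'   its full depth; 5% of the fruit-background contrast sits between the
#'   two regimes.
#' @param fuzzifier fuzzy c-means exponent used here (default 1.5). The
#'   generic default of 2 is too soft for a small bruise: with only a few
#'   percent of pixels in the dark mode, membership smearing pulls the two
#'   centers together and the bruise is absorbed; 1.5 retains soft
#'   memberships while letting a minority mode hold its own center.
#' @param smooth_radius half-width in pixels of the box average applied to
#'   the fruit-interior intensities before clustering (default 2, i.e. a
#'   5 x 5 window); suppresses pericarp texture noise so a small bruise
#'   mode stays separable. The fruit rim is eroded by the same radius so
#'   the average never mixes in background pixels. 0 disables smoothing.
#' @return a `segmentation` list: `fruit_mask`, `damage_mask`, `edges`,
#'   `threshold`, `fcm` (the `fcm_state` or NULL), `fruit_area`,
#'   `damage_area`, `damage_fraction`.
#' @export
segment_damage <- function(image, seed = 1L, min_contrast_frac = 0.05,
                           smooth_radius = 2L, fuzzifier = 1.5) {
  check_gray(image)
  eq <- equalize_hist(image)
  if (length(unique(as.vector(eq))) < 2L) {
    stop("no fruit found: image is constant", call. = FALSE)
  }
  ot <- otsu_threshold(eq)
  if (!any(ot$mask)) stop("no fruit found: empty Otsu foreground", call. = FALSE)
  fruit <- fill_holes(largest_component(ot$mask))
  edges <- robert_edges(eq)
  interior <- fruit & !edges$mask
  if (smooth_radius > 0) {
    # erode by the smoothing radius so averages stay fruit-only
    eroded <- box_smooth(matrix(as.numeric(fruit), nrow(fruit)),
                         smooth_radius) >= 1 - 1e-9
    interior <- interior & eroded
    sm <- box_smooth(matrix(as.numeric(image), nrow(image)), smooth_radius)
  } else {
    sm <- image
  }
  # flat-field the fruit interior: remove the smooth curvature/illumination
  # surface (quadratic in row, col) so clustering sees bruise-vs-pericarp
  # contrast rather than shading
  pos <- which(interior, arr.ind = TRUE)
  vals <- sm[interior]
  if (nrow(pos) > 12L) {
    Xs <- cbind(1, pos[, 1], pos[, 2], pos[, 1]^2, pos[, 1] * pos[, 2],
                pos[, 2]^2)
    vals <- stats::lm.fit(Xs, vals)$residuals
  }
  bg_mean <- mean(image[!fruit])
  fruit_mean <- mean(image[fruit])
  contrast <- abs(fruit_mean - bg_mean)
  damage <- matrix(FALSE, nrow(image), ncol(image))
  fcm <- NULL
  if (length(unique(vals)) >= 2L) {
    fcm <- fuzzy_cmeans(vals, c = 2L, m = fuzzifier, seed = seed)
    lo <- which.min(fcm$centers[, 1])
    sep <- abs(diff(fcm$centers[, 1]))
    dark_frac <- mean(fcm$cluster == lo)
    if (sep >= min_contrast_frac * contrast && dark_frac <= 0.5) {
      dm <- matrix(FALSE, nrow(image), ncol(image))
      dm[interior] <- fcm$cluster == lo
      damage <- largest_component(dm)
    }
  }
  structure(list(
    fruit_mask = fruit, damage_mask = damage, edges = edges$mask,
    threshold = ot$threshold, fcm = fcm,
    fruit_area = sum(fruit), damage_area = sum(damage),
    damage_fraction = sum(damage) / max(sum(fruit), 1)
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> fruit %d px, damage %d px (%.2f%% of fruit)\n",
              x$fruit_area, x$damage_area, 100 * x$damage_fraction))
  invisible(x)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG masks", call. = FALSE)
  }
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Intersection-over-union of two masks
#' @param a,b logical matrices of equal size.
#' @return IoU in `[0, 1]`; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Plot a segmentation over its source image
#' @param object a `segmentation`.
#' @param image the gray image it was computed from.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.segmentation <- function(object, image, ...) {
  df <- expand.grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  df$gray <- as.vector(image)
  df$overlay <- ifelse(as.vector(object$damage_mask), "damage",
                       ifelse(as.vector(object$fruit_mask), "fruit", "background"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::geom_point(data = df[df$overlay == "damage", ],
                        colour = "red", size = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "gray")
}
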