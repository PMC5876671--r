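#' Pool masked pixels from cubes into a pixel matrix
#'
#' Stacks the spectra of in-mask pixels from one or more reflectance cubes
#' into a (pixels x bands) matrix, optionally subsampling uniformly at
#' random (seeded) to cap the row count.
#'
#' @param cubes list of [hsi_cube()] objects on a shared axis.
#' @param masks list of logical matrices matching each cube's image size.
#' @param max_pixels cap on pooled rows (default 50000).
#' @param seed subsampling seed.
#' @return numeric matrix with attribute `wavelength`.
#' @export
assemble_pixels <- function(cubes, masks, max_pixels = 50000L, seed = 1L) {
  if (inherits(cubes, "hsi_cube")) cubes <- list(cubes)
  if (is.matrix(masks)) masks <- list(masks)
  stopifnot(length(cubes) == length(masks))
  wl <- wavelengths(cubes[[1]])
  rows <- lapply(seq_along(cubes), function(i) {
    cube <- cubes[[i]]; mask <- masks[[i]]
    if (!all(dim(mask) == dim(cube)[1:2])) {
      stop("mask ", i, " does not match its cube's image size", call. = FALSE)
    }
    m <- cube_to_matrix(cube)
    m[as.vector(mask), , drop = FALSE]
  })
  x <- do.call(rbind, rows)
  if (nrow(x) == 0L) stop("mask union is empty", call. = FALSE)
  if (nrow(x) > max_pixels) {
    rng <- local_rng(seed)
    keep <- sort(rng$sample_int(nrow(x), max_pixels))
    x <- x[keep, , drop = FALSE]
  }
  attr(x, "wavelength") <- wl
  x
}

#' Principal component analysis of pooled pixel spectra
#'
#' Eigen-decomposition of the band covariance matrix of the mean-centered
#' pixel matrix. Loadings (weight-coefficient vectors) are unit-norm with
#' the sign fixed so each column's largest-magnitude entry is positive;
#' the contribution rate of component k is `100 * lambda_k / sum(lambda)`
#' over all bands.
#'
#' @param pixels pixels x bands matrix (e.g. from [assemble_pixels()]).
#' @param n_pc number of components to retain (default 7).
#' @return an `image_pca` object: `means`, `loadings` (bands x n_pc),
#'   `eigenvalues` (all bands), `contribution`, `cumulative` (percent,
#'   first n_pc), `wavelength` (if known).
#' @export
image_pca <- function(pixels, n_pc = 7L) {
  x <- as.matrix(pixels)
  n_pc <- as.integer(n_pc)
  if (nrow(x) < n_pc || ncol(x) < n_pc) {
    stop("need at least n_pc pixels and bands", call. = FALSE)
  }
  means <- colMeans(x)
  xc <- sweep(x, 2, means)
  cv <- crossprod(xc) / (nrow(x) - 1)
  if (max(abs(cv)) < 1e-14) stop("pixel matrix has zero variance", call. = FALSE)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  contribution <- 100 * ev / sum(ev)
  structure(list(
    means = means,
    loadings = load,
    eigenvalues = ev,
    contribution = contribution[seq_len(n_pc)],
    cumulative = cumsum(contribution)[seq_len(n_pc)],
    n_pc = n_pc,
    wavelength = attr(pixels, "wavelength")
  ), class = "image_pca")
}

#' @export
print.image_pca <- function(x, ...) {
  cat(sprintf("<image_pca> %d components; cumulative contribution %.2f%%\n",
              x$n_pc, x$cumulative[x$n_pc]))
  invisible(x)
}

#' Tidy PCA loadings
#' @param x an `image_pca`.
#' @param ... unused.
#' @return long tibble with `band`, `wavelength` (if known), `pc`,
#'   `loading`.
#' @export
tidy.image_pca <- function(x, ...) {
  df <- tibble::as_tibble(x$loadings, .name_repair = ~ sprintf("PC%d", seq_along(.x)))
  df$band <- seq_len(nrow(df))
  if (!is.null(x$wavelength)) df$wavelength <- x$wavelength
  tidyr::pivot_longer(df, dplyr::starts_with("PC"), names_to = "pc",
                      values_to = "loading")
}

#' @export
glance.image_pca <- function(x, ...) {
  tibble::tibble(n_pc = x$n_pc,
                 pc1_contribution = x$contribution[1],
                 cumulative = x$cumulative[x$n_pc])
}

#' Contribution-rate table
#' @param pca an `image_pca`.
#' @return tibble with `pc`, `eigenvalue`, `contribution`, `cumulative`.
#' @export
contribution_table <- function(pca) {
  tibble::tibble(
    pc = seq_len(pca$n_pc),
    eigenvalue = pca$eigenvalues[seq_len(pca$n_pc)],
    contribution = pca$contribution,
    cumulative = pca$cumulative
  )
}

#' Scree / loading plot for an image PCA
#' @param object an `image_pca`.
#' @param ... unused.
#' @return a ggplot object (loading curves per component).
#' @export
autoplot.image_pca <- function(object, ...) {
  df <- tidy(object)
  xvar <- if ("wavelength" %in% names(df)) "wavelength" else "band"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$loading,
                                   colour = .data$pc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "wavelength") "wavelength (nm)" else "band",
                  y = "weight coefficient", colour = NULL)
}

#' Principal-component score image
#'
#' Projects every pixel spectrum of a cube onto one loading vector and
#' rescales the projection min-max to 8-bit gray levels. A constant
#' projection maps to an all-zero image.
#'
#' @param cube an [hsi_cube()].
#' @param pca an `image_pca` fitted on the same axis.
#' @param pc_index 1-based component index.
#' @return integer matrix (rows x cols) of gray levels in 0..255.
#' @export
score_image <- function(cube, pca, pc_index = 3L) {
  if (pc_index < 1L || pc_index > pca$n_pc) {
    stop("pc_index must be in 1..", pca$n_pc, call. = FALSE)
  }
  m <- cube_to_matrix(cube)
  sc <- drop(sweep(m, 2, pca$means) %*% pca$loadings[, pc_index])
  rescale_gray(matrix(sc, dim(cube)[1], dim(cube)[2]))
}

#' Min-max rescale a matrix to 8-bit gray levels
#'
#' Linear rescaling to integers 0..255; a constant input maps to an
#' all-zero image.
#'
#' @param m numeric matrix.
#' @return integer matrix in 0..255.
#' @export
rescale_gray <- function(m) {
  rng <- range(m)
  if (diff(rng) < .Machine$double.eps) {
    return(matrix(0L, nrow(m), ncol(m)))
  }
  matrix(as.integer(round(255 * (m - rng[1]) / diff(rng))), nrow(m), ncol(m))
}

#' Characteristic wavebands from loading-curve extrema
#'
#' Smooths one component's loading curve with a short Savitzky-Golay
#' filter, locates interior local maxima and minima from sign changes of
#' the first difference, and keeps those whose topographic prominence is at
#' least `min_prominence_frac` of the loading range. The returned
#' wavelengths are the grid band centers, sorted ascending.
#'
#' @param pca an `image_pca` (or a bare numeric loading vector).
#' @param pc_index 1-based component to analyse (default 3).
#' @param wavelength axis; taken from `pca` when available.
#' @param smooth_window odd Savitzky-Golay window (default 7; 0 disables).
#' @param min_prominence_frac prominence floor as a fraction of the
#'   smoothed loading's range (default 0.05).
#' @return a tibble with `wavelength`, `band`, `type` (`"max"`/`"min"`),
#'   `prominence`; zero rows when the curve is monotone.
#' @export
pc_loading_extrema <- function(pca, pc_index = 3L, wavelength = NULL,
                               smooth_window = 7L, min_prominence_frac = 0.05) {
  if (inherits(pca, "image_pca")) {
    v <- pca$loadings[, pc_index]
    if (is.null(wavelength)) wavelength <- pca$wavelength
  } else {
    v <- as.numeric(pca)
  }
  if (is.null(wavelength)) wavelength <- seq_along(v)
  if (length(v) < 3L) stop("loading curve too short", call. = FALSE)
  if (smooth_window > 0 && smooth_window <= length(v)) {
    v <- sg_smooth(v, window = smooth_window, polyorder = 2L)
  }
  floor_p <- min_prominence_frac * diff(range(v))
  ex_max <- local_extrema(v, floor_p)
  ex_min <- local_extrema(-v, floor_p)
  out <- rbind(
    if (nrow(ex_max)) cbind(ex_max, type = "max"),
    if (nrow(ex_min)) cbind(ex_min, type = "min")
  )
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(wavelength = numeric(0), band = integer(0),
                          type = character(0), prominence = numeric(0)))
  }
  out <- tibble::tibble(
    wavelength = wavelength[out$index],
    band = as.integer(out$index),
    type = out$type,
    prominence = out$prominence
  )
  dplyr::arrange(out, .data$wavelength)
}

# interior local maxima of v with topographic prominence >= floor_p
local_extrema <- function(v, floor_p) {
  n <- length(v)
  d <- diff(v)
  s <- sign(d)
  # collapse zero slopes onto the previous sign so plateaus count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(s[-length(s)] > 0 & s[-1] < 0) + 1L
  if (!length(idx)) return(data.frame(index = integer(0), prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    # walk outwards to the nearest strictly higher point on each side;
    # the key saddle is the higher of the two interval minima
    left <- v[seq_len(i - 1)]
    right <- if (i < n) v[(i + 1):n] else numeric(0)
    higher_l <- which(left > v[i])
    higher_r <- which(right > v[i])
    min_l <- if (length(higher_l)) min(v[(max(higher_l)):(i)]) else min(c(left, v[i]))
    min_r <- if (length(higher_r)) min(v[i:(i + min(higher_r))]) else min(c(right, v[i]))
    v[i] - max(min_l, min_r)
  }, numeric(1))
  keep <- prom >= floor_p
  data.frame(index = idx[keep], prominence = prom[keep])
}
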