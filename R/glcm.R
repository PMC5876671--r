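#' Quantize a gray image into co-occurrence levels
#'
#' Linear binning of the 0-255 range into `levels` bins; level indices are
#' 0-based. Out-of-mask pixels are set to `NA` and never enter pair
#' counting.
#'
#' @param image integer matrix in 0..255.
#' @param mask logical matrix (default: all pixels).
#' @param levels number of gray levels, 2..256 (default 64; 256 is the
#'   identity binning).
#' @return integer matrix of levels with `NA` outside the mask and a
#'   `levels` attribute.
#' @export
quantize_gray <- function(image, mask = NULL, levels = 64L) {
  check_gray(image)
  levels <- as.integer(levels)
  if (levels < 2L || levels > 256L) stop("levels must be in 2..256", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  q <- pmin(as.integer(floor(as.numeric(image) * levels / 256)), levels - 1L)
  q <- matrix(q, nrow(image), ncol(image))
  q[!mask] <- NA_integer_
  attr(q, "levels") <- levels
  q
}

glcm_offsets <- function(distance, angles) {
  lapply(angles, function(a) {
    switch(as.character(a),
           "0" = c(0L, distance),
           "45" = c(-distance, distance),
           "90" = c(-distance, 0L),
           "135" = c(-distance, -distance),
           stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
  })
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at the given pixel offset(s), summing
#' counts over the four standard angles, optionally symmetrizing by adding
#' the transpose, and normalizing to sum 1. Pairs with either pixel
#' outside the mask (`NA` level) are skipped.
#'
#' @param qimage quantized image from [quantize_gray()].
#' @param distance offset length in pixels (default 1).
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @param symmetric add the transpose before normalizing (default TRUE).
#' @return a `glcm` object: `p` (levels x levels, sums to 1), `levels`,
#'   `distance`, `angles`, `symmetric`, `n_pairs`.
#' @export
compute_glcm <- function(qimage, distance = 1L, angles = c(0, 45, 90, 135),
                         symmetric = TRUE) {
  levels <- attr(qimage, "levels")
  if (is.null(levels)) stop("qimage must come from quantize_gray()", call. = FALSE)
  nr <- nrow(qimage); nc <- ncol(qimage)
  counts <- matrix(0, levels, levels)
  n_pairs <- 0L
  for (off in glcm_offsets(as.integer(distance), angles)) {
    dr <- off[1]; dc <- off[2]
    r0 <- max(1L, 1L - dr):min(nr, nr - dr)
    c0 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- qimage[r0, c0, drop = FALSE]
    b <- qimage[r0 + dr, c0 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- cbind(a[ok] + 1L, b[ok] + 1L)
    tab <- table(factor(idx[, 1], levels = seq_len(levels)),
                 factor(idx[, 2], levels = seq_len(levels)))
    counts <- counts + as.matrix(tab)
    n_pairs <- n_pairs + sum(ok)
  }
  if (n_pairs == 0L) stop("no valid in-mask pixel pairs", call. = FALSE)
  dimnames(counts) <- NULL
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), levels = levels,
                 distance = as.integer(distance), angles = angles,
                 symmetric = symmetric, n_pairs = n_pairs),
            class = "glcm")
}

#' The 7-dimensional GLCM texture descriptor
#'
#' Computes contrast, correlation, energy, homogeneity, variance, mean and
#' entropy from a normalized co-occurrence matrix, in that fixed order:
#' * contrast `sum (i-j)^2 P_ij`
#' * correlation `sum (i - mu_i)(j - mu_j) P_ij / (sigma_i sigma_j)`
#'   (defined as 1 when a marginal variance vanishes)
#' * energy `sum P_ij^2` (angular second moment)
#' * homogeneity `sum P_ij / (1 + (i-j)^2)` (inverse difference moment)
#' * variance of the row-marginal level distribution
#' * mean: average in-mask pixel level normalized to `[0, 1]` (a proxy for
#'   region brightness/color)
#' * entropy `-sum P_ij log P_ij` in nats, with `0 log 0 = 0`.
#'
#' @param glcm a [compute_glcm()] result.
#' @param qimage the quantized image the GLCM came from (for the mean).
#' @return one-row tibble with the seven features.
#' @export
texture_features <- function(glcm, qimage) {
  P <- glcm$p
  L <- glcm$levels
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  pi_ <- rowSums(P)
  pj <- colSums(P)
  mu_i <- sum((0:(L - 1)) * pi_)
  mu_j <- sum((0:(L - 1)) * pj)
  var_i <- sum(((0:(L - 1)) - mu_i)^2 * pi_)
  var_j <- sum(((0:(L - 1)) - mu_j)^2 * pj)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (var_i < 1e-15 || var_j < 1e-15) {
    1 # degenerate single-level region: perfectly correlated by convention
  } else {
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j)
  }
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  pos <- P > 0
  entropy <- -sum(P[pos] * log(P[pos]))
  lv <- qimage[!is.na(qimage)]
  tibble::tibble(
    contrast = contrast,
    correlation = correlation,
    energy = energy,
    homogeneity = homogeneity,
    variance = var_i,
    mean = mean(lv) / (L - 1),
    entropy = entropy
  )
}

#' GLCM texture features of a masked image region
#'
#' Convenience wrapper: quantize, build the co-occurrence matrix and return
#' the 7-dim descriptor in one call.
#'
#' @inheritParams quantize_gray
#' @inheritParams compute_glcm
#' @return one-row tibble of the seven features.
#' @export
glcm_features <- function(image, mask = NULL, levels = 64L, distance = 1L,
                          angles = c(0, 45, 90, 135), symmetric = TRUE) {
  q <- quantize_gray(image, mask, levels)
  g <- compute_glcm(q, distance, angles, symmetric)
  texture_features(g, q)
}
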