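#' Fit a PLS-DA model on mean spectra
#'
#' Partial least squares regression of the ordinal quality code (0 fresh,
#' 1 newly damaged, 2 / 3 two and four hours after damage) on the spectral
#' matrix, used as a discriminant model by rounding the continuous
#' prediction to the nearest code. Components are extracted sequentially
#' (NIPALS): the weight vector is the normalized covariance direction
#' `X'y`, scores are deflated out of X after each component, and the
#' regression vector is assembled as `B = W (P'W)^{-1} q`. Only
#' mean-centering is applied; reflectance spectra already share a scale.
#'
#' @param x samples x bands numeric matrix, or a `spectrum_table`.
#' @param y numeric response codes (ignored when `x` is a table).
#' @param n_latent number of latent variables (>= 1).
#' @return a `plsda_model` with centering vectors, weights `W`, loadings
#'   `P`, response loadings `q`, coefficient vector `b`, score matrix `T`
#'   of the training data, and the code set.
#' @export
fit_plsda <- function(x, y = NULL, n_latent = 2L) {
  if (inherits(x, "spectrum_table")) {
    y <- spectra_labels(x)
    wl <- attr(x, "wavelength")
    x <- spectra_matrix(x)
  } else {
    wl <- NULL
    x <- as.matrix(x)
  }
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  n_latent <- as.integer(n_latent)
  if (n_latent < 1L) stop("n_latent must be >= 1", call. = FALSE)
  if (n_latent > min(n - 1L, p)) {
    stop("n_latent = ", n_latent, " exceeds min(samples - 1, bands) = ",
         min(n - 1L, p), call. = FALSE)
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  X <- sweep(x, 2, x_mean)
  if (all(abs(X) < 1e-12)) stop("spectral matrix has zero variance", call. = FALSE)
  u <- y - y_mean
  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  Tm <- matrix(0, n, n_latent)
  q <- numeric(n_latent)
  for (a in seq_len(n_latent)) {
    w <- drop(crossprod(X, u))
    nw <- sqrt(sum(w^2))
    if (nw >= 1e-14) {
      t_try <- drop(X %*% (w / nw))
      if (sum(t_try^2) < 1e-20) nw <- 0 # X exhausted along this direction
    }
    if (nw < 1e-14) { # response variance exhausted; keep remaining terms zero
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      n_latent <- a - 1L
      break
    }
    w <- w / nw
    t_ <- drop(X %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(X, t_)) / tt
    q_a <- sum(u * t_) / tt
    X <- X - tcrossprod(t_, p_)
    u <- u - q_a * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_a
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(
    x_mean = x_mean, y_mean = y_mean,
    W = W, P = P, q = q, b = b, scores = Tm,
    n_latent = n_latent, codes = 0:3, wavelength = wl
  ), class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d latent variable(s), %d bands\n",
              x$n_latent, length(x$b)))
  invisible(x)
}

#' Continuous and class predictions from a PLS-DA model
#'
#' The continuous prediction is `(x - x_mean) . b + y_mean`; the class is
#' the nearest code in `{0, 1, 2, 3}`, with exact midpoints resolved to the
#' lower code and values outside the code range clamped.
#'
#' @param object a `plsda_model`.
#' @param newdata samples x bands matrix, single spectrum, or
#'   `spectrum_table`.
#' @param type `"class"` (default) or `"response"` for the continuous score.
#' @param ... unused.
#' @return integer codes or numeric responses, one per sample.
#' @export
predict.plsda_model <- function(object, newdata, type = c("class", "response"),
                                ...) {
  type <- match.arg(type)
  if (inherits(newdata, "spectrum_table")) newdata <- spectra_matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$b)) {
    stop("spectrum has ", ncol(newdata), " bands but the model expects ",
         length(object$b), call. = FALSE)
  }
  yhat <- drop(sweep(as.matrix(newdata), 2, object$x_mean) %*% object$b) +
    object$y_mean
  if (type == "response") return(yhat)
  nearest_code(yhat, object$codes)
}

# nearest code; ties (exact midpoints) go to the lower code
nearest_code <- function(yhat, codes = 0:3) {
  vapply(yhat, function(v) {
    codes[which.min(abs(codes - v))]
  }, numeric(1)) |> as.integer()
}

#' Choose the number of latent variables by leave-one-out cross-validation
#'
#' Evaluates 1..`max_latent` components by full leave-one-out
#' cross-validation of the coded response and returns the count minimizing
#' the root-mean-square prediction error (ties go to the smaller count).
#'
#' @param table a `spectrum_table` (or matrix with `y` supplied).
#' @param y response codes when `table` is a bare matrix.
#' @param max_latent largest candidate count (default 10).
#' @return integer, the selected number of latent variables; the RMSE grid
#'   is attached as attribute `rmse`.
#' @export
choose_n_latent <- function(table, y = NULL, max_latent = 10L) {
  if (inherits(table, "spectrum_table")) {
    y <- spectra_labels(table)
    x <- spectra_matrix(table)
  } else {
    x <- as.matrix(table)
  }
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples for cross-validation", call. = FALSE)
  max_latent <- min(max_latent, n - 2L, ncol(x))
  press <- matrix(0, n, max_latent)
  for (i in seq_len(n)) {
    fit <- fit_plsda(x[-i, , drop = FALSE], y[-i], n_latent = max_latent)
    for (a in seq_len(max_latent)) {
      if (a > fit$n_latent) {
        press[i, a] <- press[i, fit$n_latent]
        next
      }
      b_a <- drop(fit$W[, 1:a, drop = FALSE] %*%
                    solve(crossprod(fit$P[, 1:a, drop = FALSE],
                                    fit$W[, 1:a, drop = FALSE]),
                          fit$q[1:a]))
      pred <- sum((x[i, ] - fit$x_mean) * b_a) + fit$y_mean
      press[i, a] <- (pred - y[i])^2
    }
  }
  rmse <- sqrt(colMeans(press))
  best <- which.min(rmse)
  structure(as.integer(best), rmse = rmse)
}

#' Stratified calibration/validation split
#'
#' Splits sample indices class by class with a seeded shuffle so every
#' class appears in both partitions at the requested fraction.
#'
#' @param labels integer class codes.
#' @param cal_frac calibration fraction (default 0.6).
#' @param seed integer seed.
#' @return list with integer index vectors `calibration` and `validation`.
#' @export
stratified_split <- function(labels, cal_frac = 0.6, seed = 1L) {
  stopifnot(cal_frac > 0, cal_frac < 1)
  rng <- local_rng(seed)
  cal <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_cal <- max(1L, round(cal_frac * length(idx)))
    if (n_cal >= length(idx)) n_cal <- length(idx) - 1L
    take <- rng$sample_int(length(idx), n_cal)
    cal <- c(cal, idx[take])
  }
  cal <- sort(cal)
  list(calibration = cal,
       validation = setdiff(seq_along(labels), cal))
}

#' Tidy PLS-DA coefficients
#' @param x a `plsda_model`.
#' @param ... unused.
#' @return tibble with `band`, `wavelength` (if known) and `coefficient`.
#' @export
tidy.plsda_model <- function(x, ...) {
  out <- tibble::tibble(band = seq_along(x$b), coefficient = x$b)
  if (!is.null(x$wavelength)) {
    out <- tibble::add_column(out, wavelength = x$wavelength, .after = "band")
  }
  out
}

#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(n_latent = x$n_latent, n_bands = length(x$b),
                 y_mean = x$y_mean)
}

#' Latent-variable score plot
#'
#' Projects spectra onto the first two latent variables of a fitted
#' model, coloured by quality class.
#'
#' @param model a `plsda_model`.
#' @param table a `spectrum_table` to project (training table typically).
#' @return a ggplot object.
#' @export
plot_plsda_scores <- function(model, table) {
  x <- sweep(spectra_matrix(table), 2, model$x_mean)
  # scores via the direct projection weights R = W (P'W)^{-1}
  R <- model$W %*% solve(crossprod(model$P, model$W))
  sc <- x %*% R
  df <- tibble::tibble(
    lv1 = sc[, 1],
    lv2 = if (ncol(sc) >= 2) sc[, 2] else 0,
    class = factor(spectra_labels(table))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lv1, y = .data$lv2,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent variable 1", y = "latent variable 2",
                  colour = "quality class")
}

#' Serialize / restore a PLS-DA model as JSON
#' @param model a `plsda_model`.
#' @param path JSON path.
#' @return `write_plsda()` the path invisibly; `read_plsda()` the model.
#' @export
write_plsda <- function(model, path) {
  payload <- list(
    x_mean = model$x_mean, y_mean = model$y_mean,
    W = model$W, P = model$P, q = model$q, b = model$b,
    n_latent = model$n_latent, codes = model$codes,
    wavelength = model$wavelength
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plsda
#' @export
read_plsda <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$W <- as.matrix(p$W); p$P <- as.matrix(p$P)
  p$scores <- NULL
  structure(p, class = "plsda_model")
}
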