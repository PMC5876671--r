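#' Fit a binary least-squares SVM
#'
#' Solves the LS-SVM dual in one linear system
#' `[[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y]`, with features
#' standardized to zero mean and unit variance using the training
#' statistics. The kernel is either linear or Gaussian RBF
#' `K(x, z) = exp(-||x - z||^2 / sigma2)`.
#'
#' @param x training features, n x d matrix.
#' @param y labels in `{-1, +1}`, one per row; both signs required.
#' @param gamma regularization (> 0); larger fits the targets harder.
#' @param kernel `"rbf"` or `"linear"`.
#' @param sigma2 RBF bandwidth (squared length scale).
#' @return an `lssvm_binary`: `alpha`, `b`, `gamma`, `kernel`, `sigma2`,
#'   standardization vectors, stored training features, and the relative
#'   KKT residual of the solve.
#' @export
fit_lssvm_binary <- function(x, y, gamma = 10, kernel = c("rbf", "linear"),
                             sigma2 = 1) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  K <- kernel_matrix(xs, xs, kernel, sigma2)
  n <- nrow(xs)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  rhs <- c(0, y)
  sol <- solve(A, rhs)
  resid <- sqrt(sum((A %*% sol - rhs)^2)) / sqrt(sum(rhs^2))
  structure(list(
    alpha = sol[-1], b = sol[1], gamma = gamma, kernel = kernel,
    sigma2 = sigma2, center = ctr, scale = scl, x_train = xs,
    kkt_residual = resid
  ), class = "lssvm_binary")
}

kernel_matrix <- function(a, b, kernel, sigma2) {
  if (kernel == "linear") return(tcrossprod(a, b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-pmax(d2, 0) / sigma2)
}

# signed decision value f(x) = sum_i alpha_i K(x, x_i) + b
decision_value <- function(model, x) {
  xs <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
  drop(kernel_matrix(xs, model$x_train, model$kernel, model$sigma2) %*%
         model$alpha) + model$b
}

#' Fit a one-vs-one LS-SVM ensemble for the four quality classes
#'
#' Trains the six pairwise binary machines and, when the hyperparameter
#' grids hold more than one candidate, selects `(gamma, sigma2)` jointly by
#' seeded k-fold cross-validated multiclass accuracy on the training data
#' (ties resolved to the first grid entry, i.e. the smallest values).
#'
#' @param features n x d numeric matrix or a tibble/data.frame of numeric
#'   columns (a `sample_id`/`label` column is dropped automatically).
#' @param labels integer quality codes 0-3; all four must be present.
#' @param gamma_grid,sigma2_grid candidate values (log-spaced defaults).
#' @param kernel `"rbf"` or `"linear"`.
#' @param cv_folds folds for the grid search (default 5).
#' @param seed fold-assignment seed.
#' @return an `lssvm_ensemble`: list of 6 binary models keyed
#'   `"<a>_<b>"`, chosen `gamma`/`sigma2`, the cross-validation table, and
#'   the code set.
#' @export
fit_lssvm <- function(features, labels, gamma_grid = 10^(0:4),
                      sigma2_grid = 10^seq(-1, 2), kernel = "rbf",
                      cv_folds = 5L, seed = 1L) {
  x <- feature_matrix(features)
  labels <- as.integer(labels)
  codes <- 0:3
  if (!all(codes %in% labels)) stop("all 4 classes must be present", call. = FALSE)
  if (!length(gamma_grid) || !length(sigma2_grid)) {
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(gamma = gamma_grid, sigma2 = sigma2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cv <- NULL
  if (nrow(grid) > 1L) {
    folds <- stratified_folds(labels, cv_folds, seed)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0L
      for (f in seq_len(max(folds))) {
        tr <- folds != f; te <- folds == f
        ens <- train_ovo(x[tr, , drop = FALSE], labels[tr],
                         grid$gamma[g], grid$sigma2[g], kernel, codes)
        pred <- predict_ovo(ens, x[te, , drop = FALSE], codes)
        correct <- correct + sum(pred == labels[te])
      }
      correct / length(labels)
    }, numeric(1))
    cv <- cbind(grid, accuracy = acc)
    best <- which.max(acc) # ties: first entry, smallest gamma then sigma2
    grid <- grid[best, ]
  }
  models <- train_ovo(x, labels, grid$gamma[1], grid$sigma2[1], kernel, codes)
  structure(list(models = models, gamma = grid$gamma[1],
                 sigma2 = grid$sigma2[1], kernel = kernel, codes = codes,
                 cv = cv, feature_names = colnames(x)),
            class = "lssvm_ensemble")
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[, setdiff(names(features), c("sample_id", "label")),
                         drop = FALSE]
    features <- as.matrix(features)
  }
  storage.mode(features) <- "double"
  if (anyNA(features)) stop("features contain missing values", call. = FALSE)
  features
}

stratified_folds <- function(labels, k, seed) {
  rng <- local_rng(seed)
  folds <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_int(length(idx), length(idx))]
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

train_ovo <- function(x, labels, gamma, sigma2, kernel, codes) {
  pairs <- utils::combn(codes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    if (!any(labels[sel] == pr[1]) || !any(labels[sel] == pr[2])) return(NULL)
    y <- ifelse(labels[sel] == pr[2], 1, -1)
    fit_lssvm_binary(x[sel, , drop = FALSE], y, gamma, kernel, sigma2)
  })
  names(models) <- vapply(pairs, paste, character(1), collapse = "_")
  models
}

predict_ovo <- function(models, x, codes) {
  votes <- matrix(0L, nrow(x), length(codes))
  colnames(votes) <- codes
  for (key in names(models)) {
    if (is.null(models[[key]])) next
    pr <- as.integer(strsplit(key, "_")[[1]])
    f <- decision_value(models[[key]], x)
    win <- ifelse(f > 0, pr[2], pr[1])
    for (cd in pr) {
      votes[, as.character(cd)] <- votes[, as.character(cd)] + (win == cd)
    }
  }
  codes[max.col(votes, ties.method = "first")] # ties: smallest code
}

#' Predict quality classes from an LS-SVM ensemble
#'
#' Majority vote over the six pairwise decisions; vote ties resolve to the
#' smallest class code.
#'
#' @param object an `lssvm_ensemble`.
#' @param newdata feature matrix/tibble with the training dimensionality.
#' @param ... unused.
#' @return integer quality codes.
#' @export
predict.lssvm_ensemble <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  if (is.null(dim(x)) || ncol(x) == 1L && length(object$feature_names) > 1L) {
    x <- matrix(x, nrow = 1)
  }
  d_expect <- length(object$models[[1]]$center)
  if (ncol(x) != d_expect) {
    stop("feature vector has ", ncol(x), " dimensions but the model expects ",
         d_expect, call. = FALSE)
  }
  predict_ovo(object$models, x, object$codes)
}

#' @export
print.lssvm_ensemble <- function(x, ...) {
  cat(sprintf("<lssvm_ensemble> one-vs-one, %s kernel, gamma = %g, sigma2 = %g\n",
              x$kernel, x$gamma, x$sigma2))
  invisible(x)
}

#' @export
glance.lssvm_ensemble <- function(x, ...) {
  tibble::tibble(
    kernel = x$kernel, gamma = x$gamma, sigma2 = x$sigma2,
    max_kkt_residual = max(vapply(x$models, function(m) m$kkt_residual,
                                  numeric(1)))
  )
}
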