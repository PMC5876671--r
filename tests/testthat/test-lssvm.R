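# 4 well-separated Gaussian blobs in 7-D feature space
blob_data <- function(n_per = 12, sep = 10, sd = 1, seed = 3) {
  set.seed(seed)
  centers <- matrix(0, 4, 7)
  centers[2, 1] <- sep; centers[3, 2] <- sep; centers[4, 3] <- sep
  x <- do.call(rbind, lapply(1:4, function(k) {
    sweep(matrix(rnorm(n_per * 7, 0, sd), n_per), 2, centers[k, ], "+")
  }))
  list(x = x, y = rep(0:3, each = n_per), centers = centers)
}

test_that("the dual linear system solves the hand-worked 2-point problem", {
  # two 1-D points x = -1, +1 with labels -1, +1; linear kernel, gamma large.
  # After standardization the points sit at -/+ 1/sqrt(2)... solve by hand:
  # K = [1 -1; -1 1] * (1/2) scaled; verify via the returned system residual
  # and the decision geometry instead of hard-coded algebra.
  fit <- fit_lssvm_binary(matrix(c(-1, 1)), c(-1, 1), gamma = 1e6,
                          kernel = "linear")
  f <- litchigrade:::decision_value(fit, matrix(c(-1, 0, 1)))
  expect_lt(abs(f[2]), 1e-6) # boundary at the midpoint
  expect_equal(sign(f[c(1, 3)]), c(-1, 1))
  expect_lt(fit$kkt_residual, 1e-8)
  # independent check: solve the 3x3 KKT system directly with base solve()
  xs <- c(-1, 1) / sd(c(-1, 1))
  K <- outer(xs, xs)
  A <- rbind(c(0, 1, 1), cbind(1, K + diag(2) / 1e6))
  ref <- solve(A, c(0, -1, 1))
  expect_equal(unname(fit$b), ref[1], tolerance = 1e-9)
  expect_equal(unname(fit$alpha), ref[2:3], tolerance = 1e-9)
})

test_that("every fit satisfies the KKT system to 1e-8 relative residual", {
  set.seed(14)
  for (i in 1:5) {
    x <- matrix(rnorm(60), 20, 3)
    y <- sign(x[, 1] + rnorm(20, 0, 0.5)); y[y == 0] <- 1
    for (kern in c("rbf", "linear")) {
      fit <- fit_lssvm_binary(x, y, gamma = 10^(i - 2), kernel = kern,
                              sigma2 = 2)
      expect_lt(fit$kkt_residual, 1e-8)
    }
  }
})

test_that("large gamma drives training decisions to the targets", {
  set.seed(6)
  x <- matrix(rnorm(40), 20, 2)
  y <- ifelse(x[, 1] > 0, 1, -1)
  fit <- fit_lssvm_binary(x, y, gamma = 1e6, kernel = "rbf", sigma2 = 1)
  f <- litchigrade:::decision_value(fit, x)
  expect_lt(max(abs(f - y)), 1e-3) # residual of order 1/gamma
  expect_identical(sign(f), y)
})

test_that("degenerate label sets are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fit_lssvm_binary(x, rep(1, 5), 10), "both classes")
  expect_error(fit_lssvm_binary(x, c(1, 1, 1, 1, 0), 10), "-1 or \\+1")
  expect_error(fit_lssvm_binary(x, c(1, 1, 1, -1, -1), gamma = -1), "gamma")
})

test_that("the one-vs-one ensemble classifies well-separated blobs perfectly", {
  d <- blob_data(n_per = 12, sep = 10)
  test <- blob_data(n_per = 6, sep = 10, seed = 99)
  ens <- fit_lssvm(d$x, d$y, gamma_grid = 100, sigma2_grid = 50)
  expect_length(ens$models, 6) # C(4,2) pairwise machines
  expect_identical(predict(ens, test$x), test$y)
  # blob centers themselves classify to their own class
  expect_identical(predict(ens, d$centers), 0:3)
})

test_that("grid search is skipped for singleton grids and is order-stable", {
  d <- blob_data(n_per = 8)
  single <- fit_lssvm(d$x, d$y, gamma_grid = 10, sigma2_grid = 1)
  expect_null(single$cv)
  expect_identical(c(single$gamma, single$sigma2), c(10, 1))

  grid1 <- fit_lssvm(d$x, d$y, gamma_grid = c(1, 100),
                     sigma2_grid = c(0.5, 5), cv_folds = 3, seed = 11)
  perm <- sample(length(d$y))
  grid2 <- fit_lssvm(d$x[perm, ], d$y[perm], gamma_grid = c(1, 100),
                     sigma2_grid = c(0.5, 5), cv_folds = 3, seed = 11)
  expect_identical(c(grid1$gamma, grid1$sigma2), c(grid2$gamma, grid2$sigma2))
  expect_error(fit_lssvm(d$x, d$y, gamma_grid = numeric(0)), "non-empty")
})

test_that("prediction validates dimensionality and missing values", {
  d <- blob_data(n_per = 6)
  ens <- fit_lssvm(d$x, d$y, gamma_grid = 10, sigma2_grid = 1)
  expect_error(predict(ens, matrix(0, 2, 3)), "dimensions")
  bad <- d$x[1:2, ]; bad[1, 1] <- NA
  expect_error(predict(ens, bad), "missing")
})

test_that("confusion matrices reproduce the printed per-class and average accuracies", {
  # validation set: diagonal (12, 10, 11, 12) of 12-sample rows
  cm_val <- rbind(c(12, 0, 0, 0),
                  c(1, 10, 1, 0),
                  c(0, 1, 11, 0),
                  c(0, 0, 0, 12))
  rep_val <- class_report_from_matrix(cm_val)
  expect_equal(round(rep_val$per_class$accuracy[2], 2), 83.33)
  expect_equal(rep_val$mean_accuracy, 93.75)

  cm_ext <- rbind(c(20, 0, 0, 0),
                  c(2, 18, 0, 0),
                  c(0, 2, 18, 0),
                  c(0, 0, 0, 20))
  expect_equal(class_report_from_matrix(cm_ext)$mean_accuracy, 95.00)
})
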