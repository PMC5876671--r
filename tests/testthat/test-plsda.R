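toy_data <- function(n = 24, p = 8, rank = 3, seed = 2) {
  set.seed(seed)
  scores <- matrix(rnorm(n * rank), n)
  load <- matrix(rnorm(rank * p), rank)
  x <- scores %*% load
  y <- drop(scores %*% rnorm(rank))
  list(x = x, y = y)
}

test_that("a single component fits exact rank-1 structure", {
  set.seed(1)
  t1 <- rnorm(20)
  x <- outer(t1, rnorm(6))
  y <- 2 * t1 + 1
  fit <- fit_plsda(x, y, n_latent = 1)
  expect_lt(max(abs(predict(fit, x, type = "response") - y)), 1e-8)
})

test_that("full-dimensional PLS equals ordinary least squares", {
  d <- toy_data(n = 30, p = 5, rank = 5)
  fit <- fit_plsda(d$x, d$y, n_latent = 5)
  ols <- lm(y ~ x, data = list(y = d$y, x = d$x))
  expect_equal(predict(fit, d$x, type = "response"),
               unname(fitted(ols)), tolerance = 1e-6)
})

test_that("successive score vectors are mutually orthogonal", {
  d <- toy_data(n = 40, p = 12, rank = 6, seed = 8)
  fit <- fit_plsda(d$x, d$y + rnorm(40, 0, 0.1), n_latent = 5)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
})

test_that("duplicating every training row leaves predictions unchanged", {
  d <- toy_data(n = 15, p = 6, rank = 4)
  f1 <- fit_plsda(d$x, d$y, n_latent = 3)
  f2 <- fit_plsda(rbind(d$x, d$x), c(d$y, d$y), n_latent = 3)
  expect_equal(predict(f1, d$x, type = "response"),
               predict(f2, d$x, type = "response"), tolerance = 1e-8)
})

test_that("training on offset spectra gives identical offset-data predictions", {
  d <- toy_data()
  f1 <- fit_plsda(d$x, d$y, n_latent = 2)
  f2 <- fit_plsda(d$x + 5, d$y, n_latent = 2)
  expect_equal(predict(f1, d$x, type = "response"),
               predict(f2, d$x + 5, type = "response"), tolerance = 1e-8)
})

test_that("class assignment uses the nearest code with lower-code ties and clamping", {
  expect_identical(litchigrade:::nearest_code(c(1.49, 2.5, -0.7, 3.9, 0.5)),
                   c(1L, 2L, 0L, 3L, 0L))
})

test_that("n_latent is validated against the data size", {
  d <- toy_data(n = 10, p = 4)
  expect_error(fit_plsda(d$x, d$y, n_latent = 5), "exceeds")
  expect_error(fit_plsda(matrix(1, 8, 3), rep(1, 8), n_latent = 1),
               "zero variance")
})

test_that("leave-one-out selection finds low-rank structure and honours the grid", {
  d <- toy_data(n = 24, p = 10, rank = 2, seed = 5)
  sel <- choose_n_latent(d$x, d$y, max_latent = 8)
  expect_lte(as.integer(sel), 2)
  rmse <- attr(sel, "rmse")
  expect_identical(which.min(rmse), as.integer(sel))

  expect_identical(as.integer(choose_n_latent(d$x, d$y, max_latent = 1)), 1L)

  # pure-noise response: the chosen error is near the best over the grid
  set.seed(10)
  y_noise <- rnorm(24)
  sel2 <- choose_n_latent(d$x, y_noise, max_latent = 6)
  r2 <- attr(sel2, "rmse")
  expect_lte(r2[as.integer(sel2)], 1.1 * min(r2))
})

test_that("stratified splits keep every class on both sides", {
  labels <- rep(0:3, each = 30)
  sp <- stratified_split(labels, cal_frac = 0.6, seed = 3)
  expect_length(sp$calibration, 72)
  expect_length(sp$validation, 48)
  expect_equal(as.vector(table(labels[sp$calibration])), rep(18L, 4))
  expect_equal(as.vector(table(labels[sp$validation])), rep(12L, 4))
  expect_identical(sp, stratified_split(labels, cal_frac = 0.6, seed = 3))
})

test_that("class reports compute the per-type means from per-class metrics", {
  expect_equal(round(mean_per_type(c(94.18, 90.23, 91.21, 93.15)), 2), 92.19)
  expect_equal(round(mean_per_type(c(100.00, 85.71, 90.18, 91.07)), 2), 91.74)

  perfect <- class_report(rep(0:3, each = 5), rep(0:3, each = 5))
  expect_true(all(perfect$per_class$recall == 100))
  expect_true(all(perfect$per_class$precision == 100))
  expect_equal(unname(diag(perfect$confusion)), rep(5L, 4))

  expect_error(class_report(c(0, 1), c(0, 5)), "outside")
  expect_error(class_report(c(0, 1), c(0, 1, 2)), "length")
})

test_that("tidy and glance expose report and model summaries", {
  rep <- class_report(c(0, 1, 2, 3, 0), c(0, 1, 2, 3, 1))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 4L)
  gl <- glance(rep)
  expect_identical(gl$n, 5L)

  d <- toy_data()
  fit <- fit_plsda(d$x, d$y, n_latent = 2)
  expect_identical(nrow(tidy(fit)), 8L)
  expect_identical(glance(fit)$n_latent, 2L)
})

test_that("PLS-DA models serialize to JSON and back", {
  wl <- wavelength_axis()[1:12]
  spectra <- lapply(1:12, function(i) runif(12))
  tbl <- build_spectrum_table(spectra, rep(0:3, 3), wl)
  fit <- fit_plsda(tbl, n_latent = 2)
  withr::with_tempdir({
    write_plsda(fit, "model.json")
    back <- read_plsda("model.json")
    expect_equal(back$b, fit$b, tolerance = 1e-12)
    expect_identical(predict(back, tbl), predict(fit, tbl))
  })
})
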