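make_cube <- function(values, wl = c(500, 550, 600, 650, 700),
                      kind = "reflectance", nr = 4, nc = 4) {
  hsi_cube(array(values, dim = c(nr, nc, length(wl))), wl, kind)
}

test_that("ENVI write/read round-trips both data types and interleaves", {
  withr::with_tempdir({
    set.seed(1)
    raw <- make_cube(sample(0:60000, 80), kind = "raw")
    for (il in c("bsq", "bil")) {
      write_envi(raw, paste0("raw_", il), interleave = il)
      back <- read_envi(paste0("raw_", il, ".dat"))
      expect_equal(unclass(back), unclass(raw), ignore_attr = TRUE)
      expect_identical(attr(back, "kind"), "raw")
      expect_equal(wavelengths(back), wavelengths(raw))
    }
    refl <- make_cube(runif(80))
    write_envi(refl, "refl")
    back <- read_envi("refl.dat")
    expect_equal(unclass(back), unclass(refl), ignore_attr = TRUE,
                 tolerance = 1e-6) # float32 storage
    # raw file size: rows*cols*bands*2 bytes
    expect_identical(file.size("raw_bsq.dat"), 4 * 4 * 5 * 2)
    hdr <- readLines("refl.hdr")
    expect_true(any(grepl("data type = 4", hdr)))
    wl_line <- grep("wavelength =", hdr, value = TRUE)
    expect_length(strsplit(wl_line, ",")[[1]], 5)
  })
})

test_that("header/cube inconsistencies are rejected", {
  withr::with_tempdir({
    raw <- make_cube(rep(7, 80), kind = "raw")
    write_envi(raw, "c")
    hdr <- readLines("c.hdr")
    hdr[grep("bands =", hdr)] <- "bands = 6"
    writeLines(hdr, "c.hdr")
    expect_error(read_envi("c.dat"), "wavelength list length")
    hdr[grep("wavelength =", hdr)] <-
      "wavelength = { 500, 550, 600, 650, 700, 750 }"
    writeLines(hdr, "c.hdr")
    expect_error(read_envi("c.dat"), "holds")
    hdr2 <- hdr[-grep("wavelength", hdr)]
    writeLines(hdr2, "c.hdr")
    expect_error(read_envi("c.dat"), "no wavelength list")
  })
})

test_that("calibration reproduces the two-point anchors and worked ratio", {
  raw <- make_cube(50, kind = "raw")
  expect_equal(as.vector(calibrate_reflectance(make_cube(90, kind = "raw"),
                                               white = 90, dark = 10)),
               rep(1, 80))
  expect_equal(as.vector(calibrate_reflectance(make_cube(10, kind = "raw"),
                                               white = 90, dark = 10)),
               rep(0, 80))
  expect_equal(as.vector(calibrate_reflectance(raw, white = 90, dark = 10)),
               rep(0.5, 80))
})

test_that("calibration is affine per pixel-band and clips at the ceiling", {
  W <- matrix(1000, 4, 4); D <- matrix(20, 4, 4)
  for (a in c(0.25, 0.9, 1.2)) {
    raw <- make_cube(a * 1000 + (1 - a) * 20, kind = "raw")
    out <- calibrate_reflectance(raw, W, D)
    expect_equal(as.vector(out), rep(a, 80), tolerance = 1e-6)
  }
  hot <- make_cube(3000, kind = "raw")
  expect_equal(max(calibrate_reflectance(hot, W, D)), 1.5) # clip_hi
  expect_equal(max(calibrate_reflectance(hot, W, D, clip_hi = 2.5)), 2.5,
               tolerance = 1e-6)
})

test_that("degenerate white-dark pixels yield zero reflectance with a warning", {
  W <- matrix(1000, 4, 4); D <- matrix(20, 4, 4)
  W[2, 3] <- D[2, 3] # zero dynamic range at one pixel
  raw <- make_cube(510, kind = "raw")
  expect_warning(out <- calibrate_reflectance(raw, W, D), "eps")
  expect_equal(as.vector(out[2, 3, ]), rep(0, 5))
  expect_equal(out[1, 1, 1], 0.5, tolerance = 1e-6)
  expect_identical(attr(out, "n_degenerate"), 5L)
  expect_error(calibrate_reflectance(raw, white = 0, dark = 0), "all zero")
})

test_that("reference frames broadcast from per-column vectors", {
  raw <- make_cube(510, kind = "raw")
  out <- calibrate_reflectance(raw, white = rep(1000, 4), dark = rep(20, 4))
  expect_equal(as.vector(out), rep(0.5, 80), tolerance = 1e-6)
  expect_error(calibrate_reflectance(raw, white = rep(1000, 3), dark = 20),
               "white frame")
})

test_that("band trimming filters the axis consistently and composes", {
  cube <- hsi_cube(array(runif(4 * 4 * 215), c(4, 4, 215)),
                   wavelength_axis(), "reflectance")
  tr <- trim_bands(cube, 450, 850)
  expect_true(all(wavelengths(tr) >= 450 & wavelengths(tr) <= 850))
  expect_identical(dim(tr)[3], length(wavelengths(tr)))
  # identity bounds
  expect_identical(dim(trim_bands(cube, 400, 1000)), dim(cube))
  # nested trims equal the tighter trim
  ab <- trim_bands(trim_bands(cube, 450, 850), 500, 700)
  expect_equal(unclass(ab), unclass(trim_bands(cube, 500, 700)),
               ignore_attr = TRUE)
  expect_error(trim_bands(trim_bands(cube, 400, 850), 900, 950), "no bands")
})
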