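#' Mean spectrum over a square region of interest
#'
#' Averages the cube over a `size` x `size` pixel window (default 50 x 50,
#' i.e. 2500 pixels) centred at the given pixel, one mean per band.
#'
#' @param cube an [hsi_cube()].
#' @param center_row,center_col window centre in pixels (1-based).
#' @param size window side length in pixels.
#' @return numeric vector of per-band means, named by wavelength.
#' @export
extract_roi_mean <- function(cube, center_row, center_col, size = 50L) {
  d <- dim(cube)
  r0 <- floor(center_row - (size - 1) / 2 + 0.5); r1 <- r0 + size - 1
  c0 <- floor(center_col - (size - 1) / 2 + 0.5); c1 <- c0 + size - 1
  if (r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2]) {
    stop(sprintf("ROI [%d:%d, %d:%d] falls outside the %dx%d image",
                 r0, r1, c0, c1, d[1], d[2]), call. = FALSE)
  }
  sub <- unclass(cube)[r0:r1, c0:c1, , drop = FALSE]
  m <- apply(sub, 3, mean)
  names(m) <- format(wavelengths(cube), trim = TRUE)
  m
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares polynomial convolution smoothing. Endpoints are handled by
#' fitting the local polynomial to the partial windows at the edges, so any
#' polynomial of degree at most `polyorder` passes through unchanged.
#'
#' @param x numeric spectrum.
#' @param window odd filter length in bands (default 11).
#' @param polyorder polynomial degree (default 2); must be < `window`.
#' @return smoothed numeric vector, same length and names as `x`.
#' @export
sg_smooth <- function(x, window = 11L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (window > length(x)) stop("window exceeds spectrum length", call. = FALSE)
  out <- as.numeric(signal::sgolayfilt(as.numeric(x), p = polyorder, n = window))
  names(out) <- names(x)
  out
}

#' Baseline correction and detrending
#'
#' `"baseline"` subtracts the per-spectrum minimum so the lowest point maps
#' to zero; `"detrend"` subtracts the least-squares straight line fitted
#' over wavelength; `"both"` applies baseline then detrend. Detrending is
#' idempotent.
#'
#' @param x numeric spectrum.
#' @param wavelength axis matching `x` (only used for detrending).
#' @param mode one of `"baseline"`, `"detrend"`, `"both"`.
#' @return corrected numeric vector.
#' @export
detrend_baseline <- function(x, wavelength = seq_along(x),
                             mode = c("both", "baseline", "detrend")) {
  mode <- match.arg(mode)
  if (length(x) < 3L) stop("spectrum must have at least 3 points", call. = FALSE)
  nm <- names(x)
  x <- as.numeric(x)
  if (mode %in% c("baseline", "both")) x <- x - min(x)
  if (mode %in% c("detrend", "both")) {
    fit <- stats::lm.fit(cbind(1, wavelength), x)
    x <- fit$residuals
  }
  names(x) <- nm
  x
}

#' Preprocess one mean spectrum
#'
#' The standard chain applied to every ROI mean spectrum before modelling:
#' trim to a wavelength window, Savitzky-Golay smooth, then baseline/
#' detrend correction. Any step can be disabled.
#'
#' @param x numeric spectrum over `wavelength`.
#' @param wavelength band centers in nm.
#' @param trim length-2 window in nm, or `NULL` to keep all bands.
#' @param sg_window,sg_polyorder Savitzky-Golay settings; `sg_window = 0`
#'   disables smoothing.
#' @param mode correction mode for [detrend_baseline()], or `"none"`.
#' @return list with `x` (processed spectrum) and `wavelength`.
#' @export
preprocess_spectrum <- function(x, wavelength, trim = c(450, 850),
                                sg_window = 11L, sg_polyorder = 2L,
                                mode = "both") {
  if (!is.null(trim)) {
    t <- trim_spectra(x, wavelength, trim[1], trim[2])
    x <- t$x; wavelength <- t$wavelength
  }
  if (sg_window > 0) x <- sg_smooth(x, sg_window, sg_polyorder)
  if (mode != "none") x <- detrend_baseline(x, wavelength, mode)
  list(x = x, wavelength = wavelength)
}

#' Assemble preprocessed spectra into a modelling table
#'
#' Stacks per-sample mean spectra into a tibble with one row per sample:
#' `sample_id`, `label`, then one `wl_<nm>` column per band. The wavelength
#' axis is carried in the `wavelength` attribute; all spectra must share it.
#'
#' @param spectra list of numeric vectors (one per sample, equal lengths).
#' @param labels integer quality codes 0-3, one per spectrum.
#' @param wavelength shared band axis in nm.
#' @param sample_ids optional character ids; defaults to `s001`, ...
#' @return a `spectrum_table` tibble.
#' @export
build_spectrum_table <- function(spectra, labels, wavelength,
                                 sample_ids = NULL) {
  if (length(spectra) == 0L) stop("no spectra supplied", call. = FALSE)
  if (length(labels) != length(spectra)) {
    stop("labels and spectra lengths differ", call. = FALSE)
  }
  lens <- vapply(spectra, length, integer(1))
  if (any(lens != length(wavelength))) {
    stop("spectrum length differs from the wavelength axis: got ",
         paste(unique(lens), collapse = ", "), " vs ", length(wavelength),
         call. = FALSE)
  }
  x <- do.call(rbind, lapply(spectra, as.numeric))
  if (anyNA(x)) stop("spectra contain missing values", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_along(spectra))
  colnames(x) <- sprintf("wl_%s", format(wavelength, trim = TRUE))
  out <- tibble::tibble(sample_id = sample_ids,
                        label = as.integer(labels))
  out <- dplyr::bind_cols(out, tibble::as_tibble(x))
  attr(out, "wavelength") <- as.numeric(wavelength)
  class(out) <- c("spectrum_table", class(out))
  out
}

#' @export
print.spectrum_table <- function(x, ...) {
  wl <- attr(x, "wavelength")
  cat(sprintf("<spectrum_table> %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(x), length(wl), wl[1], wl[length(wl)]))
  NextMethod()
}

#' Spectral matrix and labels of a spectrum table
#' @param table a `spectrum_table`.
#' @return `spectra_matrix()`: numeric samples x bands matrix;
#'   `spectra_labels()`: integer label vector.
#' @export
spectra_matrix <- function(table) {
  as.matrix(table[, grep("^wl_", names(table)), drop = FALSE])
}

#' @rdname spectra_matrix
#' @export
spectra_labels <- function(table) as.integer(table$label)

#' Read/write a spectrum table as CSV
#'
#' Plain-text interchange: first column `sample_id`, second `label`, then
#' one column per wavelength headed `wl_<nm>`.
#'
#' @param table a `spectrum_table`.
#' @param path CSV path.
#' @return `write_spectrum_table()` the path invisibly;
#'   `read_spectrum_table()` a `spectrum_table`.
#' @export
write_spectrum_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_table
#' @export
read_spectrum_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df), value = TRUE)
  wl <- as.numeric(sub("^wl_", "", wl_cols))
  build_spectrum_table(
    spectra = lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, wl_cols])),
    labels = df$label, wavelength = wl, sample_ids = df$sample_id
  )
}
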