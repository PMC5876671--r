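#' Default VNIR wavelength axis
#'
#' Band centers for a visible/near-infrared line-scan imager covering
#' 400-1000 nm at 2.8 nm spectral resolution. The default grid has 215
#' bands from 400 to 999.2 nm, so the sensitive wavelengths near 694,
#' 725 and 798 nm are representable by their nearest band centers
#' (694.0, 724.8 and 797.6 nm).
#'
#' @param n_bands number of band centers.
#' @param start first band center in nm (must be >= 400).
#' @param step band spacing in nm.
#' @return numeric vector of strictly increasing wavelengths in nm.
#' @export
#' @examples
#' wl <- wavelength_axis()
#' range(wl)
wavelength_axis <- function(n_bands = 215L, start = 400, step = 2.8) {
  stopifnot(n_bands >= 1, step > 0)
  wl <- start + step * (seq_len(n_bands) - 1)
  if (wl[1] < 400 || wl[length(wl)] > 1000) {
    stop("wavelength axis must lie within 400-1000 nm", call. = FALSE)
  }
  wl
}

#' Construct a hyperspectral cube
#'
#' A cube is a rows x cols x bands numeric array carrying its wavelength
#' axis (nm) and a kind tag: `"raw"` for sensor counts, `"reflectance"`
#' for calibrated relative reflectance.
#'
#' @param data 3-D numeric array, rows x cols x bands.
#' @param wavelength numeric vector of band-center wavelengths in nm,
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @param kind `"raw"` or `"reflectance"`.
#' @return an `hsi_cube` object.
#' @export
hsi_cube <- function(data, wavelength, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) {
    stop("cube data must be a 3-D array (rows x cols x bands)", call. = FALSE)
  }
  wavelength <- as.numeric(wavelength)
  if (length(wavelength) != dim(data)[3]) {
    stop("wavelength axis length (", length(wavelength),
         ") does not match band count (", dim(data)[3], ")", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  }
  structure(data, wavelength = wavelength, kind = kind,
            class = c("hsi_cube", "array"))
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x)
  wl <- attr(x, "wavelength")
  cat(sprintf("<hsi_cube [%s]> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              attr(x, "kind"), d[1], d[2], d[3], wl[1], wl[length(wl)]))
  invisible(x)
}

#' Wavelength axis of a cube
#' @param cube an `hsi_cube`.
#' @return numeric vector of band centers in nm.
#' @export
wavelengths <- function(cube) attr(cube, "wavelength")

#' Index of the band nearest a target wavelength
#' @param cube an `hsi_cube` (or a numeric axis).
#' @param nm target wavelength in nm.
#' @return integer band index.
#' @export
nearest_band <- function(cube, nm) {
  wl <- if (is.numeric(cube) && is.null(dim(cube))) cube else wavelengths(cube)
  which.min(abs(wl - nm))
}

#' Extract one spectral band as a plane
#' @param cube an `hsi_cube`.
#' @param nm wavelength in nm; the nearest band is used.
#' @return numeric matrix (rows x cols).
#' @export
band_plane <- function(cube, nm) {
  k <- nearest_band(cube, nm)
  cube[, , k, drop = TRUE]
}

# Flatten a cube to a (pixels x bands) matrix, row-major pixel order.
cube_to_matrix <- function(cube) {
  d <- dim(cube)
  matrix(cube, nrow = d[1] * d[2], ncol = d[3])
}
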