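#' Write a cube as an ENVI file pair
#'
#' Writes the binary cube plus a text header carrying the wavelength list.
#' Raw-count cubes are stored as unsigned 16-bit integers (ENVI data type
#' 12), reflectance cubes as little-endian 32-bit floats (data type 4).
#' Band-sequential (BSQ) and band-interleaved-by-line (BIL) layouts are
#' supported.
#'
#' @param cube an [hsi_cube()].
#' @param out_prefix path prefix; `<prefix>.dat` and `<prefix>.hdr` are
#'   written.
#' @param interleave `"bsq"` or `"bil"`.
#' @return invisibly, a character vector `c(data, header)` of the paths.
#' @export
write_envi <- function(cube, out_prefix, interleave = c("bsq", "bil")) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  d <- dim(cube)
  wl <- wavelengths(cube)
  kind <- attr(cube, "kind")
  data_path <- paste0(out_prefix, ".dat")
  hdr_path <- paste0(out_prefix, ".hdr")

  # ENVI order: samples (cols) fastest, then the interleave dimension
  arr <- unclass(cube)
  perm <- switch(interleave, bsq = c(2, 1, 3), bil = c(2, 3, 1))
  v <- as.vector(aperm(array(arr, d), perm))
  con <- file(data_path, "wb")
  on.exit(close(con), add = TRUE)
  if (kind == "raw") {
    iv <- as.integer(round(v))
    if (any(iv < 0 | iv > 65535)) {
      stop("raw counts outside the unsigned 16-bit range", call. = FALSE)
    }
    writeBin(iv, con, size = 2L, endian = "little")
    dtype <- 12L
  } else {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
    dtype <- 4L
  }
  hdr <- c(
    "ENVI",
    "description = { litchigrade cube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", dtype),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength units = nm"),
    paste0("wavelength = { ", paste(format(wl, trim = TRUE), collapse = ", "), " }")
  )
  writeLines(hdr, hdr_path)
  invisible(c(data = data_path, header = hdr_path))
}

#' Read an ENVI cube
#'
#' Parses the text header (samples/lines/bands, data type, interleave,
#' byte order, wavelength list) and reads the binary cube into a
#' rows x cols x bands array with origin at the top-left. Supported data
#' types: 4 (float32) read as reflectance, 12 (uint16) read as raw counts;
#' interleaves BSQ and BIL; little-endian only.
#'
#' @param cube_path path to the binary file.
#' @param header_path path to the header; defaults to `cube_path` with the
#'   extension replaced by `.hdr`.
#' @return an [hsi_cube()].
#' @export
read_envi <- function(cube_path, header_path = NULL) {
  if (is.null(header_path)) {
    header_path <- paste0(sub("\\.[^.]*$", "", cube_path), ".hdr")
  }
  if (!file.exists(cube_path)) stop("cube file not found: ", cube_path, call. = FALSE)
  if (!file.exists(header_path)) stop("header not found: ", header_path, call. = FALSE)
  h <- parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave")) {
    if (is.null(h[[key]])) stop("ENVI header missing '", key, "'", call. = FALSE)
  }
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header has no wavelength list", call. = FALSE)
  }
  samples <- as.integer(h$samples); lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
  if (length(wl) != bands) {
    stop("header wavelength list length (", length(wl),
         ") does not match bands (", bands, ")", call. = FALSE)
  }
  if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) != 0L) {
    stop("only little-endian (byte order = 0) files are supported", call. = FALSE)
  }
  interleave <- tolower(trimws(h$interleave))
  if (!interleave %in% c("bsq", "bil")) {
    stop("unsupported interleave '", interleave, "' (BSQ and BIL only)",
         call. = FALSE)
  }
  dtype <- as.integer(h[["data type"]])
  n <- samples * lines * bands
  con <- file(cube_path, "rb")
  on.exit(close(con), add = TRUE)
  if (dtype == 12L) {
    v <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                 endian = "little")
    kind <- "raw"
  } else if (dtype == 4L) {
    v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    kind <- "reflectance"
  } else {
    stop("unsupported ENVI data type ", dtype, " (4 and 12 only)", call. = FALSE)
  }
  if (length(v) != n) {
    stop("cube file holds ", length(v), " values but header implies ", n,
         call. = FALSE)
  }
  dims <- switch(interleave,
                 bsq = c(samples, lines, bands),
                 bil = c(samples, bands, lines))
  perm <- switch(interleave, bsq = c(2, 1, 3), bil = c(3, 1, 2))
  arr <- aperm(array(as.numeric(v), dims), perm)
  hsi_cube(arr, wl, kind = kind)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # join brace-wrapped values onto one logical line
  txt <- gsub("\\{([^}]*)\\}", "\\{\\1\\}", txt)
  out <- list()
  # multi-line brace values
  m <- gregexpr("([a-zA-Z ]+)=\\s*\\{([^}]*)\\}", txt)
  for (piece in regmatches(txt, m)[[1]]) {
    key <- trimws(tolower(sub("=.*", "", piece)))
    val <- sub(".*\\{", "", piece)
    val <- gsub("\\}", "", val)
    out[[key]] <- gsub("\n", " ", val)
  }
  # simple key = value lines
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line) || grepl("\\{", line)) next
    key <- trimws(tolower(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(key) && is.null(out[[key]])) out[[key]] <- val
  }
  out
}

#' Reflectance calibration from white and dark references
#'
#' Converts raw counts to relative reflectance by the standard two-point
#' model `I = (I0 - D) / (W - D)`, applied per pixel and band. Reference
#' frames may be full images (rows x cols), per-column vectors (the
#' line-scan convention: one value per sample column, recycled down the
#' lines), or scalars. Pixels whose white-dark difference falls below
#' `eps = 1e-6 * max(W)` are set to reflectance 0 and counted in the
#' `n_degenerate` attribute; output is clipped to `[0, clip_hi]` with the
#' number of clipped values recorded in `n_clipped`.
#'
#' @param raw an [hsi_cube()] of kind `"raw"` (any numeric cube accepted).
#' @param white,dark reference frames; white must exceed dark.
#' @param clip_hi upper reflectance clip (default 1.5; specular highlights
#'   can exceed 1).
#' @return an [hsi_cube()] of kind `"reflectance"` with attributes
#'   `n_degenerate` and `n_clipped`.
#' @export
#' @examples
#' cube <- hsi_cube(array(50, c(2, 2, 3)), c(500, 600, 700), "raw")
#' r <- calibrate_reflectance(cube, white = 90, dark = 10)
#' r[1, 1, 1] # (50 - 10) / (90 - 10) = 0.5
calibrate_reflectance <- function(raw, white, dark, clip_hi = 1.5) {
  d <- dim(raw)
  wl <- wavelengths(raw)
  if (all(white == 0)) stop("white reference frame is all zero", call. = FALSE)
  W <- broadcast_frame(white, d[1], d[2], "white")
  D <- broadcast_frame(dark, d[1], d[2], "dark")
  wd <- W - D
  eps <- 1e-6 * max(W)
  degenerate <- wd <= eps
  wd[degenerate] <- 1 # placeholder; result overwritten below
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    plane <- (raw[, , k] - D) / wd
    plane[degenerate] <- 0
    out[, , k] <- plane
  }
  n_clipped <- sum(out > clip_hi | out < 0)
  out[out > clip_hi] <- clip_hi
  out[out < 0] <- 0
  res <- hsi_cube(out, wl, kind = "reflectance")
  attr(res, "n_degenerate") <- sum(degenerate) * d[3]
  attr(res, "n_clipped") <- n_clipped
  if (any(degenerate)) {
    warning(sum(degenerate), " pixel(s) with white - dark <= eps set to 0",
            call. = FALSE)
  }
  res
}

broadcast_frame <- function(x, rows, cols, what) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(rows, cols))) {
      stop(what, " frame is ", nrow(x), "x", ncol(x),
           " but the cube is ", rows, "x", cols, call. = FALSE)
    }
    return(x)
  }
  if (length(x) == 1L) return(matrix(x, rows, cols))
  if (length(x) == cols) return(matrix(x, rows, cols, byrow = TRUE))
  stop(what, " frame must be a matrix, a per-column vector, or a scalar",
       call. = FALSE)
}

#' Restrict a cube to a wavelength window
#'
#' Keeps the bands with `lo <= wavelength <= hi` and updates the axis.
#' The 400-1000 nm tails of VNIR captures carry little signal; trimming to
#' 450-850 nm before spectral modelling is the usual first step.
#'
#' @param cube an [hsi_cube()].
#' @param lo,hi window bounds in nm.
#' @return the trimmed [hsi_cube()].
#' @export
trim_bands <- function(cube, lo = 450, hi = 850) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  wl <- wavelengths(cube)
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) {
    stop("no bands inside [", lo, ", ", hi, "] nm", call. = FALSE)
  }
  hsi_cube(unclass(cube)[, , keep, drop = FALSE], wl[keep],
           kind = attr(cube, "kind"))
}

#' @rdname trim_bands
#' @param x numeric matrix (samples x bands) or vector of band values.
#' @param wavelength axis matching the columns of `x`.
#' @return `trim_spectra()`: list with `x` and `wavelength` trimmed.
#' @export
trim_spectra <- function(x, wavelength, lo = 450, hi = 850) {
  keep <- wavelength >= lo & wavelength <= hi
  if (!any(keep)) stop("no bands inside [", lo, ", ", hi, "] nm", call. = FALSE)
  if (is.matrix(x)) list(x = x[, keep, drop = FALSE], wavelength = wavelength[keep])
  else list(x = x[keep], wavelength = wavelength[keep])
}
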