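# File interfaces: hyperspectral cubes (native RDS container and ENVI
# .hdr/.dat BSQ export), spectra/summary/curve CSVs, peak-set and interval
# JSON, and PNG/TIFF/JPEG images through EBImage.

#' Write a hyperspectral cube
#'
#' `format = "rds"` is the native lossless container (array + grid +
#' provenance). `format = "envi"` writes a standard ENVI pair: a text header
#' (`.hdr`) with band count and wavelengths and a band-sequential (BSQ)
#' 4-byte little-endian float data file (`.dat`).
#'
#' @param cube A [hyper_cube()].
#' @param path Output path; for ENVI, the `.hdr`/`.dat` pair shares this stem.
#' @param format `"rds"` or `"envi"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("rds", "envi")) {
  format <- match.arg(format)
  stopifnot(inherits(cube, "hyper_cube"))
  if (format == "rds") {
    saveRDS(cube, path)
    return(invisible(path))
  }
  stem <- sub("\\.(hdr|dat)$", "", path)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(format(cube$grid$values, trim = TRUE), collapse = ", "),
           "}"))
  writeLines(hdr, paste0(stem, ".hdr"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: band-sequential, each band row-major by line
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(cube$data[, , b])), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a hyperspectral cube written by [write_cube()]
#'
#' @param path `.rds` path, or the `.hdr`/`.dat` stem of an ENVI pair.
#' @param format `"rds"` or `"envi"`.
#' @param grid Optional expected [wl_grid()]; a mismatch is an error.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path, format = c("rds", "envi"), grid = NULL) {
  format <- match.arg(format)
  if (format == "rds") {
    cube <- readRDS(path)
    if (!inherits(cube, "hyper_cube")) stop("file does not contain a cube")
  } else {
    stem <- sub("\\.(hdr|dat)$", "", path)
    hdr <- readLines(paste0(stem, ".hdr"))
    getv <- function(key) {
      ln <- grep(sprintf("^%s = ", key), hdr, value = TRUE)
      if (length(ln) != 1) stop(sprintf("ENVI header missing '%s'", key))
      sub(sprintf("^%s = ", key), "", ln)
    }
    samples <- as.integer(getv("samples"))
    lines <- as.integer(getv("lines"))
    bands <- as.integer(getv("bands"))
    wl_line <- sub(".*wavelength = \\{", "", paste(hdr, collapse = " "))
    wl <- as.numeric(strsplit(sub("\\}.*", "", wl_line), ",")[[1]])
    if (length(wl) != bands) stop("ENVI header wavelength count mismatch")
    con <- file(paste0(stem, ".dat"), "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = samples * lines * bands, size = 4,
                    endian = "little")
    if (length(vals) < samples * lines * bands)
      stop("truncated ENVI data file")
    a <- array(NA_real_, c(lines, samples, bands))
    for (b in seq_len(bands)) {
      block <- vals[((b - 1) * samples * lines + 1):(b * samples * lines)]
      a[, , b] <- matrix(block, lines, samples, byrow = TRUE)
    }
    step <- if (bands > 1) wl[2] - wl[1] else 1
    cube <- hyper_cube(a, wl_grid(wl[1], wl[bands], step))
  }
  if (!is.null(grid)) stop_if_grid_mismatch(cube$grid, grid, "cube and grid")
  cube
}

#' Write / read a class spectral summary as CSV
#'
#' Columns `wavelength_nm,mean,std,n`.
#' @param summary A `class_spectrum_summary`.
#' @param path CSV path.
#' @return `path` invisibly / a data frame.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(data.frame(wavelength_nm = summary$grid$values,
                              mean = summary$mean, std = summary$std,
                              n = summary$n),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an SNR-difference curve as CSV (`wavelength_nm,snr_difference`)
#' @param curve An `snr_curve`.
#' @param path CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(wavelength_nm = curve$grid$values,
                              snr_difference = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a wide checker-spectra CSV (wavelength column + 24 patch columns)
#' @param path CSV with first column `wavelength_nm` and 24 value columns.
#' @return List with `grid` and 24 x B `spectra`.
#' @export
read_checker_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != 25) stop("expected wavelength_nm plus 24 patch columns")
  w <- df[[1]]
  step <- unique(round(diff(w), 9))
  if (length(step) != 1) stop("wavelengths must be uniformly spaced")
  list(grid = wl_grid(w[1], w[length(w)], step),
       spectra = t(as.matrix(df[, -1])))
}

#' Write peak set / band interval as JSON
#' @param x A `peak_set` or [band_interval()].
#' @param path JSON path.
#' @export
write_selection_json <- function(x, path) {
  obj <- if (inherits(x, "peak_set")) {
    list(wavelengths_nm = x$wavelengths_nm, values = x$values)
  } else {
    list(low_nm = x$low_nm, high_nm = x$high_nm,
         threshold_value = x$threshold_value, crossing_nm = x$crossing_nm)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write an image (PNG, TIFF or JPEG; 8- or 16-bit)
#'
#' @param path Image path; format from the extension.
#' @return H x W (x C) array in `[0,1]`.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores x (column) first; transpose into row-major H x W (x C)
  if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
}

#' @rdname read_image
#' @param image H x W (x C) array in `[0,1]`.
#' @export
write_image <- function(image, path) {
  a <- if (length(dim(image)) == 2) t(image) else aperm(image, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = if (length(dim(a)) == 3)
    "Color" else "Grayscale"), path)
  invisible(path)
}

#' Read box annotations from CSV (`image_id,cx,cy,w,h`)
#' @param path CSV path.
#' @return Named list of [bounding_box()].
#' @export
read_boxes_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(seq_len(nrow(df)), function(i)
    bounding_box(df$cx[i], df$cy[i], df$w[i], df$h[i]))
  names(out) <- df$image_id
  out
}
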