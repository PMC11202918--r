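#' Wavelength grid
#'
#' A uniformly spaced wavelength axis shared by spectra, hyperspectral cubes
#' and SNR-difference curves. The default covers the visible display range
#' 380--780 nm at 1 nm, i.e. 401 bands.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Increment (nm); `(stop_nm - start_nm)` must be a multiple.
#' @return An object of class `wl_grid` with fields `start_nm`, `stop_nm`,
#'   `step_nm` and `values` (the ordered wavelengths).
#' @examples
#' g <- wl_grid()
#' length(g$values)  # 401
#' @export
wl_grid <- function(start_nm = 380, stop_nm = 780, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be positive")
  if (stop_nm <= start_nm) stop("stop_nm must exceed start_nm")
  n <- (stop_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-8)
    stop("stop_nm - start_nm must be a multiple of step_nm")
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         values = seq(start_nm, stop_nm, by = step_nm)),
    class = "wl_grid")
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d bands)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$values)))
  invisible(x)
}

n_bands <- function(grid) length(grid$values)

grids_equal <- function(a, b) {
  isTRUE(all.equal(a$values, b$values, tolerance = 1e-9))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grids_equal(a, b))
    stop(sprintf("wavelength grid mismatch between %s", what))
  invisible(TRUE)
}

#' Wavelength band interval
#'
#' A contiguous wavelength range, optionally annotated with the
#' SNR-difference threshold and interpolated crossing wavelength that
#' produced it (see [select_band_interval()]).
#'
#' @param low_nm,high_nm Interval endpoints (nm), `low_nm < high_nm`.
#' @param threshold_value SNR-difference threshold used to derive the
#'   interval, or `NA`.
#' @param crossing_nm Interpolated threshold-crossing wavelength, or `NA`.
#' @return An object of class `band_interval`.
#' @export
band_interval <- function(low_nm, high_nm, threshold_value = NA_real_,
                          crossing_nm = NA_real_) {
  if (!(is.numeric(low_nm) && is.numeric(high_nm)) || low_nm >= high_nm)
    stop("band_interval requires low_nm < high_nm")
  structure(
    list(low_nm = low_nm, high_nm = high_nm,
         threshold_value = threshold_value, crossing_nm = crossing_nm),
    class = "band_interval")
}

#' @export
print.band_interval <- function(x, ...) {
  cat(sprintf("<band_interval> %g-%g nm", x$low_nm, x$high_nm))
  if (!is.na(x$threshold_value))
    cat(sprintf(" (threshold %.4g, crossing %.2f nm)",
                x$threshold_value, x$crossing_nm))
  cat("\n")
  invisible(x)
}

# indices of grid wavelengths falling inside [low, high] (inclusive)
interval_indices <- function(grid, interval) {
  if (interval$low_nm > grid$stop_nm || interval$high_nm < grid$start_nm)
    stop("band interval lies outside the wavelength grid")
  idx <- which(grid$values >= interval$low_nm - 1e-9 &
               grid$values <= interval$high_nm + 1e-9)
  if (length(idx) == 0) stop("band interval contains no grid wavelengths")
  idx
}
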