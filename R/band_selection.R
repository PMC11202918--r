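# Spectral band selection: per-class spectral summaries over ROI pixels, the
# per-wavelength SNR-difference statistic, its peak structure, and the
# threshold-crossing rule that yields the selected wavelength interval.

#' Per-class spectral summary over ROI pixels
#'
#' For each image, the mean reflectance spectrum over its masked pixels is
#' computed; the summary is the across-image mean and sample (ddof = 1)
#' standard deviation per wavelength. Variability is therefore measured
#' across subjects, not across pixels.
#'
#' @param cubes List of [hyper_cube()] on a common grid (at least 2).
#' @param masks List of logical H x W matrices, aligned with `cubes`.
#' @param class_label `"glaucoma"` or `"normal"` (free-form allowed).
#' @param roi_kind `"retinal_rim"` or `"optic_disc"`.
#' @return Object of class `class_spectrum_summary` with fields `mean`,
#'   `std`, `n`, `per_image` (n x B matrix), `class_label`, `roi_kind`, `grid`.
#' @export
summarize_class_spectra <- function(cubes, masks, class_label,
                                    roi_kind = c("retinal_rim", "optic_disc")) {
  roi_kind <- match.arg(roi_kind)
  if (length(cubes) < 2) stop("at least 2 images are required")
  if (length(masks) != length(cubes)) stop("one mask per cube is required")
  grid <- cubes[[1]]$grid
  per_image <- t(vapply(seq_along(cubes), function(i) {
    cb <- cubes[[i]]
    stop_if_grid_mismatch(cb$grid, grid, "cubes")
    m <- masks[[i]]
    d <- dim(cb$data)
    if (!is.logical(m) || !all(dim(m) == d[1:2]))
      stop(sprintf("mask %d does not align with its cube", i))
    if (!any(m)) stop(sprintf("empty ROI mask for image %d", i))
    spectra <- matrix(cb$data, d[1] * d[2], d[3])
    colMeans(spectra[as.vector(m), , drop = FALSE])
  }, numeric(n_bands(grid))))
  structure(list(
    class_label = class_label, roi_kind = roi_kind,
    mean = colMeans(per_image), std = apply(per_image, 2, stats::sd),
    n = nrow(per_image), per_image = per_image, grid = grid),
    class = "class_spectrum_summary")
}

#' @export
print.class_spectrum_summary <- function(x, ...) {
  cat(sprintf("<class_spectrum_summary> %s / %s, n = %d images, %d bands\n",
              x$class_label, x$roi_kind, x$n, n_bands(x$grid)))
  invisible(x)
}

#' SNR-difference curve between two class summaries
#'
#' At each wavelength the signal-to-noise ratio of a class is its mean
#' reflectance divided by its standard deviation; the statistic is the
#' absolute difference of the two class SNRs. Zero standard deviations are
#' replaced by `eps` so noise-free inputs remain defined.
#'
#' @param s1,s2 [summarize_class_spectra()] results on a shared grid.
#' @param eps Standard-deviation floor (default 1e-8).
#' @return Object of class `snr_curve` with fields `grid` and `values`
#'   (non-negative, finite).
#' @export
snr_difference <- function(s1, s2, eps = 1e-8) {
  stop_if_grid_mismatch(s1$grid, s2$grid, "summaries")
  sd1 <- ifelse(s1$std <= 0, eps, s1$std)
  sd2 <- ifelse(s2$std <= 0, eps, s2$std)
  structure(list(grid = s1$grid,
                 values = abs(s1$mean / sd1 - s2$mean / sd2)),
            class = "snr_curve")
}

#' Peaks of an SNR-difference curve
#'
#' An interior index is a peak when its value strictly exceeds both
#' neighbors. A grid endpoint is a peak when it strictly exceeds its single
#' neighbor. A plateau (run of equal values) whose flanks are both strictly
#' lower - an endpoint counting as a lower flank for a run that touches it
#' while the other flank drops - is reported at its leftmost index. A
#' constant curve has no peaks.
#'
#' @param curve An `snr_curve` (at least 2 bands).
#' @return Object of class `peak_set`: data frame columns `wavelength_nm`,
#'   `value`, sorted by wavelength.
#' @export
find_peaks <- function(curve) {
  v <- curve$values
  B <- length(v)
  if (B < 2) stop("a curve needs at least 2 points")
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nr <- length(r$values)
  keep <- logical(nr)
  for (k in seq_len(nr)) {
    left_ok  <- if (k == 1) TRUE else r$values[k - 1] < r$values[k]
    right_ok <- if (k == nr) TRUE else r$values[k + 1] < r$values[k]
    # a run covering the whole curve (constant curve) is not a peak
    keep[k] <- left_ok && right_ok && nr > 1
  }
  idx <- as.integer(starts[keep])
  structure(list(
    wavelengths_nm = curve$grid$values[idx],
    values = v[idx],
    indices = idx,
    grid = curve$grid),
    class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s)\n", length(x$indices)))
  if (length(x$indices))
    print(data.frame(wavelength_nm = x$wavelengths_nm, value = x$values),
          row.names = FALSE)
  invisible(x)
}

#' Select the classification band interval from the SNR-difference curve
#'
#' The threshold is the value of the rank-`reference_rank` peak (by value,
#' default the second-highest). The interval's lower edge is the largest
#' wavelength at which the curve crosses the threshold from below (linear
#' interpolation between grid points) such that the curve stays at or above
#' the threshold from there to the grid maximum; it is reported rounded down
#' to the grid step. The upper edge is pinned to the grid maximum.
#'
#' @param curve An `snr_curve`.
#' @param peaks A `peak_set` for `curve`; computed if missing.
#' @param reference_rank Which peak (1 = highest) supplies the threshold.
#' @return A [band_interval()] carrying `threshold_value` and `crossing_nm`.
#' @export
select_band_interval <- function(curve, peaks = NULL, reference_rank = 2) {
  if (is.null(peaks)) peaks <- find_peaks(curve)
  if (length(peaks$values) < max(2, reference_rank))
    stop(sprintf("need at least %d peaks, found %d",
                 max(2, reference_rank), length(peaks$values)))
  T <- sort(peaks$values, decreasing = TRUE)[reference_rank]
  v <- curve$values
  w <- curve$grid$values
  B <- length(v)
  below <- which(v < T)
  if (length(below) == 0) {
    return(band_interval(curve$grid$start_nm, curve$grid$stop_nm,
                         threshold_value = T,
                         crossing_nm = curve$grid$start_nm))
  }
  k <- max(below)
  if (k == B)
    stop("no qualifying terminal region: curve ends below the threshold")
  crossing <- w[k] + (w[k + 1] - w[k]) * (T - v[k]) / (v[k + 1] - v[k])
  step <- curve$grid$step_nm
  low <- curve$grid$start_nm +
    floor((crossing - curve$grid$start_nm) / step) * step
  low <- min(low, curve$grid$stop_nm - step)   # keep at least one full step
  band_interval(low, curve$grid$stop_nm, threshold_value = T,
                crossing_nm = crossing)
}

#' Reference SNR-difference peak table
#'
#' The five-peak reference configuration used for comparison intervals:
#' peaks at 380, 440, 485, 521 and 680 nm with SNR-difference values 0.405,
#' 0.074, 0.158, 0.162 and 0.720. Under the default rank-2 rule the 380 nm
#' peak supplies the threshold (0.405) and the top peak (0.720) lies at
#' 680 nm, inside the selected 610-780 nm range.
#'
#' @return Data frame with columns `wavelength_nm` and `value`.
#' @export
reference_peak_table <- function() {
  data.frame(wavelength_nm = c(380, 440, 485, 521, 680),
             value = c(0.405, 0.074, 0.158, 0.162, 0.720))
}

#' Default comparison intervals for per-band classification
#'
#' Consecutive-peak bracketing of the reference peak table plus the selected
#' long-wavelength range: 380-440, 440-485, 485-521, 521-680 and 610-780 nm.
#'
#' @return Named list of [band_interval()].
#' @export
comparison_intervals <- function() {
  list(`380-440` = band_interval(380, 440),
       `440-485` = band_interval(440, 485),
       `485-521` = band_interval(485, 521),
       `521-680` = band_interval(521, 680),
       `610-780` = band_interval(610, 780))
}

#' 2-D diagnostic embedding of per-image mean spectra
#'
#' Exact (quadratic-cost) t-distributed stochastic neighbour embedding of the
#' N x B matrix of per-image mean spectra, for visual inspection of class
#' overlap. Deterministic for a fixed seed; diagnostic only.
#'
#' @param spectra N x B matrix (N >= 5), finite.
#' @param labels Optional length-N labels, attached to the result.
#' @param seed RNG seed.
#' @param perplexity Neighbourhood size; default `min(30, (N-1)/3)`.
#' @param n_iter Gradient-descent iterations (default 400).
#' @return N x 2 matrix of coordinates with attribute `"labels"`.
#' @export
embed_spectra_2d <- function(spectra, labels = NULL, seed = 1,
                             perplexity = NULL, n_iter = 400) {
  X <- as.matrix(spectra)
  if (nrow(X) < 5) stop("at least 5 spectra are required")
  if (!all(is.finite(X))) stop("spectra must be finite")
  if (is.null(perplexity)) perplexity <- min(30, (nrow(X) - 1) / 3)
  perplexity <- max(1, min(perplexity, (nrow(X) - 1) / 3))
  Y <- tsne_exact(X, perplexity = perplexity, seed = seed, n_iter = n_iter)
  attr(Y, "labels") <- labels
  Y
}
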