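# RGB -> reflectance-spectrum calibration against a 24-patch color checker:
# a PCA reflectance basis fitted to the patch spectra plus a ridge-regularized
# polynomial regression from linearized, white-balanced, chromatically
# adapted camera RGB to basis coefficients.

#' Color-checker reference
#'
#' Pairs the 24 measured patch reflectance spectra with the patch RGB values
#' observed by the camera, on a common wavelength grid.
#'
#' @param patch_spectra 24 x B matrix of reflectances in `[0,1]`.
#' @param patch_rgb 24 x 3 matrix of camera RGB in `[0,1]` (display-encoded).
#' @param grid A [wl_grid()] with B wavelengths.
#' @param illuminant Optional length-B relative spectral power of the capture
#'   light source (stored; used only for color rendering).
#' @return Object of class `color_checker`.
#' @export
color_checker_ref <- function(patch_spectra, patch_rgb, grid,
                              illuminant = NULL) {
  patch_spectra <- as.matrix(patch_spectra)
  patch_rgb <- as.matrix(patch_rgb)
  if (nrow(patch_spectra) != 24 || nrow(patch_rgb) != 24)
    stop("a color checker has exactly 24 patches")
  if (ncol(patch_spectra) != n_bands(grid))
    stop("patch spectra are not sampled on the supplied wavelength grid")
  if (ncol(patch_rgb) != 3) stop("patch_rgb must be 24 x 3")
  if (!all(is.finite(patch_rgb)) || any(patch_rgb < 0) || any(patch_rgb > 1))
    stop("patch RGB values must be finite and in [0,1]")
  if (any(patch_spectra < -1e-9) || any(patch_spectra > 1 + 1e-9))
    stop("patch reflectances must lie in [0,1]")
  if (!is.null(illuminant) && length(illuminant) != n_bands(grid))
    stop("illuminant must be sampled on the same grid")
  structure(list(patch_spectra = patch_spectra, patch_rgb = patch_rgb,
                 grid = grid, illuminant = illuminant),
            class = "color_checker")
}

#' Hyperspectral reflectance cube
#'
#' @param data H x W x B array of reflectances, clipped to `[0,1]`.
#' @param grid A [wl_grid()] with B wavelengths.
#' @param provenance Optional list (source image id, model id, ...).
#' @return Object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, grid, provenance = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != n_bands(grid))
    stop("third dimension of data must match the number of grid bands")
  if (anyNA(data)) stop("cube data must not contain NA")
  data <- pmin(pmax(data, 0), 1)
  structure(list(data = data, grid = grid, provenance = provenance),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}

#' Mean patch RGB from a photographed checker
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param patch_layout 24 x 4 matrix (or data frame) of rectangles
#'   `x0, y0, x1, y1` in pixel coordinates (x = column, y = row, inclusive).
#' @return 24 x 3 matrix of per-patch mean RGB.
#' @export
extract_checker_rgb <- function(image, patch_layout) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  layout <- as.matrix(patch_layout)
  if (nrow(layout) != 24 || ncol(layout) != 4)
    stop("patch_layout must describe 24 rectangles (x0, y0, x1, y1)")
  H <- dim(image)[1]; W <- dim(image)[2]
  if (any(layout[, 1] < 1) || any(layout[, 2] < 1) ||
      any(layout[, 3] > W) || any(layout[, 4] > H) ||
      any(layout[, 3] < layout[, 1]) || any(layout[, 4] < layout[, 2]))
    stop("patch rectangle out of image bounds")
  # pairwise overlap check
  for (i in seq_len(23)) for (j in seq(i + 1, 24)) {
    if (layout[i, 1] <= layout[j, 3] && layout[j, 1] <= layout[i, 3] &&
        layout[i, 2] <= layout[j, 4] && layout[j, 2] <= layout[i, 4])
      stop(sprintf("patch rectangles %d and %d overlap", i, j))
  }
  out <- matrix(NA_real_, 24, 3)
  for (p in seq_len(24)) {
    rows <- layout[p, 2]:layout[p, 4]
    cols <- layout[p, 1]:layout[p, 3]
    out[p, ] <- apply(image[rows, cols, , drop = FALSE], 3, mean)
  }
  colnames(out) <- c("r", "g", "b")
  out
}

# monomial expansion of linear RGB up to total degree `degree`
poly_features <- function(rgb, degree) {
  stopifnot(is.matrix(rgb), ncol(rgb) == 3, degree >= 1)
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  cols <- list(`1` = rep(1, nrow(rgb)))
  for (d in seq_len(degree)) {
    for (i in d:0) for (j in (d - i):0) {
      k <- d - i - j
      cols[[sprintf("r%dg%db%d", i, j, k)]] <- r^i * g^j * b^k
    }
  }
  do.call(cbind, cols)
}

# Shared preprocessing: display decode -> per-channel gains -> Bradford
# adaptation of the implied XYZ to the target white, back to linear RGB.
preprocess_rgb <- function(rgb, gains, source_white, target_white) {
  lin <- srgb_decode(rgb)
  lin <- sweep(lin, 2, gains, `*`)
  if (!isTRUE(all.equal(source_white, target_white))) {
    xyz <- lin_rgb_to_xyz(lin)
    xyz <- bradford_adapt(xyz, source_white, target_white)
    lin <- xyz_to_lin_rgb(xyz)
  }
  lin
}

#' Fit the RGB-to-spectrum calibration transform
#'
#' Builds a K-component principal-component basis of the mean-centered patch
#' spectra and a ridge-regularized least-squares map from polynomially
#' expanded linear RGB to basis coefficients. The patch RGB values are first
#' display-decoded, white-balanced by gray-world gains computed over the 24
#' patches (a checker averages to neutral), and Bradford-adapted to D65.
#'
#' @param reference A [color_checker_ref()].
#' @param degree Polynomial expansion degree of linear RGB (default 2).
#' @param n_components Number of principal components K (default 6, at most 24).
#' @param ridge Ridge penalty (default 1e-4). `0` requires a well-conditioned
#'   feature matrix and otherwise errors advising a larger ridge.
#' @param white_balance Apply gray-world gains over the patch set (default TRUE).
#' @return Object of class `calib_model` with the basis, mean spectrum,
#'   coefficient map, recorded whites/gains, and training residual RMSE.
#' @export
fit_spectral_transform <- function(reference, degree = 2, n_components = 6,
                                   ridge = 1e-4, white_balance = TRUE) {
  stopifnot(inherits(reference, "color_checker"))
  if (n_components < 1 || n_components > 24)
    stop("n_components must lie in 1..24")
  S <- reference$patch_spectra                 # 24 x B
  lin0 <- srgb_decode(reference$patch_rgb)
  gains <- if (white_balance) {
    cm <- colMeans(lin0)
    if (any(cm <= 0)) stop("degenerate checker RGB: zero channel mean")
    mean(cm) / cm
  } else c(1, 1, 1)
  source_white <- white_point("D65")           # balanced RGB treated as sRGB/D65
  target_white <- white_point("D65")
  rgb_lin <- preprocess_rgb(reference$patch_rgb, gains, source_white,
                            target_white)

  mean_spectrum <- colMeans(S)
  Sc <- sweep(S, 2, mean_spectrum)
  sv <- svd(Sc)
  K <- min(n_components, sum(sv$d > 1e-12 * sv$d[1]))
  basis <- sv$v[, seq_len(K), drop = FALSE]    # B x K
  scores <- Sc %*% basis                       # 24 x K

  FT <- poly_features(rgb_lin, degree)         # 24 x P
  # standardize features (intercept excluded) so the ridge penalty acts on
  # comparable scales; the standardization is stored and reapplied at
  # prediction time
  f_center <- colMeans(FT); f_center[1] <- 0
  f_scale <- apply(FT, 2, stats::sd); f_scale[f_scale < 1e-12] <- 1
  FS <- sweep(sweep(FT, 2, f_center), 2, f_scale, `/`)
  G <- crossprod(FS)
  if (ridge <= 0) {
    if (rcond(G) < 1e-12)
      stop("feature matrix is rank deficient; use a larger ridge penalty")
    coeff_map <- solve(G, crossprod(FS, scores))
  } else {
    coeff_map <- solve(G + ridge * diag(ncol(FS)), crossprod(FS, scores))
  }

  fitted <- sweep(FS %*% coeff_map %*% t(basis), 2, mean_spectrum, `+`)
  rmse <- sqrt(rowMeans((fitted - S)^2))
  structure(list(
    basis = basis, mean_spectrum = mean_spectrum, coeff_map = coeff_map,
    feature_degree = degree, n_components = K, ridge = ridge,
    f_center = f_center, f_scale = f_scale,
    gains = gains, source_white = source_white, target_white = target_white,
    grid = reference$grid, illuminant = reference$illuminant,
    train_rmse = rmse), class = "calib_model")
}

#' @export
print.calib_model <- function(x, ...) {
  cat(sprintf(
    "<calib_model> K=%d components, degree-%d features, ridge %g\n  training patch RMSE: mean %.2e, max %.2e\n",
    x$n_components, x$feature_degree, x$ridge,
    mean(x$train_rmse), max(x$train_rmse)))
  invisible(x)
}

#' Convert an RGB image to a hyperspectral reflectance cube
#'
#' Applies the fitted calibration: pixels are display-decoded, scaled by the
#' model's recorded white-balance gains, Bradford-adapted with the model's
#' recorded whites, polynomially expanded and mapped through the coefficient
#' matrix onto the reflectance basis. Pixel-wise and deterministic; values
#' are clipped to `[0,1]` and the clip count recorded in the provenance.
#'
#' @param image H x W x 3 array in `[0,1]` (display-encoded RGB).
#' @param model A `calib_model` from [fit_spectral_transform()].
#' @param image_id Optional provenance tag.
#' @return A [hyper_cube()] on the model's wavelength grid.
#' @export
apply_spectral_transform <- function(image, model, image_id = NULL) {
  stopifnot(inherits(model, "calib_model"),
            is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  rgb <- matrix(image, H * W, 3)
  lin <- preprocess_rgb(rgb, model$gains, model$source_white,
                        model$target_white)
  FT <- poly_features(lin, model$feature_degree)
  FT <- sweep(sweep(FT, 2, model$f_center), 2, model$f_scale, `/`)
  spectra <- FT %*% model$coeff_map %*% t(model$basis)
  spectra <- sweep(spectra, 2, model$mean_spectrum, `+`)
  n_clipped <- sum(spectra < 0 | spectra > 1)
  spectra <- pmin(pmax(spectra, 0), 1)
  hyper_cube(array(spectra, c(H, W, n_bands(model$grid))), model$grid,
             provenance = list(image_id = image_id, model = "calib_model",
                               n_clipped = n_clipped))
}

#' Reconstruct a band-limited image from a cube
#'
#' `mode = "mean"` averages reflectance over the interval per pixel.
#' `mode = "color"` integrates the spectrum restricted to the interval
#' against the CIE color-matching functions and the illuminant (equal-energy
#' if none is stored or supplied), converts to display sRGB and clips to
#' `[0,1]`.
#'
#' @param cube A [hyper_cube()].
#' @param interval A [band_interval()] within the cube grid.
#' @param mode `"mean"` or `"color"`.
#' @param illuminant Optional length-B spectral power; defaults to the
#'   illuminant recorded in the cube provenance, else equal energy.
#' @return H x W matrix (`mean`) or H x W x 3 array (`color`).
#' @export
reconstruct_band_image <- function(cube, interval, mode = c("mean", "color"),
                                   illuminant = NULL) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(interval, "band_interval"))
  mode <- match.arg(mode)
  idx <- interval_indices(cube$grid, interval)
  d <- dim(cube$data)
  spectra <- matrix(cube$data, d[1] * d[2], d[3])
  if (mode == "mean") {
    matrix(rowMeans(spectra[, idx, drop = FALSE]), d[1], d[2])
  } else {
    if (is.null(illuminant)) illuminant <- cube$provenance$illuminant
    xyz <- spectra_to_xyz(spectra, cube$grid, idx, illuminant)
    rgb <- srgb_encode(pmin(pmax(xyz_to_lin_rgb(xyz), 0), 1))
    array(pmin(pmax(rgb, 0), 1), c(d[1], d[2], 3))
  }
}
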