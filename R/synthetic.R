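# Synthetic calibration fixtures and two-class fundus phantoms.
#
# Phantom scenes are background + bright optic-disc ellipse + brighter cup +
# dark vessel arcs. All prototype reflectance spectra are combinations of a
# small shared Gaussian-bump basis, the same family the checker fixture
# spans, so that RGB -> spectrum conversion of phantom scenes is a
# within-model-class problem. The glaucoma class adds a reflectance offset to
# the disc/rim tissue inside a planted wavelength interval (the long-
# wavelength reflectance increase that accompanies nerve-fiber-layer
# thinning) and enlarges the cup-to-disc ratio. Across-image variability is
# an additive per-image haze offset along a near-flat in-span spectral shape;
# per-pixel spectral noise is white Gaussian.

#' Shared Gaussian-bump spectral basis
#'
#' @param grid A [wl_grid()].
#' @param n_basis Number of bumps (default 3), centers spread over
#'   440-690 nm, width half the center spacing.
#' @return B x n_basis matrix, each column peak-normalized.
#' @export
spectral_basis <- function(grid, n_basis = 3) {
  stopifnot(n_basis >= 1, n_basis <= 24)
  centers <- if (n_basis == 1) 565 else seq(440, 690, length.out = n_basis)
  sigma <- if (n_basis == 1) 100 else 0.5 * diff(centers)[1]
  sapply(centers, function(m) exp(-0.5 * ((grid$values - m) / sigma)^2))
}

#' Camera forward model
#'
#' Three non-negative spectral response curves and an illuminant; responses
#' are normalized so a perfect white (reflectance 1) maps to RGB (1,1,1).
#'
#' @param grid A [wl_grid()].
#' @param sensitivities Optional 3 x B response matrix (rows R, G, B);
#'   default Gaussian responses centered at 610, 540 and 455 nm.
#' @param illuminant Optional length-B spectral power (default flat).
#' @param gamma Display-encode rendered RGB with the sRGB curve (default TRUE).
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(grid, sensitivities = NULL, illuminant = NULL,
                         gamma = TRUE) {
  B <- n_bands(grid)
  if (is.null(sensitivities)) {
    centers <- c(610, 540, 455); widths <- c(38, 33, 28)
    sensitivities <- t(sapply(1:3, function(k)
      exp(-0.5 * ((grid$values - centers[k]) / widths[k])^2)))
  }
  sensitivities <- as.matrix(sensitivities)
  stopifnot(nrow(sensitivities) == 3, ncol(sensitivities) == B)
  if (any(sensitivities < 0)) stop("sensitivities must be non-negative")
  if (is.null(illuminant)) illuminant <- rep(1, B)
  stopifnot(length(illuminant) == B, all(illuminant >= 0))
  eff <- sweep(sensitivities, 2, illuminant, `*`)
  sums <- rowSums(eff)
  if (any(sums <= 0)) stop("each channel needs a nonzero response integral")
  structure(list(grid = grid, sensitivities = sensitivities,
                 illuminant = illuminant, gamma = gamma,
                 eff_norm = eff / sums), class = "camera_model")
}

#' Render reflectance spectra to camera RGB
#'
#' @param spectra N x B matrix of reflectances.
#' @param camera A [camera_model()].
#' @return N x 3 RGB in `[0,1]` (display-encoded if the camera has gamma).
#' @export
render_rgb <- function(spectra, camera) {
  rgb <- pmin(pmax(spectra %*% t(camera$eff_norm), 0), 1)
  if (camera$gamma) rgb <- srgb_encode(rgb)
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

#' Synthetic 24-patch color-checker fixture
#'
#' Smooth random reflectance spectra spanned by `n_basis` Gaussian bumps,
#' imaged through the camera forward model.
#'
#' @param camera A [camera_model()].
#' @param n_basis Spectral degrees of freedom of the patch set (default 3).
#' @param seed RNG seed.
#' @return A [color_checker_ref()].
#' @export
make_checker_fixture <- function(camera, n_basis = 3, seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  basis <- spectral_basis(camera$grid, n_basis)
  coeff <- matrix(stats::runif(24 * n_basis, 0.05, 1), 24, n_basis)
  spectra <- coeff %*% t(basis)
  spectra <- spectra * (0.95 / max(spectra))
  rgb <- render_rgb(spectra, camera)
  color_checker_ref(spectra, rgb, camera$grid, illuminant = camera$illuminant)
}

#' Phantom generation parameters
#'
#' Defaults define the reference simulation conditions: 1000 x 1000 scenes on
#' a 380-780 nm grid at 5 nm, disc radius 10-15% of the image, cup-to-disc
#' ratio 0.25-0.45 (normal) vs 0.55-0.80 (glaucoma), a planted 610-780 nm
#' reflectance offset of 0.1 on disc/rim tissue of the glaucoma class,
#' per-pixel spectral noise sd 0.02, and per-image haze offsets of sd 0.02.
#'
#' @param image_size Scene side length in pixels.
#' @param grid Simulation wavelength grid.
#' @param disc_center_range,disc_radius_range Uniform sampling ranges
#'   (fractions of the image).
#' @param aspect_range Disc ellipse y/x radius ratio range.
#' @param cup_ratio_range Named list of cup-to-disc ratio ranges per class.
#' @param planted_interval [band_interval()] carrying the class effect.
#' @param effect_size Reflectance offset inside the planted interval.
#' @param edge_nm Smoothstep width of the planted interval's spectral edges.
#' @param noise_sd Per-pixel Gaussian noise sd (marginal, per band).
#' @param noise_corr_nm Spectral correlation length of the pixel noise;
#'   converted cubes have spectrally smooth errors, so phantom noise is
#'   smooth in wavelength too.
#' @param haze_sd Sd of the per-image additive haze amplitude.
#' @param n_vessels Number of vessel arcs.
#' @param camera A [camera_model()] on `grid` (default constructed).
#' @return Object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 1000,
                           grid = wl_grid(380, 780, 5),
                           disc_center_range = c(0.38, 0.62),
                           disc_radius_range = c(0.10, 0.15),
                           aspect_range = c(0.85, 1.15),
                           cup_ratio_range = list(normal = c(0.25, 0.45),
                                                  glaucoma = c(0.55, 0.80)),
                           planted_interval = band_interval(610, 780),
                           effect_size = 0.1, edge_nm = 15,
                           noise_sd = 0.02, noise_corr_nm = 40,
                           haze_sd = 0.02, n_vessels = 3, camera = NULL) {
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (planted_interval$low_nm < grid$start_nm ||
      planted_interval$high_nm > grid$stop_nm)
    stop("planted interval must lie within the grid")
  if (is.null(camera)) camera <- camera_model(grid)
  stop_if_grid_mismatch(camera$grid, grid, "camera and phantom grids")
  basis <- spectral_basis(grid, 3)
  base_coeff <- list(
    background = c(0.30, 0.18, 0.60) * 0.11,
    disc       = c(0.70, 0.25, 0.85) * 0.165,
    cup        = c(0.70, 0.25, 0.85) * 0.165 * 1.3,
    vessel     = c(0.08, 0.05, 0.45) * 0.08)
  base_spectra <- lapply(base_coeff, function(cf) as.vector(basis %*% cf))
  # per-image haze variability is weighted toward short wavelengths
  # (scatter-like); expressed in the spectral basis so it stays within the
  # model class of the calibration
  haze_raw <- as.vector(basis %*% c(1.0, 0.55, 0.30))
  # spectral smoothing kernel for pixel noise (rows L2-normalized so the
  # marginal per-band noise sd equals noise_sd exactly)
  K <- exp(-0.5 * (outer(grid$values, grid$values, `-`) / noise_corr_nm)^2)
  K <- K / sqrt(rowSums(K^2))
  structure(list(
    image_size = image_size, grid = grid,
    disc_center_range = disc_center_range,
    disc_radius_range = disc_radius_range, aspect_range = aspect_range,
    cup_ratio_range = cup_ratio_range,
    planted_interval = planted_interval, effect_size = effect_size,
    edge_nm = edge_nm, noise_sd = noise_sd, noise_corr_nm = noise_corr_nm,
    noise_kernel = K, haze_sd = haze_sd,
    n_vessels = n_vessels, camera = camera,
    base_spectra = base_spectra,
    haze_shape = haze_raw / mean(haze_raw)), class = "phantom_params")
}

# smooth 0/1 profile of the planted interval over the grid
planted_profile <- function(params) {
  w <- params$grid$values
  lo <- params$planted_interval$low_nm
  hi <- params$planted_interval$high_nm
  e <- params$edge_nm
  sstep <- function(u) { u <- pmin(pmax(u, 0), 1); u * u * (3 - 2 * u) }
  up <- sstep((w - lo) / e)
  down <- if (hi >= params$grid$stop_nm - 1e-9) 1 else sstep((hi - w) / e)
  up * down
}

sample_phantom_geometry <- function(params, class_label) {
  ru <- function(r) stats::runif(1, r[1], r[2])
  cupr <- params$cup_ratio_range[[class_label]]
  if (is.null(cupr)) stop(sprintf("no cup ratio range for class '%s'",
                                  class_label))
  list(cx = ru(params$disc_center_range), cy = ru(params$disc_center_range),
       r = ru(params$disc_radius_range), aspect = ru(params$aspect_range),
       cup_ratio = ru(cupr),
       vessel_angles = stats::runif(params$n_vessels, 0, 2 * pi),
       vessel_curv = stats::runif(params$n_vessels, -0.8, 0.8),
       haze = stats::rnorm(1, 0, params$haze_sd))
}

#' Generate one fundus phantom
#'
#' @param params A [phantom_params()].
#' @param class_label `"glaucoma"` or `"normal"`.
#' @param seed RNG seed (geometry, haze and pixel noise).
#' @param geometry Optional geometry list (as produced internally) to pin
#'   the scene layout, e.g. for matched-pair comparisons.
#' @return List with `cube` ([hyper_cube()]), `rgb` (H x W x 3), `box`
#'   (true [bounding_box()] tight on the disc), `label`, `masks` (logical
#'   `disc`, `cup`, `rim`), and `geometry`.
#' @export
make_fundus_phantom <- function(params, class_label = c("normal", "glaucoma"),
                                seed = 1, geometry = NULL) {
  class_label <- match.arg(class_label)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  if (is.null(geometry)) geometry <- sample_phantom_geometry(params, class_label)
  n <- params$image_size
  B <- n_bands(params$grid)
  cxp <- geometry$cx * n; cyp <- geometry$cy * n
  rx <- geometry$r * n; ry <- rx * geometry$aspect
  if (cxp - rx < 1 || cxp + rx > n || cyp - ry < 1 || cyp + ry > n)
    stop("disc lies outside the image bounds")
  X <- matrix(seq_len(n), n, n, byrow = TRUE)   # column index
  Y <- matrix(seq_len(n), n, n)                 # row index
  d2 <- ((X - cxp) / rx)^2 + ((Y - cyp) / ry)^2
  disc <- d2 <= 1
  cup <- d2 <= geometry$cup_ratio^2
  vessel <- matrix(FALSE, n, n)
  thick <- max(1L, as.integer(round(n / 150)))
  for (v in seq_len(params$n_vessels)) {
    th0 <- geometry$vessel_angles[v]; cv <- geometry$vessel_curv[v]
    tt <- seq(0, 0.45 * n, length.out = 200)
    th <- th0 + cv * tt / n * 2
    px <- round(cxp + (rx + tt) * cos(th))
    py <- round(cyp + (ry + tt) * sin(th))
    for (dx in -thick:thick) for (dy in -thick:thick) {
      ok <- px + dx >= 1 & px + dx <= n & py + dy >= 1 & py + dy <= n
      vessel[cbind(py[ok] + dy, px[ok] + dx)] <- TRUE
    }
  }
  vessel <- vessel & !disc
  lab <- matrix(1L, n, n)                       # 1 bg, 2 disc, 3 cup, 4 vessel
  lab[disc] <- 2L; lab[cup] <- 3L; lab[vessel] <- 4L
  proto <- rbind(params$base_spectra$background, params$base_spectra$disc,
                 params$base_spectra$cup, params$base_spectra$vessel)
  if (class_label == "glaucoma" && params$effect_size > 0) {
    prof <- params$effect_size * planted_profile(params)
    proto[2, ] <- proto[2, ] + prof
    proto[3, ] <- proto[3, ] + prof
  }
  spectra <- proto[as.vector(lab), , drop = FALSE]
  spectra <- spectra + rep(geometry$haze * params$haze_shape, each = n * n)
  if (params$noise_sd > 0)
    spectra <- spectra + params$noise_sd *
      (matrix(stats::rnorm(length(spectra)), nrow(spectra), B) %*%
         t(params$noise_kernel))
  cube <- hyper_cube(array(spectra, c(n, n, B)), params$grid,
                     provenance = list(image_id = sprintf("phantom_%s_%d",
                                                          class_label, seed),
                                       illuminant = params$camera$illuminant))
  rgb_mat <- render_rgb(matrix(cube$data, n * n, B), params$camera)
  rgb <- array(rgb_mat, c(n, n, 3))
  box <- bounding_box(cx = geometry$cx, cy = geometry$cy,
                      w = 2 * rx / n, h = 2 * ry / n)
  list(cube = cube, rgb = rgb, box = box, label = class_label,
       masks = list(disc = disc, cup = cup, rim = disc & !cup),
       geometry = geometry)
}

#' Generate a two-class phantom dataset
#'
#' Per-image seeds are derived from the master seed by a fixed counter
#' scheme, so extending the dataset never reshuffles earlier images.
#'
#' @param n_per_class Images per class (at least 5).
#' @param params A [phantom_params()].
#' @param seed Master seed.
#' @param manifest_path Optional path to write the manifest CSV
#'   (`image_id,label,cx,cy,w,h,seed`).
#' @return List with `phantoms` (list of [make_fundus_phantom()] results),
#'   `labels`, `manifest` (data frame), `params`.
#' @export
make_phantom_dataset <- function(n_per_class, params = phantom_params(),
                                 seed = 1, manifest_path = NULL) {
  if (n_per_class < 5) stop("n_per_class must be at least 5")
  labels <- rep(c("glaucoma", "normal"), each = n_per_class)
  phantoms <- vector("list", length(labels))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    s <- derive_seed(seed, i)
    phantoms[[i]] <- make_fundus_phantom(params, labels[i], seed = s)
    b <- phantoms[[i]]$box
    rows[[i]] <- data.frame(image_id = sprintf("phantom_%03d", i),
                            label = labels[i], cx = b$cx, cy = b$cy,
                            w = b$w, h = b$h, seed = s)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(manifest_path))
    utils::write.csv(manifest, manifest_path, row.names = FALSE)
  list(phantoms = phantoms, labels = labels, manifest = manifest,
       params = params)
}

# Analytic per-wavelength sd of the null (no effect) SNR-difference curve:
# dominated by sampling error of the across-image mean and sd at sample size
# n; used by null-behavior tests.
null_curve_sd <- function(params, n, roi = "disc") {
  mu <- params$base_spectra[[if (roi == "disc") "disc" else "disc"]]
  snr <- mu / (params$haze_sd * params$haze_shape)
  sqrt(2) * sqrt(snr^2 / (2 * (n - 1)) + 1 / n)
}
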