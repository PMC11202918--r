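test_that("checker fixtures are deterministic and follow the camera model", {
  grid <- test_grid()
  cam <- camera_model(grid)
  a <- make_checker_fixture(cam, n_basis = 3, seed = 5)
  b <- make_checker_fixture(cam, n_basis = 3, seed = 5)
  expect_identical(a$patch_spectra, b$patch_spectra)
  expect_identical(a$patch_rgb, b$patch_rgb)
  expect_false(identical(
    a$patch_spectra, make_checker_fixture(cam, 3, seed = 6)$patch_spectra))

  # flat sensitivities + white illuminant: RGB proportional to mean
  # reflectance (identical across channels, linear in the patch mean)
  flat <- camera_model(grid, sensitivities = matrix(1, 3, n_bands(grid)),
                       gamma = FALSE)
  ck <- make_checker_fixture(flat, n_basis = 3, seed = 2)
  expect_equal(ck$patch_rgb[, 1], rowMeans(ck$patch_spectra),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ck$patch_rgb[, 1], ck$patch_rgb[, 3], ignore_attr = TRUE)
})

test_that("phantoms are seeded, bounded and geometrically consistent", {
  params <- test_params()
  a <- make_fundus_phantom(params, "glaucoma", seed = 4)
  b <- make_fundus_phantom(params, "glaucoma", seed = 4)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$rgb, b$rgb)

  # box is tight on the disc mask
  m <- a$masks$disc
  rows <- range(which(apply(m, 1, any)))
  cols <- range(which(apply(m, 2, any)))
  n <- params$image_size
  expect_equal((rows[1] + rows[2]) / 2 / n, a$box$cy, tolerance = 0.03)
  expect_equal((cols[1] + cols[2]) / 2 / n, a$box$cx, tolerance = 0.03)
  expect_equal(diff(cols) / n, a$box$w, tolerance = 0.05)
  # cup inside disc, rim = disc minus cup
  expect_true(all(a$masks$disc[a$masks$cup]))
  expect_identical(a$masks$rim, a$masks$disc & !a$masks$cup)

  # disc outside bounds errors
  expect_error(make_fundus_phantom(
    test_params(disc_center_range = c(0.98, 0.99)), "normal", seed = 1),
    "outside")
})

test_that("a null effect with pinned geometry gives identical classes", {
  params <- test_params(effect_size = 0, noise_sd = 0)
  geom <- fundusHSI:::sample_phantom_geometry(params, "normal")
  a <- make_fundus_phantom(params, "normal", seed = 3, geometry = geom)
  b <- make_fundus_phantom(params, "glaucoma", seed = 3, geometry = geom)
  expect_identical(a$cube$data, b$cube$data)
})

test_that("the planted effect has the constructed arithmetic", {
  # noise-free: class-mean spectral gap inside the interval is exactly the
  # effect on disc tissue, and doubles when the effect doubles
  params1 <- test_params(effect_size = 0.1, noise_sd = 0, haze_sd = 0)
  params2 <- test_params(effect_size = 0.2, noise_sd = 0, haze_sd = 0)
  geom <- fundusHSI:::sample_phantom_geometry(params1, "normal")
  inside <- which(params1$grid$values >= 630 & params1$grid$values <= 770)
  outside <- which(params1$grid$values < 600)
  gap_for <- function(params) {
    g <- make_fundus_phantom(params, "glaucoma", seed = 5, geometry = geom)
    n <- make_fundus_phantom(params, "normal", seed = 5, geometry = geom)
    rim_g <- apply(g$cube$data, 3, function(sl) mean(sl[g$masks$rim]))
    rim_n <- apply(n$cube$data, 3, function(sl) mean(sl[n$masks$rim]))
    rim_g - rim_n
  }
  gap1 <- gap_for(params1)
  expect_equal(mean(gap1[inside]), 0.1, tolerance = 1e-9)
  expect_equal(max(abs(gap1[outside])), 0, tolerance = 1e-12)
  gap2 <- gap_for(params2)
  expect_equal(gap2[inside], 2 * gap1[inside], tolerance = 1e-9)

  # with noise: inside gap ~ effect within 3 standard errors, outside ~ 0
  params <- test_params(effect_size = 0.1)
  g <- make_fundus_phantom(params, "glaucoma", seed = 6, geometry = geom)
  n <- make_fundus_phantom(params, "normal", seed = 7, geometry = geom)
  rim_px <- sum(g$masks$rim)
  se <- sqrt(2) * sqrt(params$noise_sd^2 / rim_px + params$haze_sd^2)
  gap <- apply(g$cube$data, 3, function(sl) mean(sl[g$masks$rim])) -
    apply(n$cube$data, 3, function(sl) mean(sl[n$masks$rim]))
  expect_lt(abs(mean(gap[inside]) - 0.1), 3 * se)
  expect_lt(abs(mean(gap[outside])), 3 * se)
})

test_that("datasets have exact composition and reproducible manifests", {
  params <- test_params(image_size = 48)
  ds <- make_phantom_dataset(5, params, seed = 9)
  expect_length(ds$phantoms, 10)
  expect_equal(as.vector(table(ds$labels)), c(5, 5))
  ds2 <- make_phantom_dataset(5, params, seed = 9)
  expect_identical(ds$manifest, ds2$manifest)
  expect_error(make_phantom_dataset(4, params, seed = 1), "at least 5")
  # extending the dataset preserves earlier per-image seeds
  ds3 <- make_phantom_dataset(6, params, seed = 9)
  expect_identical(ds3$manifest$seed[1:5], ds$manifest$seed[1:5])
})

test_that("with no planted effect the SNR-difference curve stays at noise
           level", {
  params <- test_params(effect_size = 0, image_size = 48)
  n_img <- 10
  thresh <- 4 * max(fundusHSI:::null_curve_sd(params, n_img))
  ok <- 0; reps <- 20
  for (r in seq_len(reps)) {
    phs_g <- lapply(seq_len(n_img), function(i)
      make_fundus_phantom(params, "glaucoma",
                          seed = fundusHSI:::derive_seed(1000 + r, i)))
    phs_n <- lapply(seq_len(n_img), function(i)
      make_fundus_phantom(params, "normal",
                          seed = fundusHSI:::derive_seed(2000 + r, i)))
    s_g <- summarize_class_spectra(lapply(phs_g, `[[`, "cube"),
                                   lapply(phs_g, function(p) p$masks$disc),
                                   "glaucoma", "optic_disc")
    s_n <- summarize_class_spectra(lapply(phs_n, `[[`, "cube"),
                                   lapply(phs_n, function(p) p$masks$disc),
                                   "normal", "optic_disc")
    pk <- find_peaks(snr_difference(s_g, s_n))
    if (length(pk$values) == 0 || max(pk$values) <= thresh) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95)
})
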