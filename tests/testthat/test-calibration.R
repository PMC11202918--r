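test_that("extract_checker_rgb averages patches and validates the layout", {
  img <- array(0, c(40, 60, 3))
  layout <- matrix(NA_real_, 24, 4)
  cols <- matrix(runif(72), 24, 3)
  k <- 0
  for (r in 0:3) for (c in 0:5) {
    k <- k + 1
    x0 <- c * 10 + 1; y0 <- r * 10 + 1
    layout[k, ] <- c(x0, y0, x0 + 8, y0 + 8)
    for (ch in 1:3) img[y0:(y0 + 8), x0:(x0 + 8), ch] <- cols[k, ch]
  }
  expect_equal(unname(extract_checker_rgb(img, layout)), cols,
               tolerance = 1e-12)

  # noisy patches recover the mean within a CLT bound (3 sd / sqrt(n))
  set.seed(7)
  noisy <- img + array(rnorm(length(img), 0, 0.05), dim(img))
  got <- extract_checker_rgb(noisy, layout)
  n_px <- 81
  expect_true(all(abs(got - cols) < 3 * 0.05 / sqrt(n_px) + 1e-9))

  bad <- layout; bad[1, 3] <- 100
  expect_error(extract_checker_rgb(img, bad), "bounds")
  overlapping <- layout; overlapping[2, ] <- layout[1, ]
  expect_error(extract_checker_rgb(img, overlapping), "overlap")
})

test_that("calibration recovers spectra exactly within the model class", {
  grid <- test_grid(5)
  cam <- camera_model(grid)
  checker <- make_checker_fixture(cam, n_basis = 3, seed = 42)
  model <- fit_spectral_transform(checker)
  expect_lt(max(model$train_rmse), 1e-3)

  # nested models: K = 24 residual <= K = 6 residual; degree 2 <= degree 1
  m6 <- fit_spectral_transform(checker, n_components = 6)
  m24 <- fit_spectral_transform(checker, n_components = 24)
  expect_lte(mean(m24$train_rmse), mean(m6$train_rmse) + 1e-12)
  # nesting holds for the unpenalized fit (ridge shrinks the two models
  # differently)
  d1 <- fit_spectral_transform(checker, degree = 1, ridge = 1e-10)
  d2 <- fit_spectral_transform(checker, degree = 2, ridge = 1e-10)
  expect_lte(mean(d2$train_rmse), mean(d1$train_rmse) + 1e-9)
})

test_that("apply_spectral_transform is consistent, clipped and pixel-wise", {
  grid <- test_grid(5)
  cam <- camera_model(grid)
  checker <- make_checker_fixture(cam, n_basis = 3, seed = 1)
  model <- fit_spectral_transform(checker)

  # a pixel equal to a training patch RGB reproduces that patch's fitted
  # spectrum
  img <- array(rep(checker$patch_rgb[5, ], each = 1), c(1, 1, 3))
  cube <- apply_spectral_transform(img, model)
  expect_equal(as.vector(cube$data[1, 1, ]), checker$patch_spectra[5, ],
               tolerance = 2e-3)

  # black pixel stays within [0,1]
  black <- apply_spectral_transform(array(0, c(1, 1, 3)), model)
  expect_true(all(black$data >= 0 & black$data <= 1))

  # pixel-wise: permuting pixels commutes with the transform
  set.seed(3)
  img <- array(runif(5 * 4 * 3, 0.1, 0.9), c(5, 4, 3))
  cube <- apply_spectral_transform(img, model)
  perm <- sample(20)
  img_p <- array(apply(img, 3, function(ch) ch[perm]), c(5, 4, 3))
  cube_p <- apply_spectral_transform(img_p, model)
  expect_equal(matrix(cube_p$data, 20),
               matrix(cube$data, 20)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("phantom scenes convert back to their cubes within tolerance", {
  grid <- test_grid(5)
  cam <- camera_model(grid)
  checker <- make_checker_fixture(cam, n_basis = 3, seed = 11)
  model <- fit_spectral_transform(checker)
  params <- phantom_params(image_size = 48, grid = grid, noise_sd = 0.005,
                           camera = cam)
  ph <- make_fundus_phantom(params, "normal", seed = 5)
  cube <- apply_spectral_transform(ph$rgb, model)
  rmse <- sqrt(rowMeans(matrix((cube$data - ph$cube$data)^2, 48 * 48)))
  expect_lt(mean(rmse), 0.02)
})

test_that("band reconstruction obeys closed-form means and linearity", {
  grid <- test_grid(10)
  cube <- constant_cube(0.42, grid)
  full <- band_interval(grid$start_nm, grid$stop_nm)
  expect_equal(reconstruct_band_image(cube, full, "mean"),
               matrix(0.42, 8, 8), tolerance = 1e-12)

  # cube that is zero below 610: band mean over [610,780] equals full mean
  # scaled by the band-count ratio
  B <- n_bands(grid)
  idx <- which(grid$values >= 610)
  a <- array(0, c(4, 4, B))
  a[, , idx] <- 0.3
  cube <- hyper_cube(a, grid)
  m_band <- reconstruct_band_image(cube, band_interval(610, 780), "mean")
  m_full <- reconstruct_band_image(cube, full, "mean")
  expect_equal(m_band, m_full * B / length(idx), tolerance = 1e-12)

  # two disjoint intervals covering the grid combine linearly
  set.seed(1)
  a <- array(runif(4 * 4 * B), c(4, 4, B))
  cube <- hyper_cube(a, grid)
  i1 <- band_interval(380, 575); i2 <- band_interval(580, 780)
  n1 <- sum(grid$values <= 575)
  n2 <- B - n1
  m1 <- reconstruct_band_image(cube, i1, "mean")
  m2 <- reconstruct_band_image(cube, i2, "mean")
  expect_equal((m1 * n1 + m2 * n2) / B,
               reconstruct_band_image(cube, full, "mean"), tolerance = 1e-12)

  # color mode returns an RGB image in range; empty interval errors
  col <- reconstruct_band_image(cube, i2, "color")
  expect_equal(dim(col), c(4, 4, 3))
  expect_true(all(col >= 0 & col <= 1))
  expect_error(reconstruct_band_image(cube, band_interval(781, 800), "mean"),
               "outside")
})
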