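test_that("class spectral summaries aggregate per-image means", {
  grid <- test_grid()
  cubes <- list(constant_cube(0.3, grid), constant_cube(0.3, grid))
  masks <- replicate(2, matrix(TRUE, 8, 8), simplify = FALSE)
  s <- summarize_class_spectra(cubes, masks, "normal")
  expect_equal(s$mean, rep(0.3, n_bands(grid)), tolerance = 1e-12)
  expect_equal(s$std, rep(0, n_bands(grid)), tolerance = 1e-12)

  # hand computation: per-image means {0.2, 0.4} -> mean 0.3, sample sd
  cubes <- list(constant_cube(0.2, grid), constant_cube(0.4, grid))
  s <- summarize_class_spectra(cubes, masks, "normal")
  expect_equal(s$mean[1], 0.3, tolerance = 1e-12)
  expect_equal(s$std[1], sd(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(s$std[1], 0.1414214, tolerance = 1e-6)

  # permutation symmetry
  s_rev <- summarize_class_spectra(rev(cubes), masks, "normal")
  expect_equal(s$mean, s_rev$mean)
  expect_equal(s$std, s_rev$std)

  # empty mask names the offending image
  masks[[2]][] <- FALSE
  expect_error(summarize_class_spectra(cubes, masks, "normal"), "image 2")
  expect_error(summarize_class_spectra(cubes[1], masks[1], "normal"),
               "at least 2")
})

test_that("the SNR-difference statistic matches its definition", {
  grid <- wl_grid(380, 382, 1)
  m1 <- rbind(c(1.0, 1.0, 1.0), c(1.0, 1.0, 1.0))
  s1 <- summary_from_matrix(m1, grid)
  expect_equal(snr_difference(s1, s1)$values, rep(0, 3))

  # equal SNRs with unequal spectra cancel: 1.0/0.5 vs 0.8/0.4
  s1 <- list(grid = grid, mean = rep(1, 3), std = rep(0.5, 3))
  s2 <- list(grid = grid, mean = rep(0.8, 3), std = rep(0.4, 3))
  expect_equal(snr_difference(s1, s2)$values, rep(0, 3), tolerance = 1e-12)

  # direct evaluation: |1.0/0.5 - 1.0/0.4| = 0.5
  s2$mean <- rep(1, 3)
  expect_equal(snr_difference(s1, s2)$values, rep(0.5, 3), tolerance = 1e-12)

  # symmetry and scale invariance
  set.seed(1)
  a <- list(grid = grid, mean = runif(3), std = runif(3, 0.1, 1))
  b <- list(grid = grid, mean = runif(3), std = runif(3, 0.1, 1))
  expect_equal(snr_difference(a, b)$values, snr_difference(b, a)$values)
  a2 <- list(grid = grid, mean = 3.7 * a$mean, std = 3.7 * a$std)
  expect_equal(snr_difference(a, b)$values, snr_difference(a2, b)$values,
               tolerance = 1e-12)
})

test_that("peak detection matches the brute-force oracle", {
  expect_equal(find_peaks(curve_from_values(c(0, 1, 0)))$indices, 2L)

  # monotone decreasing curve: single endpoint peak at the first wavelength
  v <- seq(0.405, 0.1, length.out = 10)
  pk <- find_peaks(curve_from_values(v))
  expect_equal(pk$indices, 1L)
  expect_equal(pk$values, 0.405)

  # constant curve: no peaks, not an error
  expect_length(find_peaks(curve_from_values(rep(0.2, 5)))$indices, 0)

  # plateau maxima at the leftmost plateau index
  expect_equal(find_peaks(curve_from_values(c(0, 1, 1, 0)))$indices, 2L)

  # oracle equivalence on 1000 seeded random curves, including ties
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    v <- sample(0:5, n, replace = TRUE) / 5   # many ties/plateaus
    expect_identical(find_peaks(curve_from_values(v))$indices,
                     brute_force_peaks(v))
  }
})

test_that("band-interval selection follows the threshold-crossing rule", {
  # analytic piecewise-linear case: crossing at 588.55 nm
  grid <- wl_grid(380, 780, 1)
  w <- grid$values
  v <- approx(x = c(380, 500, 680, 780), y = c(0.405, 0.1, 0.72, 0.72),
              xout = w)$y
  curve <- curve_from_values(v, grid)
  sel <- select_band_interval(curve)
  expect_equal(sel$threshold_value, 0.405, tolerance = 1e-12)
  expect_equal(sel$crossing_nm, 500 + 180 * (0.405 - 0.1) / (0.72 - 0.1),
               tolerance = 0.01)
  expect_equal(sel$crossing_nm, 588.55, tolerance = 0.01)
  expect_equal(sel$low_nm, 588)
  expect_equal(sel$high_nm, 780)

  # terminal value below threshold: no qualifying region
  g2 <- wl_grid(380, 420, 10)
  v3 <- c(0, 1, 0, 0.5, 0.1)
  expect_error(select_band_interval(curve_from_values(v3, g2)),
               "no qualifying terminal region")

  # fewer than two peaks
  v4 <- c(0, 0.5, 1, 1.5, 2)
  expect_error(select_band_interval(curve_from_values(v4, g2)),
               "at least 2 peaks")
})

test_that("the reference peak table ranks as reported", {
  tab <- reference_peak_table()
  ord <- order(tab$value, decreasing = TRUE)
  expect_equal(tab$wavelength_nm[ord[1]], 680)
  expect_equal(tab$value[ord[1]], 0.720)
  expect_equal(tab$wavelength_nm[ord[2]], 380)
  expect_equal(tab$value[ord[2]], 0.405)
  # the rank-2 rule therefore thresholds at the 380 nm peak value
  expect_equal(sort(tab$value, decreasing = TRUE)[2], 0.405)
})

test_that("the 2-D embedding separates well-separated clusters", {
  set.seed(5)
  n <- 20; B <- 30
  X <- rbind(matrix(rnorm(n * B, 0, 0.05), n),
             matrix(rnorm(n * B, 1, 0.05), n))
  labels <- rep(c(1, 2), each = n)
  Y <- embed_spectra_2d(X, labels, seed = 3)
  sil <- cluster::silhouette(labels, dist(Y))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # determinism and minimum size
  Y2 <- embed_spectra_2d(X, labels, seed = 3)
  expect_identical(Y, Y2)
  expect_silent(embed_spectra_2d(X[1:5, ], seed = 1))
  expect_error(embed_spectra_2d(X[1:4, ], seed = 1), "at least 5")
  X[1, 1] <- NA
  expect_error(embed_spectra_2d(X, seed = 1), "finite")
})
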