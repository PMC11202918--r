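# Shared fixtures: a coarse wavelength grid, a default camera, and small
# phantom parameters sized for fast tests.

test_grid <- function(step = 10) wl_grid(380, 780, step)

test_camera <- function(grid = test_grid()) camera_model(grid)

test_params <- function(image_size = 64, step = 10, ...) {
  phantom_params(image_size = image_size, grid = test_grid(step), ...)
}

# an snr_curve from raw values on a grid
curve_from_values <- function(values, grid = NULL) {
  if (is.null(grid)) grid <- wl_grid(380, 380 + (length(values) - 1), 1)
  structure(list(grid = grid, values = values), class = "snr_curve")
}

# a class summary built directly from per-image mean spectra (n x B)
summary_from_matrix <- function(per_image, grid, label = "a",
                                roi_kind = "retinal_rim") {
  structure(list(class_label = label, roi_kind = roi_kind,
                 mean = colMeans(per_image),
                 std = apply(per_image, 2, stats::sd),
                 n = nrow(per_image), per_image = per_image, grid = grid),
            class = "class_spectrum_summary")
}

# independent brute-force peak finder used as the oracle: for every index,
# scan left and right past any equal-valued plateau and require strictly
# lower values (or the curve edge) on both sides; report plateau leftmost
# indices only.
brute_force_peaks <- function(v) {
  B <- length(v)
  out <- integer(0)
  for (i in seq_len(B)) {
    if (i > 1 && v[i - 1] == v[i]) next        # not a plateau's left end
    j <- i
    while (j < B && v[j + 1] == v[i]) j <- j + 1
    left_ok <- i == 1 || v[i - 1] < v[i]
    right_ok <- j == B || v[j + 1] < v[i]
    if (left_ok && right_ok && !(i == 1 && j == B)) out <- c(out, i)
  }
  out
}

# linearly separable two-class feature vectors for head-training checks
separable_features <- function(n_per_class = 50, D = 64, sd = 0.3,
                               seed = 11) {
  set.seed(seed)
  mu <- rep(c(0.5, -0.5), length.out = D)
  x <- lapply(seq_len(2 * n_per_class), function(i) {
    cl <- if (i <= n_per_class) 1 else -1
    cl * mu + rnorm(D, 0, sd)
  })
  list(x = x, labels = rep(c("glaucoma", "normal"), each = n_per_class))
}

# constant-color cube helper
constant_cube <- function(value, grid = test_grid(), n = 8) {
  hyper_cube(array(value, c(n, n, n_bands(grid))), grid)
}
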