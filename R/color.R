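# Color science: sRGB transfer curves, XYZ conversion, gray-world white
# balance, Bradford chromatic adaptation, and CIE 1931 color-matching
# functions (multi-lobe Gaussian fits) used for band-limited color rendering.

# sRGB (IEC 61966-2-1) electro-optical transfer, elementwise on [0,1].
srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

srgb_encode <- function(v) {
  v <- pmax(v, 0)
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

# sRGB primaries, D65 white
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)

#' Standard illuminant white points
#'
#' @param name `"D65"`, `"D50"` or `"E"` (equal energy).
#' @return XYZ triple with Y = 1.
#' @export
white_point <- function(name = c("D65", "D50", "E")) {
  name <- match.arg(name)
  switch(name,
    D65 = c(0.95047, 1.00000, 1.08883),
    D50 = c(0.96422, 1.00000, 0.82521),
    E   = c(1, 1, 1))
}

# Bradford cone-response matrix
.M_BRADFORD <- matrix(c(
   0.8951,  0.2664, -0.1614,
  -0.7502,  1.7135,  0.0367,
   0.0389, -0.0685,  1.0296), 3, 3, byrow = TRUE)
.M_BRADFORD_INV <- solve(.M_BRADFORD)

#' Gray-world white balance
#'
#' Estimates the scene illuminant as the per-channel mean of the image and
#' rescales each channel so all three channel means equal the mean of the
#' original channel means.
#'
#' @param image H x W x 3 array, values in `[0,1]`.
#' @param clip Clip the corrected image to `[0,1]` (default `TRUE`). Disable
#'   to verify the exact equal-means property.
#' @return Corrected image, same shape; attribute `"gains"` holds the three
#'   per-channel scale factors.
#' @export
gray_world_balance <- function(image, clip = TRUE) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  if (!all(is.finite(image))) stop("image contains non-finite values")
  ch_means <- apply(image, 3, mean)
  if (any(ch_means <= 0))
    stop("degenerate illuminant estimate: a channel mean is zero")
  gains <- mean(ch_means) / ch_means
  out <- sweep(image, 3, gains, `*`)
  if (clip) out <- pmin(pmax(out, 0), 1)
  attr(out, "gains") <- gains
  out
}

#' Bradford chromatic adaptation
#'
#' Linear von-Kries-style adaptation in the Bradford cone space: the
#' tristimulus value is mapped to cone responses, scaled by the ratio of the
#' target and source white cone responses, and mapped back. The source white
#' maps exactly onto the target white.
#'
#' @param tristimulus XYZ triple, or an N x 3 matrix of XYZ rows.
#' @param source_white,target_white XYZ white points with positive luminance.
#' @return Adapted XYZ, same shape as `tristimulus`.
#' @export
bradford_adapt <- function(tristimulus, source_white, target_white) {
  if (length(source_white) != 3 || length(target_white) != 3)
    stop("white points must be XYZ triples")
  if (source_white[2] <= 0 || target_white[2] <= 0)
    stop("white points must have positive luminance Y")
  g <- as.vector(.M_BRADFORD %*% target_white) /
       as.vector(.M_BRADFORD %*% source_white)
  M <- .M_BRADFORD_INV %*% diag(g) %*% .M_BRADFORD
  if (is.matrix(tristimulus)) {
    stopifnot(ncol(tristimulus) == 3)
    tristimulus %*% t(M)
  } else {
    as.vector(M %*% tristimulus)
  }
}

# linear sRGB <-> XYZ, on N x 3 matrices or length-3 vectors
lin_rgb_to_xyz <- function(rgb) {
  if (is.matrix(rgb)) rgb %*% t(.M_RGB2XYZ) else as.vector(.M_RGB2XYZ %*% rgb)
}

xyz_to_lin_rgb <- function(xyz) {
  if (is.matrix(xyz)) xyz %*% t(.M_XYZ2RGB) else as.vector(.M_XYZ2RGB %*% xyz)
}

# CIE 1931 2-degree color-matching functions via multi-lobe piecewise
# Gaussian fits (Wyman, Sloan & Shirley 2013). Adequate for display-oriented
# rendering of band-limited spectra.
.pw_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 color-matching functions
#'
#' @param wavelengths_nm Numeric vector of wavelengths (nm).
#' @return Matrix with columns `x`, `y`, `z`.
#' @export
cie_cmf <- function(wavelengths_nm) {
  w <- wavelengths_nm
  xb <- 1.056 * .pw_gauss(w, 599.8, 37.9, 31.0) +
        0.362 * .pw_gauss(w, 442.0, 16.0, 26.7) -
        0.065 * .pw_gauss(w, 501.1, 20.4, 26.2)
  yb <- 0.821 * .pw_gauss(w, 568.8, 46.9, 40.5) +
        0.286 * .pw_gauss(w, 530.9, 16.3, 31.1)
  zb <- 1.217 * .pw_gauss(w, 437.0, 11.8, 36.0) +
        0.681 * .pw_gauss(w, 459.0, 26.0, 13.8)
  cbind(x = xb, y = yb, z = zb)
}

# Integrate spectra (N x B, reflectance) against illuminant and CMFs over the
# band indices `idx`; normalized by the in-band white (a perfect reflector
# restricted to the band has Y = 1), so every band renders at display
# exposure.
spectra_to_xyz <- function(spectra, grid, idx = seq_len(n_bands(grid)),
                           illuminant = NULL) {
  B <- n_bands(grid)
  if (is.null(illuminant)) illuminant <- rep(1, B)
  stopifnot(length(illuminant) == B)
  cmf <- cie_cmf(grid$values)
  k <- 1 / sum(illuminant[idx] * cmf[idx, "y"])
  W <- cmf[idx, , drop = FALSE] * illuminant[idx]
  (spectra[, idx, drop = FALSE] %*% W) * k
}
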