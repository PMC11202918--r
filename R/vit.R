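# Reduced Vision Transformer feature extractor (forward only, frozen).
# Standard pre-LayerNorm encoder: patch embedding + class token + learned
# position embeddings, multi-head self-attention, GELU MLP blocks, final
# LayerNorm; the class-token state is the image feature.

vit_init <- function(cfg, n_patches, in_dim) {
  d <- cfg$d
  rn <- function(n, sd = 0.02) stats::rnorm(n, sd = sd)
  blocks <- lapply(seq_len(cfg$depth), function(l) list(
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wqkv = matrix(rn(d * 3 * d), d, 3 * d), bqkv = rep(0, 3 * d),
    Wo = matrix(rn(d * d), d, d), bo = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    W1 = matrix(rn(d * 4 * d), d, 4 * d), b1 = rep(0, 4 * d),
    W2 = matrix(rn(4 * d * d), 4 * d, d), b2 = rep(0, d)))
  list(
    Wp = matrix(rn(in_dim * d), in_dim, d), bp = rep(0, d),
    cls = rn(d),
    pos = matrix(rn((n_patches + 1) * d), n_patches + 1, d),
    blocks = blocks,
    lnf_g = rep(1, d), lnf_b = rep(0, d))
}

layer_norm <- function(X, g, b, eps = 1e-6) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  sweep(sweep(Xc / sqrt(v + eps), 2, g, `*`), 2, b, `+`)
}

gelu <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))

# split an H x W x 3 image into non-overlapping p x p patches, row-major
# over the patch grid; each row is the flattened patch (p*p*3).
image_to_patches <- function(img, p) {
  H <- dim(img)[1]; W <- dim(img)[2]
  gh <- H / p; gw <- W / p
  n <- gh * gw
  out <- matrix(NA_real_, n, p * p * 3)
  k <- 0
  for (gi in seq_len(gh)) for (gj in seq_len(gw)) {
    k <- k + 1
    out[k, ] <- as.vector(img[((gi - 1) * p + 1):(gi * p),
                              ((gj - 1) * p + 1):(gj * p), ])
  }
  out
}

vit_forward <- function(backbone, img) {
  cfg <- backbone$cfg
  w <- backbone$weights
  s <- backbone$input_size
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] != 3) stop("vit_tiny expects a 3-channel image")
  img <- resize_bilinear(img, s, s)
  img <- (img - 0.5) / 0.5                       # channel normalization
  P <- image_to_patches(img, cfg$patch)
  X <- sweep(P %*% w$Wp, 2, w$bp, `+`)
  X <- rbind(w$cls, X) + w$pos
  n <- nrow(X); d <- cfg$d; h <- cfg$heads; dh <- d / h
  for (blk in w$blocks) {
    Xn <- layer_norm(X, blk$ln1_g, blk$ln1_b)
    QKV <- sweep(Xn %*% blk$Wqkv, 2, blk$bqkv, `+`)
    att_out <- matrix(0, n, d)
    for (head in seq_len(h)) {
      cols <- ((head - 1) * dh + 1):(head * dh)
      Q <- QKV[, cols, drop = FALSE]
      K <- QKV[, d + cols, drop = FALSE]
      V <- QKV[, 2 * d + cols, drop = FALSE]
      A <- Q %*% t(K) / sqrt(dh)
      A <- A - apply(A, 1, max)
      A <- exp(A); A <- A / rowSums(A)
      att_out[, cols] <- A %*% V
    }
    X <- X + sweep(att_out %*% blk$Wo, 2, blk$bo, `+`)
    Xn <- layer_norm(X, blk$ln2_g, blk$ln2_b)
    X <- X + sweep(gelu(sweep(Xn %*% blk$W1, 2, blk$b1, `+`)) %*% blk$W2,
                   2, blk$b2, `+`)
  }
  Xf <- layer_norm(X, w$lnf_g, w$lnf_b)
  Xf[1, ]
}
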