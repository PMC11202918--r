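# Frozen feature-extraction backbones. Pretrained deep networks are not
# bundled; the registry provides reduced, randomly initialized backbones
# whose weights are generated deterministically from a seed and never
# updated by training (the freeze contract is bitwise). Only the dense heads
# on top of these features are trainable.

#' Registered backbone names
#' @return Character vector of backbone names accepted by
#'   [build_localizer()] and [build_vit_classifier()].
#' @export
registered_backbones <- function() c("cnn_tiny", "vit_tiny", "identity")

# bilinear resize of an H x W (x C) array to oh x ow
resize_bilinear <- function(img, oh, ow) {
  d <- dim(img)
  if (is.null(d)) stop("image must be a matrix or array")
  if (length(d) == 2) { img <- array(img, c(d, 1)); d <- dim(img) }
  H <- d[1]; W <- d[2]; C <- d[3]
  if (H == oh && W == ow) return(if (C == 1) img[, , 1] else img)
  rf <- pmin(pmax((seq_len(oh) - 0.5) * H / oh + 0.5, 1), H)
  cf <- pmin(pmax((seq_len(ow) - 0.5) * W / ow + 0.5, 1), W)
  r0 <- pmin(floor(rf), H - 1); c0 <- pmin(floor(cf), W - 1)
  wr <- rf - r0; wc <- cf - c0
  out <- array(NA_real_, c(oh, ow, C))
  for (ch in seq_len(C)) {
    M <- img[, , ch]
    out[, , ch] <-
      M[r0, c0]         * ((1 - wr) %o% (1 - wc)) +
      M[r0 + 1, c0]     * (wr %o% (1 - wc)) +
      M[r0, c0 + 1]     * ((1 - wr) %o% wc) +
      M[r0 + 1, c0 + 1] * (wr %o% wc)
  }
  if (C == 1) out[, , 1] else out
}

make_backbone <- function(name, seed = 1, input_size = NULL,
                          pool_grid = 4, feature_dim = NULL) {
  if (!name %in% registered_backbones())
    stop(sprintf("unknown backbone '%s'; registered backbones: %s",
                 name, paste(registered_backbones(), collapse = ", ")))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(derive_seed(seed, 7001))
  if (name == "cnn_tiny") {
    if (is.null(input_size)) input_size <- 96
    c_in <- 5                                  # RGB + 2 coordinate channels
    f1 <- 16; f2 <- 32
    w1 <- matrix(stats::rnorm(9 * c_in * f1, sd = sqrt(2 / (9 * c_in))),
                 9 * c_in, f1)
    b1 <- rep(0, f1)
    w2 <- matrix(stats::rnorm(9 * f1 * f2, sd = sqrt(2 / (9 * f1))),
                 9 * f1, f2)
    b2 <- rep(0, f2)
    list(name = name, input_size = input_size, pool_grid = pool_grid,
         weights = list(w1 = w1, b1 = b1, w2 = w2, b2 = b2),
         feature_dim = pool_grid^2 * f2)
  } else if (name == "vit_tiny") {
    if (is.null(input_size)) input_size <- 224
    cfg <- list(patch = 16, d = 192, depth = 4, heads = 3)
    np <- (input_size / cfg$patch)^2
    if (abs(np - round(np)) > 1e-9)
      stop("input size must be divisible by the patch size")
    list(name = name, input_size = input_size, cfg = cfg,
         weights = vit_init(cfg, n_patches = as.integer(round(np)),
                            in_dim = 3 * cfg$patch^2),
         feature_dim = cfg$d)
  } else {                                     # identity: features in = out
    if (is.null(feature_dim))
      stop("identity backbone requires feature_dim")
    list(name = name, input_size = NA_integer_, feature_dim = feature_dim)
  }
}

# Extract a feature vector from one image (or pass-through vector).
backbone_features <- function(backbone, x) {
  if (backbone$name == "identity") {
    v <- as.numeric(x)
    if (length(v) != backbone$feature_dim)
      stop("identity backbone: input length does not match feature_dim")
    return(v)
  }
  if (backbone$name == "cnn_tiny") {
    s <- backbone$input_size
    img <- x
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] != 3) stop("cnn_tiny expects a 3-channel image")
    img <- resize_bilinear(img, s, s)
    cx <- matrix(seq(-1, 1, length.out = s), s, s, byrow = TRUE)
    cy <- matrix(seq(-1, 1, length.out = s), s, s)
    inp <- array(c(img, cx, cy), c(s, s, 5))
    w <- backbone$weights
    h1 <- pmax(conv3x3(inp, w$w1, w$b1, stride = 2), 0)
    h2 <- pmax(conv3x3(h1, w$w2, w$b2, stride = 2), 0)
    return(avg_pool_grid(h2, backbone$pool_grid))
  }
  # vit_tiny
  vit_forward(backbone, x)
}

# Batch feature matrix from a list of images
backbone_feature_matrix <- function(backbone, images) {
  t(vapply(images, function(im) backbone_features(backbone, im),
           numeric(backbone$feature_dim)))
}

backbone_checksum <- function(backbone) {
  if (is.null(backbone$weights)) return(0)
  sum(vapply(backbone$weights, function(w) {
    if (is.list(w)) sum(vapply(w, function(u) sum(as.numeric(u)), numeric(1)))
    else sum(as.numeric(w))
  }, numeric(1)))
}
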