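# Minimal neural-network primitives: dense layers with ReLU and inverted
# dropout, softmax cross-entropy and mean-square-error losses, SGD with
# Nesterov momentum, and Adam. Backpropagation is only ever needed through
# the trainable heads; the frozen backbones are forward-only (backbones.R).

# independent sub-stream seeds derived from a master seed, exact in doubles
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 12345) %%
               2147483647)
}

# He-initialized MLP parameters. sizes = c(in, h1, ..., out)
mlp_init <- function(sizes, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  n <- length(sizes) - 1
  layers <- vector("list", n)
  for (l in seq_len(n)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                              sd = sqrt(2 / sizes[l])),
                 sizes[l], sizes[l + 1]),
      b = rep(0, sizes[l + 1]))
  }
  layers
}

mlp_n_params <- function(layers) {
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Forward pass. X: N x d. dropout: per-hidden-layer rates (after ReLU), or
# NULL. In training mode dropout masks are sampled from `rng_env$seed_counter`
# -derived seeds so runs are reproducible. Returns list(out, cache).
mlp_forward <- function(layers, X, dropout = NULL, training = FALSE,
                        drop_seed = NULL) {
  n <- length(layers)
  acts <- vector("list", n + 1)
  masks <- vector("list", n)
  acts[[1]] <- X
  for (l in seq_len(n)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    if (l < n) {
      Z <- pmax(Z, 0)
      rate <- if (!is.null(dropout) && l <= length(dropout)) dropout[l] else 0
      if (training && rate > 0) {
        set.seed(derive_seed(drop_seed, l))
        m <- matrix(stats::rbinom(length(Z), 1, 1 - rate), nrow(Z)) / (1 - rate)
        Z <- Z * m
        masks[[l]] <- m
      }
    }
    acts[[l + 1]] <- Z
  }
  list(out = acts[[n + 1]], acts = acts, masks = masks)
}

# Backward pass given dL/dout. Returns list of grads (dW, db).
mlp_backward <- function(layers, fwd, dout) {
  n <- length(layers)
  grads <- vector("list", n)
  delta <- dout
  for (l in rev(seq_len(n))) {
    A <- fwd$acts[[l]]
    grads[[l]] <- list(dW = crossprod(A, delta),
                      db = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(layers[[l]]$W)
      hidden <- fwd$acts[[l]]            # post-ReLU (and dropout) activation
      delta <- delta * (hidden > 0)
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
    }
  }
  grads
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# cross-entropy loss and gradient; y: integer class in 1..K
ce_loss_grad <- function(logits, y) {
  P <- softmax(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, grad = G / n, probs = P)
}

mse_loss_grad <- function(pred, target) {
  d <- pred - target
  list(loss = mean(d^2), grad = 2 * d / length(d))
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

sgd_init <- function(layers) {
  lapply(layers, function(l) list(vW = l$W * 0, vb = l$b * 0))
}

# SGD with (optionally Nesterov) momentum
sgd_step <- function(layers, grads, state, lr, momentum = 0.9,
                     nesterov = TRUE) {
  for (l in seq_along(layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$vW <- momentum * s$vW - lr * g$dW
    s$vb <- momentum * s$vb - lr * g$db
    if (nesterov) {
      layers[[l]]$W <- layers[[l]]$W + momentum * s$vW - lr * g$dW
      layers[[l]]$b <- layers[[l]]$b + momentum * s$vb - lr * g$db
    } else {
      layers[[l]]$W <- layers[[l]]$W + s$vW
      layers[[l]]$b <- layers[[l]]$b + s$vb
    }
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# im2col 3x3 stride-s convolution. x: H x W x C. w: (9*C) x F, b: length F.
conv3x3 <- function(x, w, b, stride = 2) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Ho <- floor((H - 3) / stride) + 1
  Wo <- floor((W - 3) / stride) + 1
  rows <- (seq_len(Ho) - 1) * stride + 1
  cols <- (seq_len(Wo) - 1) * stride + 1
  patch <- matrix(NA_real_, Ho * Wo, 9 * C)
  k <- 0
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    patch[, k] <- as.vector(x[rows + di, cols + dj, c])
  }
  out <- sweep(patch %*% w, 2, b, `+`)
  array(out, c(Ho, Wo, length(b)))
}

# average-pool feature maps to a g x g grid, then flatten (g = 1 is GAP)
avg_pool_grid <- function(x, g) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  rb <- floor(seq(0, H, length.out = g + 1))
  cb <- floor(seq(0, W, length.out = g + 1))
  out <- numeric(g * g * C)
  k <- 0
  for (c in seq_len(C)) for (j in seq_len(g)) for (i in seq_len(g)) {
    k <- k + 1
    out[k] <- mean(x[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1], c])
  }
  out
}
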