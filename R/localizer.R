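# Optic-disc localization: a frozen backbone followed by pooled features and
# a small dense head regressing a normalized bounding box (cx, cy, w, h)
# under mean-square-error loss with the Adam optimizer.

#' Normalized bounding box
#'
#' @param cx,cy Box center in `[0,1]`, relative to image width/height.
#' @param w,h Box width/height in `(0,1]`.
#' @return Object of class `bounding_box`.
#' @export
bounding_box <- function(cx, cy, w, h) {
  if (any(!is.finite(c(cx, cy, w, h)))) stop("box coordinates must be finite")
  if (cx < 0 || cx > 1 || cy < 0 || cy > 1) stop("cx, cy must lie in [0,1]")
  if (w <= 0 || w > 1 || h <= 0 || h > 1) stop("w, h must lie in (0,1]")
  structure(list(cx = cx, cy = cy, w = w, h = h), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> center (%.3f, %.3f), size %.3f x %.3f\n",
              x$cx, x$cy, x$w, x$h))
  invisible(x)
}

#' Intersection-over-union of two normalized boxes
#' @param a,b [bounding_box()] objects.
#' @return IoU in `[0,1]`.
#' @export
box_iou <- function(a, b) {
  ax <- c(a$cx - a$w / 2, a$cx + a$w / 2); ay <- c(a$cy - a$h / 2, a$cy + a$h / 2)
  bx <- c(b$cx - b$w / 2, b$cx + b$w / 2); by <- c(b$cy - b$h / 2, b$cy + b$h / 2)
  iw <- max(0, min(ax[2], bx[2]) - max(ax[1], bx[1]))
  ih <- max(0, min(ay[2], by[2]) - max(ay[1], by[1]))
  inter <- iw * ih
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Localizer configuration
#'
#' @param backbone_name Registered backbone (see [registered_backbones()]);
#'   default `"cnn_tiny"`, a reduced randomly initialized CNN.
#' @param freeze_backbone Keep backbone weights fixed (default `TRUE`; the
#'   only supported mode for the bundled backbones).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 3000 full-batch passes over the
#'   cached features; head-only training is cheap).
#' @param batch_size Minibatch size; `Inf` = full batch (default).
#' @param hidden Hidden width of the regression head (default 64).
#' @param input_size Backbone input resolution (default 96 for `cnn_tiny`).
#' @param pool_grid Average-pooling grid of the backbone output (default 4;
#'   1 reproduces exact global average pooling).
#' @param augment_flip Add horizontally flipped copies (with mirrored boxes)
#'   during training (default `FALSE`).
#' @param seed RNG seed controlling backbone weights, head init, shuffling.
#' @return Object of class `localizer_config`.
#' @export
localizer_config <- function(backbone_name = "cnn_tiny",
                             freeze_backbone = TRUE,
                             learning_rate = 1e-4, epochs = 3000,
                             batch_size = Inf, hidden = 64,
                             input_size = 96, pool_grid = 4,
                             augment_flip = FALSE, seed = 1) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (!isTRUE(freeze_backbone))
    stop("bundled backbones are frozen; freeze_backbone must be TRUE")
  structure(list(backbone_name = backbone_name,
                 freeze_backbone = freeze_backbone,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, hidden = hidden,
                 input_size = input_size, pool_grid = pool_grid,
                 augment_flip = augment_flip, seed = seed,
                 loss = "mse", optimizer = "adam"),
            class = "localizer_config")
}

#' Build the box-regression model
#'
#' Frozen backbone, pooled features, and a dense head
#' `Linear(hidden) -> ReLU -> Linear(4)` emitting normalized
#' `(cx, cy, w, h)`. Only the head is trainable.
#'
#' @param config A [localizer_config()].
#' @return Object of class `od_localizer`.
#' @export
build_localizer <- function(config = localizer_config()) {
  backbone <- make_backbone(config$backbone_name, seed = config$seed,
                            input_size = config$input_size,
                            pool_grid = config$pool_grid)
  head <- mlp_init(c(backbone$feature_dim, config$hidden, 4),
                   seed = derive_seed(config$seed, 11))
  structure(list(backbone = backbone, head = head, config = config,
                 history = NULL), class = "od_localizer")
}

#' Trainable-parameter count (head only; backbones are frozen)
#' @param model An `od_localizer` or `vit_classifier`.
#' @return Integer parameter count.
#' @export
n_trainable_params <- function(model) mlp_n_params(model$head)

localizer_prepare_xy <- function(model, images, boxes) {
  stopifnot(length(images) == length(boxes))
  Y <- t(vapply(boxes, function(b) {
    if (b$w <= 0 || b$h <= 0) stop("degenerate box: zero width or height")
    c(b$cx, b$cy, b$w, b$h)
  }, numeric(4)))
  X <- backbone_feature_matrix(model$backbone, images)
  list(X = X, Y = Y)
}

#' Train the box-regression head
#'
#' Backbone features are computed once (the backbone is frozen) and the head
#' is optimized with Adam on mean-square error over the normalized box
#' coordinates. With `augment_flip`, horizontally mirrored images (with
#' `cx -> 1 - cx`) are appended to the training set.
#'
#' @param model An `od_localizer`.
#' @param images List of H x W x 3 arrays in `[0,1]` (at least 8).
#' @param boxes List of [bounding_box()], aligned with `images`.
#' @param epochs,learning_rate Optional overrides of the model config.
#' @return The trained model; `model$history` is a data frame with per-epoch
#'   training loss.
#' @export
train_localizer <- function(model, images, boxes, epochs = NULL,
                            learning_rate = NULL) {
  cfg <- model$config
  if (length(images) < 8) stop("at least 8 labeled images are required")
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(learning_rate)) learning_rate <- cfg$learning_rate
  if (cfg$augment_flip) {
    flipped <- lapply(images, function(im) im[, dim(im)[2]:1, , drop = FALSE])
    fboxes <- lapply(boxes, function(b)
      bounding_box(1 - b$cx, b$cy, b$w, b$h))
    images <- c(images, flipped)
    boxes <- c(boxes, fboxes)
  }
  xy <- localizer_prepare_xy(model, images, boxes)
  n <- nrow(xy$X)
  bs <- min(cfg$batch_size, n)
  head <- model$head
  state <- adam_init(head)
  loss_hist <- numeric(epochs)
  t <- 0
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(cfg$seed, 100000 + ep))
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      fwd <- mlp_forward(head, xy$X[idx, , drop = FALSE])
      lg <- mse_loss_grad(fwd$out, xy$Y[idx, , drop = FALSE])
      grads <- mlp_backward(head, fwd, lg$grad)
      t <- t + 1
      upd <- adam_step(head, grads, state, learning_rate, t)
      head <- upd$layers; state <- upd$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    loss_hist[ep] <- ep_loss / nb
  }
  model$head <- head
  model$history <- data.frame(epoch = seq_len(epochs), loss = loss_hist)
  model
}

#' Predict the optic-disc bounding box for one image
#'
#' @param model A trained `od_localizer`.
#' @param image H x W x 3 array in `[0,1]`.
#' @return A [bounding_box()]; coordinates are clamped into their valid
#'   ranges.
#' @export
predict_box <- function(model, image) {
  f <- backbone_features(model$backbone, image)
  out <- mlp_forward(model$head, matrix(f, 1))$out[1, ]
  bounding_box(cx = min(max(out[1], 0), 1),
               cy = min(max(out[2], 0), 1),
               w = min(max(out[3], 1e-3), 1),
               h = min(max(out[4], 1e-3), 1))
}

# reflect an index vector into 1..n (half-sample-symmetric boundary)
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, p - j)
}

#' Crop a fixed-size ROI around a predicted box
#'
#' Extracts a `size` x `size` crop centered on the box center (pixel
#' coordinates); parts falling outside the image are filled by reflection
#' padding, so no artificial border is introduced.
#'
#' @param image H x W (x C) array.
#' @param box A [bounding_box()].
#' @param size Output side length in pixels (default 450; at most twice the
#'   smaller image dimension).
#' @return `size` x `size` (x C) array.
#' @export
crop_roi <- function(image, box, size = 450) {
  d <- dim(image)
  two_d <- length(d) == 2
  if (two_d) { image <- array(image, c(d, 1)); d <- dim(image) }
  H <- d[1]; W <- d[2]
  if (size > 2 * min(H, W))
    stop("crop size exceeds twice the image dimension")
  r0 <- round(box$cy * H - size / 2)
  c0 <- round(box$cx * W - size / 2)
  rows <- reflect_index(r0 + seq_len(size), H)
  cols <- reflect_index(c0 + seq_len(size), W)
  out <- image[rows, cols, , drop = FALSE]
  if (two_d) out[, , 1] else out
}
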