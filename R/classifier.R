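# Two-class ROI classification: frozen Vision Transformer features with a
# trainable dense head (512 -> 256 -> 2 with ReLU and dropout), cross-entropy
# loss, SGD with Nesterov momentum, and early stopping on validation loss.

#' Classifier configuration
#'
#' Defaults follow the transfer-learning recipe: 16-pixel patches on a
#' 224-pixel input, head widths 512 and 256 with dropout 0.25 and 0.50,
#' cross-entropy loss, SGD (learning rate 1e-4, momentum 0.9, Nesterov), at
#' most 25 epochs with early stopping (patience 3 epochs, minimum
#' improvement 0.03 in validation loss), and a stratified 80/10/10 split.
#'
#' @param backbone_name Registered backbone (default `"vit_tiny"`, a reduced
#'   frozen ViT; `"identity"` feeds precomputed feature vectors straight to
#'   the head; `"cnn_tiny"` gives a convolutional ablation backbone).
#' @param patch_size,input_size ViT patch and input sizes (16, 224).
#' @param head_dims Hidden widths of the head (512, 256).
#' @param dropout Dropout rates after each hidden layer (0.25, 0.50).
#' @param n_classes Number of classes (2).
#' @param learning_rate,momentum,nesterov SGD settings (1e-4, 0.9, TRUE).
#' @param max_epochs,early_stop_patience,early_stop_min_delta Training
#'   schedule (25, 3, 0.03).
#' @param split Train/validation/test proportions, summing to 1.
#' @param batch_size Minibatch size (default 16).
#' @param feature_scale Multiplier applied to backbone features before the
#'   head (default 10): keeps head gradients effective at the small
#'   configured learning rate.
#' @param feature_dim Input dimension for the `"identity"` backbone.
#' @param seed RNG seed.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(backbone_name = "vit_tiny", patch_size = 16,
                              input_size = 224, head_dims = c(512, 256),
                              dropout = c(0.25, 0.50), n_classes = 2,
                              learning_rate = 1e-4, momentum = 0.9,
                              nesterov = TRUE, max_epochs = 25,
                              early_stop_patience = 3,
                              early_stop_min_delta = 0.03,
                              split = c(0.8, 0.1, 0.1), batch_size = 16,
                              feature_scale = 10, feature_dim = NULL,
                              seed = 1) {
  if (abs(sum(split) - 1) > 1e-8) stop("split must sum to 1")
  if (any(head_dims <= 0)) stop("head dims must be positive")
  if (input_size %% patch_size != 0)
    stop("input size must be divisible by the patch size")
  structure(as.list(environment()), class = "classifier_config")
}

#' Stratified train/validation/test preparation of ROI images
#'
#' Splits by label at the configured proportions with the configured seed,
#' resizes every ROI to the classifier input size by bilinear interpolation,
#' and records the channel normalization applied downstream.
#'
#' @param rois List of ROI images (H x W x 3 arrays in `[0,1]`), at least 10
#'   per class.
#' @param labels Character/factor vector aligned with `rois` (2 classes).
#' @param config A [classifier_config()].
#' @return List with elements `train`, `val`, `test` (each `x`: list of
#'   resized images, `y`: integer class 1/2, `labels`), `classes`, and
#'   `normalization`.
#' @export
prepare_dataset <- function(rois, labels, config = classifier_config()) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly two classes are required")
  tab <- table(labels)
  if (any(tab < 10)) stop("at least 10 images per class are required")
  idx_split <- list(train = integer(0), val = integer(0), test = integer(0))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(derive_seed(config$seed, 501))
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_val <- round(config$split[2] * n)
    n_test <- round(config$split[3] * n)
    n_train <- n - n_val - n_test
    if (n_train < 1 || n_val < 1 || n_test < 1)
      stop(sprintf("split leaves an empty subset for class '%s'", cl))
    idx_split$train <- c(idx_split$train, idx[seq_len(n_train)])
    idx_split$val <- c(idx_split$val, idx[n_train + seq_len(n_val)])
    idx_split$test <- c(idx_split$test, idx[n_train + n_val + seq_len(n_test)])
  }
  s <- config$input_size
  prep <- if (config$backbone_name == "identity") identity else function(im) {
    im <- if (length(dim(im)) == 2) array(rep(im, 3), c(dim(im), 3)) else im
    resize_bilinear(im, s, s)
  }
  make_split <- function(idx) list(
    x = lapply(rois[idx], prep),
    y = match(labels[idx], classes),
    labels = labels[idx])
  out <- lapply(idx_split, make_split)
  out$classes <- classes
  out$normalization <- list(mean = 0.5, sd = 0.5)
  out
}

#' Build the frozen-ViT classifier
#'
#' Frozen feature extractor plus the trainable head
#' `Linear(512) -> ReLU -> Dropout(0.25) -> Linear(256) -> ReLU ->
#' Dropout(0.50) -> Linear(2)`.
#'
#' @param config A [classifier_config()].
#' @return Object of class `vit_classifier`.
#' @export
build_vit_classifier <- function(config = classifier_config()) {
  backbone <- make_backbone(config$backbone_name, seed = config$seed,
                            input_size = if (config$backbone_name == "vit_tiny")
                              config$input_size else NULL,
                            pool_grid = 1, feature_dim = config$feature_dim)
  head <- mlp_init(c(backbone$feature_dim, config$head_dims,
                     config$n_classes),
                   seed = derive_seed(config$seed, 13))
  structure(list(backbone = backbone, head = head, config = config,
                 history = NULL), class = "vit_classifier")
}

# Backbone features, standardized per dimension with statistics recorded at
# training time, then scaled; standardization puts all feature directions on
# a common footing so the head trains effectively at the configured
# learning rate.
classifier_features <- function(model, images) {
  X <- backbone_feature_matrix(model$backbone, images)
  if (!is.null(model$feat_center))
    X <- sweep(sweep(X, 2, model$feat_center), 2, model$feat_scale, `/`)
  X * model$config$feature_scale
}

#' Forward pass to class probabilities (evaluation mode, dropout off)
#'
#' @param model A `vit_classifier`.
#' @param images List of images (or feature vectors for the identity
#'   backbone).
#' @return N x 2 matrix of softmax probabilities (columns follow the class
#'   order used at training).
#' @export
predict_proba <- function(model, images) {
  X <- classifier_features(model, images)
  softmax(mlp_forward(model$head, X)$out)
}

#' Train the classifier head
#'
#' The frozen backbone's features are cached, then the head is trained with
#' SGD (Nesterov momentum) on cross-entropy. Training stops when the
#' validation loss has failed to improve by at least
#' `early_stop_min_delta` for `early_stop_patience` consecutive epochs, or
#' at `max_epochs`; the head from the best validation epoch is restored.
#'
#' @param model A `vit_classifier`.
#' @param splits Output of [prepare_dataset()] (or a list with `train` and
#'   `val`, each `x`/`y`).
#' @return The trained model with `history` (per-epoch train/val loss and
#'   validation accuracy) and `stopped_epoch`.
#' @export
train_classifier <- function(model, splits) {
  cfg <- model$config
  if (length(splits$train$x) == 0 || length(splits$val$x) == 0)
    stop("train and validation splits must be non-empty")
  Xtr_raw <- backbone_feature_matrix(model$backbone, splits$train$x)
  model$feat_center <- colMeans(Xtr_raw)
  fs <- apply(Xtr_raw, 2, stats::sd)
  model$feat_scale <- ifelse(fs < 1e-8, 1, fs)
  Xtr <- sweep(sweep(Xtr_raw, 2, model$feat_center), 2, model$feat_scale,
               `/`) * cfg$feature_scale
  ytr <- splits$train$y
  Xva <- classifier_features(model, splits$val$x)
  yva <- splits$val$y
  head <- model$head
  state <- sgd_init(head)
  best <- list(loss = Inf, head = head, epoch = 0)
  wait <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  n <- nrow(Xtr)
  bs <- min(cfg$batch_size, n)
  for (ep in seq_len(cfg$max_epochs)) {
    set.seed(derive_seed(cfg$seed, 200000 + ep))
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      fwd <- mlp_forward(head, Xtr[idx, , drop = FALSE],
                         dropout = cfg$dropout, training = TRUE,
                         drop_seed = derive_seed(cfg$seed,
                                                 300000 + ep * 1000 + nb))
      lg <- ce_loss_grad(fwd$out, ytr[idx])
      if (!is.finite(lg$loss)) stop("training aborted: non-finite loss")
      grads <- mlp_backward(head, fwd, lg$grad)
      upd <- sgd_step(head, grads, state, cfg$learning_rate, cfg$momentum,
                      cfg$nesterov)
      head <- upd$layers; state <- upd$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    val <- ce_loss_grad(mlp_forward(head, Xva)$out, yva)
    val_acc <- mean(max.col(val$probs) == yva)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val$loss, val_acc = val_acc))
    if (best$loss - val$loss >= cfg$early_stop_min_delta) {
      best <- list(loss = val$loss, head = head, epoch = ep)
      wait <- 0
    } else {
      if (val$loss < best$loss) { best$loss <- val$loss; best$head <- head
                                  best$epoch <- ep }
      wait <- wait + 1
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$head <- best$head
  model$history <- hist
  model$stopped_epoch <- nrow(hist)
  model$best_epoch <- best$epoch
  model
}

#' Classification metric suite
#'
#' Accuracy, macro-averaged precision/recall/F1, and AUC-ROC from the
#' positive-class probability (rank statistic, tie-corrected), plus the
#' confusion matrix (rows = truth, columns = prediction).
#'
#' @param model A trained `vit_classifier`.
#' @param test A split with `x`, `y`, `labels` (both classes present).
#' @param positive_class Label treated as positive (default `"glaucoma"` when
#'   present, else the second class).
#' @return Object of class `classification_metrics` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `auc_roc`, `confusion`, `positive_class`,
#'   `averaging`.
#' @export
evaluate_classifier <- function(model, test, positive_class = NULL) {
  if (length(test$x) == 0) stop("test split is empty")
  probs <- predict_proba(model, test$x)
  classes <- if (!is.null(test$labels)) sort(unique(test$labels)) else
    as.character(seq_len(ncol(probs)))
  y <- test$y
  if (length(unique(y)) < 2)
    stop("AUC undefined: test split contains a single class")
  if (is.null(positive_class))
    positive_class <- if ("glaucoma" %in% classes) "glaucoma" else classes[2]
  pred <- max.col(probs)
  metrics_from_predictions(y, pred, probs, classes, positive_class)
}

# shared metric computation; y/pred integer class indices, probs N x 2
metrics_from_predictions <- function(y, pred, probs, classes,
                                     positive_class) {
  K <- length(classes)
  confusion <- matrix(0L, K, K, dimnames = list(truth = classes,
                                                prediction = classes))
  for (i in seq_along(y)) {
    confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  }
  acc <- sum(diag(confusion)) / sum(confusion)
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- confusion[k, k]
    prec[k] <- if (sum(confusion[, k]) > 0) tp / sum(confusion[, k]) else 0
    rec[k] <- if (sum(confusion[k, ]) > 0) tp / sum(confusion[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  pos <- match(positive_class, classes)
  if (is.na(pos)) stop("positive_class not among the class labels")
  p_pos <- probs[, pos]
  is_pos <- y == pos
  r <- rank(p_pos)
  auc <- (sum(r[is_pos]) - sum(is_pos) * (sum(is_pos) + 1) / 2) /
    (sum(is_pos) * sum(!is_pos))
  structure(list(accuracy = acc, precision = mean(prec), recall = mean(rec),
                 f1 = mean(f1), auc_roc = auc, confusion = confusion,
                 per_class = data.frame(class = classes, precision = prec,
                                        recall = rec, f1 = f1),
                 positive_class = positive_class, averaging = "macro"),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "<classification_metrics> (macro, positive = %s)\n  accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  auc_roc %.4f\n",
    x$positive_class, x$accuracy, x$precision, x$recall, x$f1, x$auc_roc))
  invisible(x)
}

#' Metrics as a one-row data frame (`accuracy,precision,recall,f1,auc_roc`)
#' @param metrics A `classification_metrics` object.
#' @return One-row data frame.
#' @export
metrics_row <- function(metrics) {
  data.frame(accuracy = metrics$accuracy, precision = metrics$precision,
             recall = metrics$recall, f1 = metrics$f1,
             auc_roc = metrics$auc_roc)
}
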