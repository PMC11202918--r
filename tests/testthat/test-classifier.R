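test_that("head architecture and parameter count match the recipe", {
  cfg <- classifier_config(seed = 1)
  model <- build_vit_classifier(cfg)
  D <- model$backbone$feature_dim
  expect_equal(n_trainable_params(model),
               (D * 512 + 512) + (512 * 256 + 256) + (256 * 2 + 2))
  # logits shape (3, 2) on a batch of 3
  imgs <- lapply(1:3, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  p <- predict_proba(model, imgs)
  expect_equal(dim(p), c(3, 2))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  # eval-mode forward is deterministic (dropout off)
  expect_identical(p, predict_proba(model, imgs))
  expect_error(classifier_config(input_size = 225), "divisible")
})

test_that("dataset preparation is stratified, seeded and size-exact", {
  feats <- separable_features(50)
  rois <- lapply(feats$x, function(v) array(abs(v[1:48]) / 2, c(4, 4, 3)))
  cfg <- classifier_config(seed = 9)
  sp <- prepare_dataset(rois, feats$labels, cfg)
  expect_length(sp$train$x, 80)
  expect_length(sp$val$x, 10)
  expect_length(sp$test$x, 10)
  expect_equal(as.vector(table(sp$train$labels)), c(40, 40))
  expect_equal(as.vector(table(sp$val$labels)), c(5, 5))
  expect_equal(as.vector(table(sp$test$labels)), c(5, 5))
  # determinism of membership
  sp2 <- prepare_dataset(rois, feats$labels, cfg)
  expect_identical(sp$train$y, sp2$train$y)
  expect_identical(sapply(sp$train$x, sum), sapply(sp2$train$x, sum))
  # constant image resizes to a constant image
  sp3 <- prepare_dataset(c(rois[1:19], list(array(0.4, c(8, 8, 3))),
                           rois[21:100]),
                         feats$labels, cfg)
  const <- Filter(function(x) max(abs(x - 0.4)) < 1e-12,
                  c(sp3$train$x, sp3$val$x, sp3$test$x))
  expect_length(const, 1)
  expect_equal(dim(const[[1]]), c(224, 224, 3))
  few <- c(1:12, 51:58)    # 12 glaucoma, 8 normal
  expect_error(prepare_dataset(rois[few], feats$labels[few], cfg),
               "at least 10")
})

test_that("the head reaches high accuracy on separable embeddings under the
           exact early-stopping rule", {
  feats <- separable_features(60)
  cfg <- classifier_config(backbone_name = "identity", feature_dim = 64,
                           seed = 4)
  splits <- prepare_dataset(feats$x, feats$labels, cfg)
  model <- build_vit_classifier(cfg)
  before <- fundusHSI:::backbone_checksum(model$backbone)
  model <- train_classifier(model, splits)
  expect_lte(model$stopped_epoch, 25)
  best_val_acc <- model$history$val_acc[model$best_epoch]
  expect_gte(best_val_acc, 0.95)
  # frozen-backbone contract: weights bitwise unchanged by training
  expect_identical(before, fundusHSI:::backbone_checksum(model$backbone))
  # reproducible history
  model2 <- train_classifier(build_vit_classifier(cfg), splits)
  expect_identical(model$history, model2$history)
})

test_that("early stopping with infinite min-delta stops at patience + 1", {
  feats <- separable_features(20)
  cfg <- classifier_config(backbone_name = "identity", feature_dim = 64,
                           seed = 2, early_stop_min_delta = Inf)
  splits <- prepare_dataset(feats$x, feats$labels, cfg)
  model <- train_classifier(build_vit_classifier(cfg), splits)
  expect_equal(model$stopped_epoch, cfg$early_stop_patience + 1)
})

test_that("metric suite matches hand computation and is label-symmetric", {
  classes <- c("glaucoma", "normal")
  # perfect predictions
  y <- c(1L, 1L, 2L, 2L)
  probs <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.1, 0.9), c(0.2, 0.8))
  m <- fundusHSI:::metrics_from_predictions(y, y, probs, classes, "glaucoma")
  expect_equal(unlist(metrics_row(m)), rep(1, 5), ignore_attr = TRUE)

  # hand-computed confusion: TP=3 FP=1 FN=1 TN=5 for the positive class
  y <- c(rep(1L, 4), rep(2L, 6))
  pred <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 1L)
  probs <- cbind(ifelse(pred == 1, 0.9, 0.1), ifelse(pred == 1, 0.1, 0.9))
  m <- fundusHSI:::metrics_from_predictions(y, pred, probs, classes,
                                            "glaucoma")
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$per_class$precision[1], 0.75)
  expect_equal(m$per_class$recall[1], 0.75)
  expect_equal(m$precision, (0.75 + 5 / 6) / 2, tolerance = 1e-12)
  expect_equal(m$precision, 0.7917, tolerance = 1e-4)
  # accuracy equals trace(confusion)/sum(confusion)
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion))
  # macro metrics from an independent per-formula recomputation
  cm <- m$confusion
  prec <- diag(cm) / colSums(cm); rec <- diag(cm) / rowSums(cm)
  expect_equal(m$precision, mean(prec))
  expect_equal(m$recall, mean(rec))
  expect_equal(m$f1, mean(2 * prec * rec / (prec + rec)))

  # label-swap symmetry of macro metrics
  m_sw <- fundusHSI:::metrics_from_predictions(3L - y, 3L - pred,
                                               probs[, 2:1], classes,
                                               "glaucoma")
  expect_equal(m$precision, m_sw$precision)
  expect_equal(m$recall, m_sw$recall)
  expect_equal(m$f1, m_sw$f1)
})

test_that("rank-based AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- c(rep(1L, 12), rep(2L, 15))
  p_pos <- c(rnorm(12, 0.7, 0.2), rnorm(15, 0.4, 0.2))
  probs <- cbind(p_pos, 1 - p_pos)
  m <- fundusHSI:::metrics_from_predictions(
    y, ifelse(p_pos > 0.5, 1L, 2L), probs, c("glaucoma", "normal"),
    "glaucoma")
  ref <- pROC::auc(pROC::roc(response = y == 1, predictor = p_pos,
                             quiet = TRUE, direction = "<"))
  expect_equal(m$auc_roc, as.numeric(ref), tolerance = 1e-12)
  # single-class test set: AUC undefined
  expect_error(evaluate_classifier(
    build_vit_classifier(classifier_config(backbone_name = "identity",
                                           feature_dim = 4)),
    list(x = list(1:4, 2:5), y = c(1L, 1L), labels = c("a", "a"))),
    "single class")
})
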