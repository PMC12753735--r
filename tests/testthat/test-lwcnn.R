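test_that("the classifier reproduces the reference layer table", {
  m <- build_lwcnn(lwcnn_config())
  sp <- m$spec
  conv <- sp[sp$name == "Conv2D", ]
  expect_equal(conv$params, c(896, 18496, 73856, 295168))
  expect_equal(conv$output_shape,
               c("(None, 62, 62, 32)", "(None, 29, 29, 64)",
                 "(None, 12, 12, 128)", "(None, 4, 4, 256)"))
  dense <- sp[sp$name == "Dense", ]
  expect_equal(dense$params, c(262400, 2313))
  expect_equal(dense$activation, c("ReLU", "Softmax"))
  expect_equal(sp$output_shape[nrow(sp)], "(None, 9)")
  expect_equal(count_trainable_params(m), 653129)
  expect_true(all(sp$params[sp$name %in% c("MaxPooling2D", "Dropout",
                                           "Flatten")] == 0))
  # initialized weights carry exactly that many numbers
  expect_equal(sum(vapply(m$params, length, 0L)), 653129L)
})

test_that("stratified folds partition the data with class balance", {
  y <- rep(c("a", "b"), each = 5)
  folds <- stratified_kfold(y, k = 5, seed = 2)
  test_sets <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), 1:10)
  for (fs in folds) {
    expect_equal(length(fs$test), 2L)
    expect_equal(sort(table(y[fs$test])), sort(c(a = 1L, b = 1L)),
                 ignore_attr = TRUE)
    expect_equal(sort(c(fs$train, fs$val, fs$test)), 1:10)
    expect_equal(length(intersect(fs$train, fs$test)), 0L)
  }
  expect_error(stratified_kfold(c("a", rep("b", 9)), k = 5), "fewer than")

  # n = 10124 in nine classes: test folds sized 2024 or 2025
  set.seed(1)
  big <- sample(rep(CELL_CLASSES, REFERENCE_CLASS_COUNTS))
  bf <- stratified_kfold(big, k = 5, seed = 3)
  sizes <- vapply(bf, function(f) length(f$test), 0L)
  expect_true(all(sizes %in% c(2024L, 2025L)))
  expect_equal(sum(sizes), 10124L)
  # per-class proportions preserved within one sample
  for (fs in bf) {
    tt <- table(factor(big[fs$test], CELL_CLASSES))
    expect_true(all(abs(tt - REFERENCE_CLASS_COUNTS / 5) <= 1))
  }
  # train:val close to 75:25 within each fold
  fr <- vapply(bf, function(f) length(f$val) / (length(f$val) +
                                                  length(f$train)), 0)
  expect_true(all(abs(fr - 0.25) < 0.01))
})

test_that("fold leakage is detected and rejected", {
  fix <- roi_fixture(n_per_class = 2, roi_size = 48L)
  bad <- list(structure(list(fold = 1L, train = 1:10, val = 10:12,
                             test = 13:18), class = "fold_split"))
  m <- build_lwcnn(lwcnn_config(input_size = 48L,
                                filters = c(4L, 8L, 12L, 16L),
                                dense = 32L))
  expect_error(train_classifier(m, fix$x, fix$y, bad), "leakage")
})

test_that("predict_proba returns a valid distribution", {
  cfg <- lwcnn_config(input_size = 48L, filters = c(4L, 8L, 12L, 16L),
                      dense = 32L)
  m <- build_lwcnn(cfg, seed = 1)
  roi <- array(runif(48 * 48 * 3), c(48, 48, 3))
  pr <- predict_proba(m, image_rgb(roi, "unit"))
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))
  expect_true(attr(pr, "predicted_class") %in% CELL_CLASSES)
  # uniform logits (zeroed head) give exactly 1/9 everywhere
  m$params$fc2_w[] <- 0
  m$params$fc2_b[] <- 0
  pr0 <- predict_proba(m, image_rgb(roi, "unit"))
  expect_equal(unclass(pr0), rep(1 / 9, 9), ignore_attr = TRUE)
  expect_error(predict_proba(m, image_rgb(array(0, c(32, 32, 3)), "unit")),
               "48")
})

test_that("the network can memorize a small sample (capacity check)", {
  fix <- roi_fixture(n_per_class = 12, roi_size = 48L)
  set.seed(4)
  idx <- unlist(lapply(CELL_CLASSES, function(cl)
    sample(which(fix$y == cl), 2)))     # 18 samples, ~20
  cfg <- lwcnn_config(input_size = 48L, filters = c(8L, 16L, 24L, 32L),
                      dense = 64L, dropout_conv = 0, dropout_dense = 0)
  m <- build_lwcnn(cfg, seed = 2)
  rest <- setdiff(seq_along(fix$y), idx)
  fold <- structure(list(fold = 1L, train = idx, val = rest[1:9],
                         test = rest[10:18]), class = "fold_split")
  pol <- training_policy(batch_size = 6L, max_epochs = 30L,
                         es_patience = 30L, augment = FALSE)
  cv <- train_classifier(m, fix$x, fix$y, list(fold), pol, seed = 3)
  # after overfitting, the model scores its own training samples perfectly
  tr <- hemosmear:::lwcnn_evaluate(cv$folds[[1]]$model$params, fix$x,
                                   fix$y, idx, cfg, CELL_CLASSES)
  expect_equal(tr$metrics$accuracy, 1.0)
  expect_lte(nrow(cv$folds[[1]]$model$history), 30L)
})

test_that("cross-validated training separates the nine synthetic classes", {
  fix <- roi_fixture(n_per_class = 30, roi_size = 48L)
  folds <- stratified_kfold(fix$y, k = 5, seed = 7)
  cfg <- lwcnn_config(input_size = 48L, filters = c(8L, 16L, 24L, 32L),
                      dense = 64L, dropout_conv = 0, dropout_dense = 0)
  m <- build_lwcnn(cfg, seed = 1)
  pol <- training_policy(batch_size = 8L, max_epochs = 25L,
                         augment = FALSE)
  cv <- train_classifier(m, fix$x, fix$y, folds, pol, seed = 5)
  agg <- aggregate_folds(cv$per_fold[, c("accuracy", "f1")])
  expect_gte(agg$mean[["accuracy"]], 0.90)
  # macro-F1 tracks accuracy closely on this balanced, separable fixture
  expect_lt(abs(agg$mean[["f1"]] - agg$mean[["accuracy"]]), 0.02)
  h <- cv$folds[[1]]$model$history
  expect_true(all(c("train_accuracy", "train_f1", "val_accuracy",
                    "val_recall", "val_loss") %in% names(h)))
})
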