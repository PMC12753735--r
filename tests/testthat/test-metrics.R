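test_that("confusion matrix follows the actual-row convention", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "a", "b"))
  expect_equal(diag(cm), c(a = 2L, b = 1L))
  expect_true(all(cm[row(cm) != col(cm)] == 0))

  # every basophil predicted eosinophil lands in that row/column cell
  true <- c(rep("basophil", 4), rep("eosinophil", 3))
  pred <- c(rep("eosinophil", 4), rep("eosinophil", 3))
  cm2 <- confusion_matrix(true, pred, levels = c("basophil", "eosinophil"))
  expect_equal(cm2["basophil", "eosinophil"], 4L)
  expect_equal(sum(cm2), 7L)

  expect_error(confusion_matrix("a", "z", levels = c("a", "b")),
               "outside levels")
})

test_that("binary metrics follow the defining formulas", {
  m <- binary_metrics(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_equal(m[["accuracy"]], 1.0)
  expect_equal(m[["f1"]], 1.0)

  m2 <- binary_metrics(tp = 3, tn = 0, fp = 1, fn = 3)
  expect_equal(m2[["precision"]], 0.75)
  expect_equal(m2[["recall"]], 0.5)

  # harmonic mean: precision .8, recall .6 -> 0.6857...
  f1 <- 2 * 0.8 * 0.6 / (0.8 + 0.6)
  m3 <- binary_metrics(tp = 12, tn = 0, fp = 3, fn = 8)  # p=0.8, r=0.6
  expect_equal(m3[["f1"]], f1, tolerance = 1e-12)
  expect_equal(m3[["f1"]], 0.48 * 2 / 1.4, tolerance = 1e-12)
  # F1 always between precision and recall
  expect_gte(m3[["f1"]], min(m3[["precision"]], m3[["recall"]]))
  expect_lte(m3[["f1"]], max(m3[["precision"]], m3[["recall"]]))

  # zero denominators: undefined (NA with a flag), never 0
  m4 <- binary_metrics(tp = 0, tn = 4, fp = 0, fn = 0)
  expect_true(is.na(m4[["precision"]]))
  expect_true("precision" %in% attr(m4, "undefined"))
})

test_that("IoU and Dice follow set arithmetic and their identity", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(overlap_metrics(a, a), c(iou = 1, dice = 1))
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(overlap_metrics(a, b), c(iou = 0, dice = 0))

  # |A|=|B|=4, |A^B|=2 -> IoU 1/3, Dice 1/2
  c1 <- matrix(0, 4, 4); c1[1:2, 1:2] <- 1
  c2 <- matrix(0, 4, 4); c2[2:3, 1:2] <- 1
  om <- overlap_metrics(c1, c2)
  expect_equal(om[["iou"]], 1 / 3)
  expect_equal(om[["dice"]], 0.5)

  expect_equal(overlap_metrics(matrix(0, 3, 3), matrix(0, 3, 3)),
               c(iou = 1, dice = 1))
  expect_error(overlap_metrics(matrix(0, 2, 2), matrix(0, 3, 3)),
               "mismatch")

  # Dice = 2 IoU / (1 + IoU) across randomized pairs, to 1e-12
  set.seed(8)
  for (i in 1:50) {
    x <- matrix(rbinom(100, 1, 0.4), 10, 10)
    y <- matrix(rbinom(100, 1, 0.4), 10, 10)
    om <- overlap_metrics(x, y)
    expect_equal(om[["dice"]], 2 * om[["iou"]] / (1 + om[["iou"]]),
                 tolerance = 1e-12)
  }
})

test_that("AUC matches perfect, random, and hand-enumerated cases", {
  p <- matrix(c(.9, .8, .3, .1, .1, .2, .7, .9), 4, 2,
              dimnames = list(NULL, c("pos", "neg")))
  labs <- c("pos", "pos", "neg", "neg")
  r <- roc_auc(labs, p)
  expect_equal(r$per_class[["pos"]], 1.0)

  # swap one pair: 3 of 4 pairs ordered -> 0.75
  p2 <- p; p2[c(2, 3), "pos"] <- p[c(3, 2), "pos"]
  expect_equal(roc_auc(labs, p2)$per_class[["pos"]], 0.75)

  # scores carrying no information: 0.5
  pc <- matrix(0.5, 4, 2, dimnames = list(NULL, c("pos", "neg")))
  expect_equal(roc_auc(labs, pc)$per_class[["pos"]], 0.5)

  expect_warning(
    r3 <- roc_auc(c("a", "a"), matrix(c(.6, .4, .4, .6), 2, 2,
                                      dimnames = list(NULL, c("a", "b")))),
    "absent")
  expect_true(is.na(r3$per_class[["b"]]))
})

test_that("AUC equals the pair-counting oracle on small inputs", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    sc <- round(runif(n), 2)            # rounded: force some ties
    got <- hemosmear:::binary_auc(pos, sc)
    expect_equal(got, auc_pair_oracle(pos, sc), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  set.seed(10)
  pos <- runif(40) < 0.5
  sc <- runif(40)
  got <- hemosmear:::binary_auc(pos, sc)
  ref <- as.numeric(pROC::auc(pROC::roc(as.integer(pos), sc,
                                        quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("micro accuracy equals trace over total", {
  set.seed(12)
  true <- sample(CELL_CLASSES, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, true, sample(CELL_CLASSES, 60,
                                               replace = TRUE))
  cm <- confusion_matrix(true, pred, levels = CELL_CLASSES)
  mm <- hemosmear:::multiclass_metrics(cm)
  expect_equal(mm$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(sum(cm), 60L)
})

test_that("fold aggregation reproduces printed means", {
  same <- data.frame(accuracy = rep(0.9, 3), f1 = rep(0.8, 3))
  agg <- aggregate_folds(same)
  expect_equal(agg$mean[["accuracy"]], 0.9)
  expect_equal(agg$sd[["accuracy"]], 0)

  one <- aggregate_folds(data.frame(accuracy = 0.77))
  expect_equal(one$mean[["accuracy"]], 0.77)
  expect_equal(one$sd[["accuracy"]], 0)

  folds <- data.frame(accuracy = c(97.07, 97.41, 96.72, 97.46, 96.82))
  agg2 <- aggregate_folds(folds)
  expect_equal(sprintf("%.2f", agg2$mean[["accuracy"]]), "97.10")
})
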