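# Pixel-, object- and classification-level evaluation: confusion counts,
# accuracy/precision/recall/F1, IoU and Dice, one-vs-rest ROC/AUC with
# micro and macro averaging, and cross-fold aggregation.

#' Multiclass confusion matrix
#'
#' Rows are actual classes, columns predicted classes; entries sum to the
#' number of samples.
#'
#' @param true_labels,predicted_labels aligned label vectors.
#' @param levels class levels (default: union of observed labels, sorted).
#' @param n_classes optional expected class count; labels outside `levels`
#'   are an error.
#' @return integer matrix with dimnames actual x predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, levels = NULL,
                             n_classes = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (is.null(levels)) levels <- sort(unique(c(true_labels,
                                               predicted_labels)))
  if (!is.null(n_classes) && length(levels) > n_classes)
    stop("labels outside the expected ", n_classes, " classes")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), levels)
  if (length(bad) > 0) stop("label(s) outside levels: ",
                            paste(bad, collapse = ", "))
  m <- table(factor(true_labels, levels), factor(predicted_labels, levels))
  m <- matrix(as.integer(m), length(levels), length(levels),
              dimnames = list(actual = levels, predicted = levels))
  m
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2 * precision * recall / (precision + recall). A zero
#' denominator yields `NA` with the corresponding flag in the `undefined`
#' attribute rather than 0.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named numeric vector (accuracy, precision, recall, f1) with an
#'   `undefined` attribute naming any undefined metric.
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  undef <- character(0)
  total <- tp + tn + fp + fn
  acc <- if (total > 0) (tp + tn) / total else { undef <- c(undef,
                                                            "accuracy"); NA }
  prec <- if (tp + fp > 0) tp / (tp + fp) else { undef <- c(undef,
                                                            "precision"); NA }
  rec <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef,
                                                           "recall"); NA }
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec)
  else { undef <- c(undef, "f1"); NA }
  structure(c(accuracy = acc, precision = prec, recall = rec, f1 = f1),
            undefined = undef)
}

# macro-averaged one-vs-rest metrics from a multiclass confusion matrix
multiclass_metrics <- function(cm) {
  n <- sum(cm)
  k <- nrow(cm)
  per <- lapply(seq_len(k), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- n - tp - fp - fn
    binary_metrics(tp, tn, fp, fn)
  })
  prec <- mean(vapply(per, `[[`, 0, "precision"), na.rm = TRUE)
  rec <- mean(vapply(per, `[[`, 0, "recall"), na.rm = TRUE)
  f1 <- mean(vapply(per, `[[`, 0, "f1"), na.rm = TRUE)
  list(accuracy = sum(diag(cm)) / n, precision = prec, recall = rec,
       f1 = f1, per_class = per)
}

#' Mask overlap metrics
#'
#' IoU = |A intersect B| / |A union B|; Dice = 2 |A intersect B| /
#' (|A| + |B|). Two empty masks are defined as perfect agreement (1, 1).
#'
#' @param pred_mask,true_mask binary matrices of identical shape.
#' @return named numeric vector (iou, dice).
#' @export
overlap_metrics <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask)))
    stop("mask shape mismatch")
  a <- pred_mask > 0
  b <- true_mask > 0
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(c(iou = 1, dice = 1))
  c(iou = inter / uni, dice = 2 * inter / (sum(a) + sum(b)))
}

# trapezoidal AUC of a binary scoring problem (ties handled by grouping
# equal scores, equivalent to the Mann-Whitney statistic with 1/2 ties)
binary_auc <- function(pos, score) {
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- pos[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' One-vs-rest ROC AUC, per class and micro/macro averaged
#'
#' Per-class AUC by trapezoidal integration of the one-vs-rest ROC curve;
#' micro AUC pools all (indicator, probability) decisions; macro AUC is the
#' unweighted mean over classes with defined AUC (a class absent from the
#' truth is excluded with a warning).
#'
#' @param true_labels label vector.
#' @param probability_matrix samples x classes matrix of class
#'   probabilities (column names = class labels).
#' @return list with `per_class`, `micro`, `macro`.
#' @export
roc_auc <- function(true_labels, probability_matrix) {
  true_labels <- as.character(true_labels)
  cls <- colnames(probability_matrix)
  stopifnot(!is.null(cls), nrow(probability_matrix) == length(true_labels))
  per <- vapply(cls, function(cl)
    binary_auc(true_labels == cl, probability_matrix[, cl]), 0)
  if (anyNA(per))
    warning("class(es) absent from the truth excluded from macro AUC: ",
            paste(cls[is.na(per)], collapse = ", "))
  ind <- as.vector(outer(true_labels, cls, `==`))
  micro <- binary_auc(ind, as.vector(probability_matrix))
  list(per_class = per, micro = micro, macro = mean(per, na.rm = TRUE))
}

#' Aggregate per-fold metric rows
#'
#' Unweighted mean and standard deviation over the fold rows, plus a
#' 2-decimal formatted "mean +/- sd" presentation row.
#'
#' @param reports data frame with one row per fold (a `fold` column is
#'   ignored for aggregation) or a list of named numeric vectors.
#' @return a `metrics_report`: list with `per_fold`, `mean`, `sd`,
#'   `formatted`.
#' @export
aggregate_folds <- function(reports) {
  if (!is.data.frame(reports))
    reports <- as.data.frame(do.call(rbind, reports))
  stopifnot(nrow(reports) >= 1)
  num <- reports[, setdiff(names(reports), "fold"), drop = FALSE]
  mu <- vapply(num, mean, 0)
  sdev <- if (nrow(num) > 1) vapply(num, sd, 0) else
    stats::setNames(rep(0, ncol(num)), names(num))
  structure(list(per_fold = reports, mean = mu, sd = sdev,
                 formatted = sprintf("%.2f ± %.2f", mu, sdev)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Cross-fold metrics (", nrow(x$per_fold), " folds)\n", sep = "")
  out <- data.frame(metric = names(x$mean), `mean +/- sd` = x$formatted,
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Pixel-level segmentation report over an evaluation set
#'
#' Pools pixels over all mask pairs (micro aggregation) for the confusion
#' counts and derived accuracy/precision/recall/F1, and reports IoU/Dice on
#' the pooled masks.
#'
#' @param pred_masks,true_masks lists of aligned binary matrices.
#' @return named numeric vector: accuracy, precision, recall, f1, iou,
#'   dice.
#' @export
segmentation_report <- function(pred_masks, true_masks) {
  stopifnot(length(pred_masks) == length(true_masks))
  tp <- tn <- fp <- fn <- 0
  inter <- pa <- ta <- uni <- 0
  for (i in seq_along(pred_masks)) {
    a <- pred_masks[[i]] > 0
    b <- true_masks[[i]] > 0
    tp <- tp + sum(a & b); tn <- tn + sum(!a & !b)
    fp <- fp + sum(a & !b); fn <- fn + sum(!a & b)
    inter <- inter + sum(a & b); uni <- uni + sum(a | b)
    pa <- pa + sum(a); ta <- ta + sum(b)
  }
  bm <- binary_metrics(tp, tn, fp, fn)
  c(bm, iou = if (uni > 0) inter / uni else 1,
    dice = if (pa + ta > 0) 2 * inter / (pa + ta) else 1)
}
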