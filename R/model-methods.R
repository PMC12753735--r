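# S3 methods for model objects and layer specifications.

#' @export
print.model_spec <- function(x, ...) {
  cat("Layer specification (", nrow(x), " layers, ",
      format(sum(x$params), big.mark = ","), " trainable parameters)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.cnn_model <- function(x, ...) {
  kind <- if (inherits(x, "unet_model")) "U-Net segmentation" else
    "lightweight CNN classification"
  cat(kind, " model\n", sep = "")
  cat("  layers: ", nrow(x$spec), ", trainable parameters: ",
      format(sum(x$spec$params), big.mark = ","), "\n", sep = "")
  if (!is.null(x$history))
    cat("  trained: ", nrow(x$history), " epochs, best epoch ",
        x$best_epoch %||% which.min(x$history$val_loss), "\n", sep = "")
  else cat("  untrained (He-initialized weights)\n")
  invisible(x)
}

#' @export
summary.cnn_model <- function(object, ...) {
  print(object)
  print(object$spec)
  invisible(object)
}

#' @export
predict.unet_model <- function(object, newdata, tau = 0.5, ...) {
  predict_mask(object, newdata, tau)
}

#' @export
predict.lwcnn_model <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' @export
plot.cnn_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(h$loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.class_probabilities <- function(x, ...) {
  cat("predicted:", attr(x, "predicted_class"),
      sprintf("(confidence %.3f)\n", attr(x, "confidence")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
print.synthetic_smear <- function(x, ...) {
  cat(sprintf("<synthetic_smear %dx%d, %d cells, overlap %.2f>\n",
              nrow(x$instances), ncol(x$instances), length(x$labels),
              x$overlap_achieved))
  invisible(x)
}

#' @export
print.lwcnn_cv <- function(x, ...) {
  cat("Cross-validated classifier (", length(x$folds), " folds)\n",
      sep = "")
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}
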