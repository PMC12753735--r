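# Grad-CAM: class-discriminative localization heatmaps for the classifier.

#' Gradient-weighted class activation map
#'
#' Channel weights are the spatial averages of the gradients of the target
#' class score (pre-softmax logit) with respect to the chosen convolutional
#' layer's post-activation feature maps; the heatmap is the rectified
#' weighted sum, normalized by its maximum and bilinearly upsampled to the
#' input size. A degenerate all-zero map (zero gradients everywhere) is
#' returned as-is with a warning.
#'
#' @param model a trained `lwcnn_model`.
#' @param roi unit-scale `S x S x 3` array at the model input size.
#' @param target_class class name or index in `model$classes`.
#' @param layer convolutional layer name, `"conv1"`..`"conv4"` (default the
#'   last one).
#' @return a `heatmap`: matrix in \[0, 1\] at the input size, with
#'   attributes `target_class` and `layer`.
#' @export
compute_gradcam <- function(model, roi, target_class,
                            layer = "conv4") {
  if (!grepl("^conv[1-4]$", layer))
    stop("'", layer, "' is not a convolutional feature layer of this model")
  li <- as.integer(substring(layer, 5))
  if (is.character(target_class))
    target_class <- match(target_class, model$classes)
  if (is.na(target_class) || target_class < 1 ||
      target_class > length(model$classes))
    stop("target_class out of range")
  a <- unclass(roi)
  if (img_scale(roi) == "byte" && max(a) > 1) a <- a / 255
  x <- array(a, c(dim(a), 1L))
  p <- model$params
  cfg <- model$cfg
  fw <- lwcnn_forward(p, x, cfg, drop = NULL)
  cache <- fw$cache
  # gradient of the target logit w.r.t. the network, stopping at layer li
  dlog <- matrix(0, 1, length(model$classes))
  dlog[1, target_class] <- 1
  dh <- dlog %*% t(p$fc2_w)
  dh <- relu_bwd(dh, cache$h_pre_drop)
  dflat <- dh %*% t(p$fc1_w)
  da <- array(t(dflat), dim(cache$pd4))
  for (b in 4:1) {
    if (b == li) {
      # da currently holds d(score)/d(post-pool); push back through pooling
      da <- .maxpool_bwd(da, cache[[paste0("pl", b)]]$which,
                         dim(cache[[paste0("a", b)]]))
      feat <- cache[[paste0("a", b)]]
      grads <- da
      wts <- apply(grads[, , , 1, drop = FALSE], 3, mean)
      fmap <- feat[, , , 1]
      if (length(dim(fmap)) == 2L) fmap <- array(fmap, c(dim(fmap), 1L))
      cam <- matrix(0, dim(fmap)[1], dim(fmap)[2])
      for (k in seq_along(wts)) cam <- cam + wts[k] * fmap[, , k]
      cam[cam < 0] <- 0
      if (max(cam) <= 0) {
        warning("zero-gradient Grad-CAM; returning an all-zero heatmap")
        hm <- matrix(0, dim(a)[1], dim(a)[2])
      } else {
        cam <- cam / max(cam)
        hm <- resize_bilinear(cam, dim(a)[1], dim(a)[2])
        hm <- pmin(pmax(hm, 0), 1)
      }
      return(structure(hm, class = "heatmap",
                       target_class = model$classes[target_class],
                       layer = layer))
    }
    da <- .maxpool_bwd(da, cache[[paste0("pl", b)]]$which,
                       dim(cache[[paste0("a", b)]]))
    da <- relu_bwd(da, cache[[paste0("a", b)]])
    xin <- if (b == 1) cache$x else cache[[paste0("pd", b - 1L)]]
    da <- .conv_bwd(xin, p[[paste0("c", b, "_w")]], da, 0L)$dx
  }
  stop("internal: layer not reached")
}

#' Overlay a heatmap on an image
#'
#' Alpha-blends a blue-to-red colorized heatmap over the ROI: `alpha = 0`
#' returns the original image, `alpha = 1` the pure colormap render.
#'
#' @param image byte-scale [image_rgb()].
#' @param heatmap matrix in \[0, 1\] of the same spatial size.
#' @param alpha blend weight in \[0, 1\].
#' @return byte-scale [image_rgb()].
#' @export
overlay <- function(image, heatmap, alpha = 0.4) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  stopifnot(all(dim(image)[1:2] == dim(heatmap)))
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(pmin(pmax(heatmap, 0), 1)))
  a <- unclass(image)
  out <- a
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * a[, , ch] +
      alpha * matrix(cols[, ch], nrow(heatmap), ncol(heatmap))
  restore_img(out, image)
}
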