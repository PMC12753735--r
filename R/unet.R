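# U-Net encoder-decoder for binary segmentation of smear images.
# Four 2x2-pooled encoder blocks of paired same-padded 3x3 convolutions
# (filter ladder doubling from the base width), a bottleneck pair,
# a mirrored decoder with parameter-free 2x nearest upsampling and skip
# concatenations, and a 1x1 sigmoid head.

#' U-Net configuration
#'
#' The default reproduces the reference architecture: 256 x 256 x 3 input,
#' encoder filter ladder 64-128-256-512, bottleneck 1024, mirrored decoder,
#' 1 x 1 sigmoid head. `width_scale` divides the whole ladder for
#' desk-scale experiments (e.g. 4 gives 16-32-64-128 with bottleneck 256).
#'
#' @param input_size length-2 (height, width); must be divisible by 16
#'   (four 2x pooling stages).
#' @param channels input channels.
#' @param filters encoder ladder (4 widths).
#' @param bottleneck bottleneck width.
#' @param width_scale divides all widths.
#' @return a `unet_config` list.
#' @export
unet_config <- function(input_size = c(256L, 256L), channels = 3L,
                        filters = c(64L, 128L, 256L, 512L),
                        bottleneck = 1024L, width_scale = 1L) {
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  if (any(input_size %% 16L != 0L))
    stop("input dimensions must be divisible by 16 (four 2x2 poolings); got ",
         paste(input_size, collapse = "x"))
  filters <- as.integer(filters / width_scale)
  bottleneck <- as.integer(bottleneck / width_scale)
  stopifnot(length(filters) == 4L, all(filters >= 1), bottleneck >= 1)
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 filters = filters, bottleneck = bottleneck),
            class = "unet_config")
}

conv_params <- function(kh, kw, cin, cout) kh * kw * cin * cout + cout

shape_str <- function(h, w, c) sprintf("(None, %d, %d, %d)", h, w, c)

#' Build a U-Net model
#'
#' Constructs the layer specification (name, output shape, parameter count,
#' kernel, activation per layer; convolution counts follow the closed form
#' kh*kw*c_in*c_out + c_out, pooling/upsampling/concatenation carry none)
#' and He-initialized weights.
#'
#' @param cfg a [unet_config()].
#' @param seed seed for weight initialization.
#' @return a `unet_model` with elements `spec` (a `model_spec` data frame),
#'   `params`, and `cfg`.
#' @export
build_unet <- function(cfg = unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  f <- cfg$filters; fb <- cfg$bottleneck
  h <- cfg$input_size[1]; w <- cfg$input_size[2]; cin <- cfg$channels
  rows <- list(list("InputLayer", shape_str(h, w, cin), 0L, "-", "-"))
  add <- function(name, hh, ww, cc, pars, kern, act)
    rows[[length(rows) + 1L]] <<- list(name, shape_str(hh, ww, cc),
                                       as.numeric(pars), kern, act)
  ci <- cin; hh <- h; ww <- w; nconv <- 0L
  for (b in 1:4) {
    for (s in 1:2) {
      nconv <- nconv + 1L
      add(sprintf("Conv2D_%d", nconv), hh, ww, f[b],
          conv_params(3, 3, ci, f[b]), "(3, 3)", "ReLU")
      ci <- f[b]
    }
    hh <- hh / 2; ww <- ww / 2
    add(sprintf("MaxPooling2D_%d", b), hh, ww, f[b], 0, "(2, 2)", "-")
  }
  for (s in 1:2) {
    nconv <- nconv + 1L
    add(sprintf("Conv2D_%d", nconv), hh, ww, fb,
        conv_params(3, 3, ci, fb), "(3, 3)", "ReLU")
    ci <- fb
  }
  for (b in 4:1) {
    hh <- hh * 2; ww <- ww * 2
    add(sprintf("UpSampling2D_%d", 5L - b), hh, ww, ci, 0, "(2, 2)", "-")
    add(sprintf("Concatenate_%d", 5L - b), hh, ww, ci + f[b], 0, "-", "-")
    ci <- ci + f[b]
    for (s in 1:2) {
      nconv <- nconv + 1L
      add(sprintf("Conv2D_%d", nconv), hh, ww, f[b],
          conv_params(3, 3, ci, f[b]), "(3, 3)", "ReLU")
      ci <- f[b]
    }
  }
  nconv <- nconv + 1L
  add(sprintf("Conv2D_%d", nconv), hh, ww, 1L, conv_params(1, 1, ci, 1L),
      "(1, 1)", "Sigmoid")
  spec <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], output_shape = r[[2]], params = r[[3]],
               kernel = r[[4]], activation = r[[5]],
               stringsAsFactors = FALSE)))
  class(spec) <- c("model_spec", "data.frame")
  params <- with_seed(seed, {
    p <- list()
    nm <- c("e1a", "e1b", "e2a", "e2b", "e3a", "e3b", "e4a", "e4b",
            "ba", "bb", "d4a", "d4b", "d3a", "d3b", "d2a", "d2b",
            "d1a", "d1b")
    cins <- c(cin, f[1], f[1], f[2], f[2], f[3], f[3], f[4],
              f[4], fb, fb + f[4], f[4], f[4] + f[3], f[3],
              f[3] + f[2], f[2], f[2] + f[1], f[1])
    couts <- c(f[1], f[1], f[2], f[2], f[3], f[3], f[4], f[4],
               fb, fb, f[4], f[4], f[3], f[3], f[2], f[2], f[1], f[1])
    for (i in seq_along(nm)) {
      p[[paste0(nm[i], "_w")]] <- he_conv(3, 3, cins[i], couts[i])
      p[[paste0(nm[i], "_b")]] <- rep(0, couts[i])
    }
    p$out_w <- he_conv(1, 1, f[1], 1L)
    p$out_b <- 0
    p
  })
  structure(list(spec = spec, params = params, cfg = cfg, history = NULL),
            class = c("unet_model", "cnn_model"))
}

#' Total trainable parameters of a model specification
#'
#' Sums the per-layer closed-form counts; independent of weight values.
#'
#' @param spec a `model_spec` data frame, or a model carrying one in
#'   `$spec`.
#' @return integer-valued numeric total.
#' @export
count_trainable_params <- function(spec) {
  if (is.list(spec) && !is.data.frame(spec) && !is.null(spec$spec))
    spec <- spec$spec
  stopifnot(is.data.frame(spec), "params" %in% names(spec))
  sum(spec$params)
}

unet_forward <- function(p, x) {
  cache <- list(x = x)
  a1 <- relu(.conv_fwd(x, p$e1a_w, p$e1a_b, 1L)); cache$a1 <- a1
  a1b <- relu(.conv_fwd(a1, p$e1b_w, p$e1b_b, 1L)); cache$a1b <- a1b
  pl1 <- .maxpool_fwd(a1b); cache$pl1 <- pl1
  a2 <- relu(.conv_fwd(pl1$y, p$e2a_w, p$e2a_b, 1L)); cache$a2 <- a2
  a2b <- relu(.conv_fwd(a2, p$e2b_w, p$e2b_b, 1L)); cache$a2b <- a2b
  pl2 <- .maxpool_fwd(a2b); cache$pl2 <- pl2
  a3 <- relu(.conv_fwd(pl2$y, p$e3a_w, p$e3a_b, 1L)); cache$a3 <- a3
  a3b <- relu(.conv_fwd(a3, p$e3b_w, p$e3b_b, 1L)); cache$a3b <- a3b
  pl3 <- .maxpool_fwd(a3b); cache$pl3 <- pl3
  a4 <- relu(.conv_fwd(pl3$y, p$e4a_w, p$e4a_b, 1L)); cache$a4 <- a4
  a4b <- relu(.conv_fwd(a4, p$e4b_w, p$e4b_b, 1L)); cache$a4b <- a4b
  pl4 <- .maxpool_fwd(a4b); cache$pl4 <- pl4
  b1 <- relu(.conv_fwd(pl4$y, p$ba_w, p$ba_b, 1L)); cache$b1 <- b1
  b2 <- relu(.conv_fwd(b1, p$bb_w, p$bb_b, 1L)); cache$b2 <- b2
  u4 <- .upsample2_fwd(b2); c4 <- cat_channels(u4, a4b); cache$c4 <- c4
  d4 <- relu(.conv_fwd(c4, p$d4a_w, p$d4a_b, 1L)); cache$d4 <- d4
  d4b <- relu(.conv_fwd(d4, p$d4b_w, p$d4b_b, 1L)); cache$d4b <- d4b
  u3 <- .upsample2_fwd(d4b); c3 <- cat_channels(u3, a3b); cache$c3 <- c3
  d3 <- relu(.conv_fwd(c3, p$d3a_w, p$d3a_b, 1L)); cache$d3 <- d3
  d3b <- relu(.conv_fwd(d3, p$d3b_w, p$d3b_b, 1L)); cache$d3b <- d3b
  u2 <- .upsample2_fwd(d3b); c2 <- cat_channels(u2, a2b); cache$c2 <- c2
  d2 <- relu(.conv_fwd(c2, p$d2a_w, p$d2a_b, 1L)); cache$d2 <- d2
  d2b <- relu(.conv_fwd(d2, p$d2b_w, p$d2b_b, 1L)); cache$d2b <- d2b
  u1 <- .upsample2_fwd(d2b); c1 <- cat_channels(u1, a1b); cache$c1 <- c1
  d1 <- relu(.conv_fwd(c1, p$d1a_w, p$d1a_b, 1L)); cache$d1 <- d1
  d1b <- relu(.conv_fwd(d1, p$d1b_w, p$d1b_b, 1L)); cache$d1b <- d1b
  z <- .conv_fwd(d1b, p$out_w, p$out_b, 0L)
  list(z = z, cache = cache)
}

unet_backward <- function(p, cache, dz) {
  g <- list()
  bw <- .conv_bwd(cache$d1b, p$out_w, dz, 0L)
  g$out_w <- bw$dw; g$out_b <- bw$db
  dd1b <- relu_bwd(bw$dx, cache$d1b)
  bw <- .conv_bwd(cache$d1, p$d1b_w, dd1b, 1L)
  g$d1b_w <- bw$dw; g$d1b_b <- bw$db
  dd1 <- relu_bwd(bw$dx, cache$d1)
  bw <- .conv_bwd(cache$c1, p$d1a_w, dd1, 1L)
  g$d1a_w <- bw$dw; g$d1a_b <- bw$db
  sc <- split_channels(bw$dx, dim(cache$d2b)[3])
  dd2b <- relu_bwd(.upsample2_bwd(sc$a), cache$d2b)
  da1b_skip <- sc$b
  bw <- .conv_bwd(cache$d2, p$d2b_w, dd2b, 1L)
  g$d2b_w <- bw$dw; g$d2b_b <- bw$db
  dd2 <- relu_bwd(bw$dx, cache$d2)
  bw <- .conv_bwd(cache$c2, p$d2a_w, dd2, 1L)
  g$d2a_w <- bw$dw; g$d2a_b <- bw$db
  sc <- split_channels(bw$dx, dim(cache$d3b)[3])
  dd3b <- relu_bwd(.upsample2_bwd(sc$a), cache$d3b)
  da2b_skip <- sc$b
  bw <- .conv_bwd(cache$d3, p$d3b_w, dd3b, 1L)
  g$d3b_w <- bw$dw; g$d3b_b <- bw$db
  dd3 <- relu_bwd(bw$dx, cache$d3)
  bw <- .conv_bwd(cache$c3, p$d3a_w, dd3, 1L)
  g$d3a_w <- bw$dw; g$d3a_b <- bw$db
  sc <- split_channels(bw$dx, dim(cache$d4b)[3])
  dd4b <- relu_bwd(.upsample2_bwd(sc$a), cache$d4b)
  da3b_skip <- sc$b
  bw <- .conv_bwd(cache$d4, p$d4b_w, dd4b, 1L)
  g$d4b_w <- bw$dw; g$d4b_b <- bw$db
  dd4 <- relu_bwd(bw$dx, cache$d4)
  bw <- .conv_bwd(cache$c4, p$d4a_w, dd4, 1L)
  g$d4a_w <- bw$dw; g$d4a_b <- bw$db
  sc <- split_channels(bw$dx, dim(cache$b2)[3])
  db2 <- relu_bwd(.upsample2_bwd(sc$a), cache$b2)
  da4b_skip <- sc$b
  bw <- .conv_bwd(cache$b1, p$bb_w, db2, 1L)
  g$bb_w <- bw$dw; g$bb_b <- bw$db
  db1 <- relu_bwd(bw$dx, cache$b1)
  bw <- .conv_bwd(cache$pl4$y, p$ba_w, db1, 1L)
  g$ba_w <- bw$dw; g$ba_b <- bw$db
  da4b <- .maxpool_bwd(bw$dx, cache$pl4$which, dim(cache$a4b)) + da4b_skip
  da4b <- relu_bwd(da4b, cache$a4b)
  bw <- .conv_bwd(cache$a4, p$e4b_w, da4b, 1L)
  g$e4b_w <- bw$dw; g$e4b_b <- bw$db
  da4 <- relu_bwd(bw$dx, cache$a4)
  bw <- .conv_bwd(cache$pl3$y, p$e4a_w, da4, 1L)
  g$e4a_w <- bw$dw; g$e4a_b <- bw$db
  da3b <- .maxpool_bwd(bw$dx, cache$pl3$which, dim(cache$a3b)) + da3b_skip
  da3b <- relu_bwd(da3b, cache$a3b)
  bw <- .conv_bwd(cache$a3, p$e3b_w, da3b, 1L)
  g$e3b_w <- bw$dw; g$e3b_b <- bw$db
  da3 <- relu_bwd(bw$dx, cache$a3)
  bw <- .conv_bwd(cache$pl2$y, p$e3a_w, da3, 1L)
  g$e3a_w <- bw$dw; g$e3a_b <- bw$db
  da2b <- .maxpool_bwd(bw$dx, cache$pl2$which, dim(cache$a2b)) + da2b_skip
  da2b <- relu_bwd(da2b, cache$a2b)
  bw <- .conv_bwd(cache$a2, p$e2b_w, da2b, 1L)
  g$e2b_w <- bw$dw; g$e2b_b <- bw$db
  da2 <- relu_bwd(bw$dx, cache$a2)
  bw <- .conv_bwd(cache$pl1$y, p$e2a_w, da2, 1L)
  g$e2a_w <- bw$dw; g$e2a_b <- bw$db
  da1b <- .maxpool_bwd(bw$dx, cache$pl1$which, dim(cache$a1b)) + da1b_skip
  da1b <- relu_bwd(da1b, cache$a1b)
  bw <- .conv_bwd(cache$a1, p$e1b_w, da1b, 1L)
  g$e1b_w <- bw$dw; g$e1b_b <- bw$db
  da1 <- relu_bwd(bw$dx, cache$a1)
  bw <- .conv_bwd(cache$x, p$e1a_w, da1, 1L)
  g$e1a_w <- bw$dw; g$e1a_b <- bw$db
  g
}

#' Train the segmentation network
#'
#' Minibatch Adam training with binary cross-entropy on pixel logits,
#' optional on-the-fly affine augmentation of training samples (image and
#' mask transformed together; validation is never augmented), early
#' stopping on validation loss with best-weight restore, and learning-rate
#' reduction on plateau.
#'
#' @param model a [build_unet()] model.
#' @param images list of unit-scale `H x W x 3` arrays matching the model
#'   input size.
#' @param masks list of binary `H x W` matrices aligned with `images`.
#' @param policy a [training_policy()].
#' @param seed seed for shuffling, augmentation and validation split.
#' @param val_frac fraction held out for validation.
#' @param verbose print per-epoch progress.
#' @return the model with trained `params` and a `history` data frame
#'   (epoch, loss, val_loss, lr).
#' @export
train_segmenter <- function(model, images, masks,
                            policy = training_policy(), seed = 1L,
                            val_frac = 0.2, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), length(images) >= 1,
            length(images) == length(masks))
  for (i in seq_along(images)) {
    di <- dim(images[[i]]); dm <- dim(masks[[i]])
    if (!all(di[1:2] == dm))
      stop("image/mask shape mismatch at sample ", i)
    if (!all(masks[[i]] %in% c(0, 1)))
      stop("masks must be binary")
  }
  p <- model$params
  st <- adam_init(p)
  ctl <- policy_controller(policy)
  n <- length(images)
  hist_rows <- list()
  with_seed(seed, {
    val_idx <- sample.int(n, max(1L, round(val_frac * n)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0L) stop("empty training set")
    for (epoch in seq_len(policy$max_epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1, length(ord), by = policy$batch_size)) {
        bi <- ord[s:min(s + policy$batch_size - 1L, length(ord))]
        xs <- vector("list", length(bi)); ys <- vector("list", length(bi))
        for (k in seq_along(bi)) {
          xi <- images[[bi[k]]]; yi <- masks[[bi[k]]]
          if (policy$augment) {
            tr <- sample_augmentation(sample.int(.Machine$integer.max, 1L))
            xi <- apply_augmentation(image_rgb(xi, "unit"), tr)
            yi <- apply_augmentation(yi, tr)
          }
          xs[[k]] <- unclass(xi)
          ys[[k]] <- array(yi, c(dim(yi), 1L))
        }
        xb <- stack_batch(xs)
        yb <- stack_batch(ys)
        fw <- unet_forward(p, xb)
        l <- bce_from_logits(fw$z, yb)
        g <- unet_backward(p, fw$cache, l$dz)
        if (policy$l2 > 0)
          for (k in names(g))
            if (endsWith(k, "_w")) g[[k]] <- g[[k]] + 2 * policy$l2 * p[[k]]
        up <- adam_step(p, g, st, ctl$lr, policy$beta1, policy$beta2,
                        policy$epsilon)
        p <- up$params; st <- up$state
        ep_loss <- ep_loss + l$loss; nb <- nb + 1L
      }
      vl <- 0; nv <- 0L
      for (s in seq(1, length(val_idx), by = policy$batch_size)) {
        bi <- val_idx[s:min(s + policy$batch_size - 1L, length(val_idx))]
        xb <- stack_batch(lapply(images[bi], identity))
        yb <- stack_batch(lapply(masks[bi], function(m)
          array(m, c(dim(m), 1L))))
        vl <- vl + bce_from_logits(unet_forward(p, xb)$z, yb)$loss
        nv <- nv + 1L
      }
      vl <- vl / nv
      hist_rows[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / nb,
                                       val_loss = vl, lr = ctl$lr)
      if (verbose)
        message(sprintf("epoch %d loss %.4f val %.4f lr %.2g",
                        epoch, ep_loss / nb, vl, ctl$lr))
      ctl$update(epoch, vl, p)
      if (ctl$stop) break
    }
  })
  if (!is.null(ctl$best_params)) p <- ctl$best_params
  model$params <- p
  model$history <- do.call(rbind, hist_rows)
  model$best_epoch <- ctl$best_epoch
  model
}

#' Predict a probability map and binary mask
#'
#' @param model a trained `unet_model`.
#' @param img unit-scale `H x W x 3` array (or [image_rgb()]) at the model
#'   input size.
#' @param tau probability threshold in (0, 1); the mask is `prob >= tau`.
#' @return list with `prob` (matrix in \[0, 1\]) and `mask` (binary matrix).
#' @export
predict_mask <- function(model, img, tau = 0.5) {
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly inside (0, 1)")
  a <- unclass(img)
  if (img_scale(img) == "byte" && max(a) > 1) a <- a / 255
  d <- dim(a)
  if (!all(d[1:2] == model$cfg$input_size))
    stop("input size ", paste(d[1:2], collapse = "x"),
         " does not match model input ",
         paste(model$cfg$input_size, collapse = "x"))
  x <- array(a, c(d, 1L))
  z <- unet_forward(model$params, x)$z
  prob <- sigmoid(z[, , 1, 1])
  list(prob = prob, mask = (prob >= tau) * 1L)
}
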