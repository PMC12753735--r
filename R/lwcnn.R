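# Lightweight CNN for nine-class single-cell classification: four valid
# 3x3 conv + 2x2 max-pool stages (32-64-128-256), dropout after pools 2-4,
# flatten -> dense 256 -> dense softmax head. 653,129 trainable parameters
# at the reference configuration.

#' Lightweight classifier configuration
#'
#' @param input_size square input size (64 is forced by the reference shape
#'   ladder: a valid 3x3 convolution maps 64 to 62 and the ladder ends at
#'   2 x 2 x 256, flattening to 1024).
#' @param channels input channels.
#' @param filters conv ladder widths.
#' @param dense hidden dense width.
#' @param classes number of output classes.
#' @param dropout_conv dropout rate after pools 2-4.
#' @param dropout_dense dropout rate before the output layer.
#' @param extra_conv_blocks 0 or 2 extra same-padded 3x3 conv blocks before
#'   flattening (architecture-ablation variant).
#' @return an `lwcnn_config` list.
#' @export
lwcnn_config <- function(input_size = 64L, channels = 3L,
                         filters = c(32L, 64L, 128L, 256L), dense = 256L,
                         classes = 9L, dropout_conv = 0.25,
                         dropout_dense = 0.5, extra_conv_blocks = 0L) {
  stopifnot(length(filters) == 4L, extra_conv_blocks %in% c(0L, 2L))
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 filters = as.integer(filters), dense = as.integer(dense),
                 classes = as.integer(classes),
                 dropout_conv = dropout_conv, dropout_dense = dropout_dense,
                 extra_conv_blocks = as.integer(extra_conv_blocks)),
            class = "lwcnn_config")
}

# reference shape ladder at the standard configuration (feature-map sizes
# after each conv/pool stage for a 64 px input)
LWCNN_REFERENCE_SHAPES <- data.frame(
  name = c("Conv2D", "MaxPooling2D", "Conv2D", "MaxPooling2D", "Dropout",
           "Conv2D", "MaxPooling2D", "Dropout", "Conv2D", "MaxPooling2D",
           "Dropout", "Flatten", "Dense", "Dropout", "Dense"),
  size = c(62, 31, 29, 14, 14, 12, 6, 6, 4, 2, 2, 1024, 256, 256, 9),
  stringsAsFactors = FALSE)

#' Build the lightweight classifier
#'
#' Constructs the layer specification and He-initialized weights. At the
#' standard configuration the computed shape ladder is verified against the
#' reference ladder and any mismatch is reported naming the first divergent
#' layer; the total parameter count is 653,129.
#'
#' @param cfg an [lwcnn_config()].
#' @param seed seed for weight initialization.
#' @return an `lwcnn_model` with `spec`, `params`, `cfg`.
#' @export
build_lwcnn <- function(cfg = lwcnn_config(), seed = 1L) {
  stopifnot(inherits(cfg, "lwcnn_config"))
  f <- cfg$filters
  s <- cfg$input_size
  ci <- cfg$channels
  rows <- list()
  add <- function(name, shape, pars, kern, act)
    rows[[length(rows) + 1L]] <<- list(name, shape, as.numeric(pars), kern,
                                       act)
  sizes <- numeric(0)
  for (b in 1:4) {
    s <- s - 2L
    add("Conv2D", shape_str(s, s, f[b]), conv_params(3, 3, ci, f[b]),
        "(3, 3)", "ReLU"); sizes <- c(sizes, s)
    ci <- f[b]
    s <- s %/% 2L
    add("MaxPooling2D", shape_str(s, s, f[b]), 0, "(2, 2)", "-")
    sizes <- c(sizes, s)
    if (b >= 2) {
      add("Dropout", shape_str(s, s, f[b]), 0, "-", "-")
      sizes <- c(sizes, s)
    }
  }
  if (cfg$extra_conv_blocks > 0)
    for (e in seq_len(cfg$extra_conv_blocks)) {
      add("Conv2D", shape_str(s, s, ci), conv_params(3, 3, ci, ci),
          "(3, 3)", "ReLU")
      sizes <- c(sizes, s)
    }
  flat <- s * s * ci
  add("Flatten", sprintf("(None, %d)", flat), 0, "-", "-")
  sizes <- c(sizes, flat)
  add("Dense", sprintf("(None, %d)", cfg$dense),
      flat * cfg$dense + cfg$dense, "-", "ReLU")
  sizes <- c(sizes, cfg$dense)
  add("Dropout", sprintf("(None, %d)", cfg$dense), 0, "-", "-")
  sizes <- c(sizes, cfg$dense)
  add("Dense", sprintf("(None, %d)", cfg$classes),
      cfg$dense * cfg$classes + cfg$classes, "-", "Softmax")
  sizes <- c(sizes, cfg$classes)
  spec <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], output_shape = r[[2]], params = r[[3]],
               kernel = r[[4]], activation = r[[5]],
               stringsAsFactors = FALSE)))
  class(spec) <- c("model_spec", "data.frame")
  if (cfg$input_size == 64L && identical(cfg$filters, c(32L, 64L, 128L, 256L)) &&
      cfg$dense == 256L && cfg$classes == 9L && cfg$extra_conv_blocks == 0L) {
    ref <- LWCNN_REFERENCE_SHAPES
    for (i in seq_len(nrow(ref))) {
      if (spec$name[i] != ref$name[i] || sizes[i] != ref$size[i])
        stop("layer ", i, " (", spec$name[i],
             ") diverges from the reference shape ladder")
    }
  }
  params <- with_seed(seed, {
    p <- list()
    ci <- cfg$channels
    for (b in 1:4) {
      p[[paste0("c", b, "_w")]] <- he_conv(3, 3, ci, f[b])
      p[[paste0("c", b, "_b")]] <- rep(0, f[b])
      ci <- f[b]
    }
    if (cfg$extra_conv_blocks > 0)
      for (e in seq_len(cfg$extra_conv_blocks)) {
        p[[paste0("x", e, "_w")]] <- he_conv(3, 3, ci, ci)
        p[[paste0("x", e, "_b")]] <- rep(0, ci)
      }
    p$fc1_w <- he_dense(flat, cfg$dense)
    p$fc1_b <- rep(0, cfg$dense)
    p$fc2_w <- he_dense(cfg$dense, cfg$classes)
    p$fc2_b <- rep(0, cfg$classes)
    p
  })
  structure(list(spec = spec, params = params, cfg = cfg, history = NULL,
                 classes = CELL_CLASSES[seq_len(cfg$classes)]),
            class = c("lwcnn_model", "cnn_model"))
}

# forward pass; drop = list of dropout masks (NULL = inference)
lwcnn_forward <- function(p, x, cfg, drop = NULL) {
  cache <- list(x = x)
  a <- x
  for (b in 1:4) {
    z <- .conv_fwd(a, p[[paste0("c", b, "_w")]], p[[paste0("c", b, "_b")]],
                   0L)
    a <- relu(z)
    cache[[paste0("a", b)]] <- a
    pl <- .maxpool_fwd(a)
    cache[[paste0("pl", b)]] <- pl
    a <- pl$y
    if (b >= 2 && !is.null(drop)) a <- a * drop[[b - 1L]]
    cache[[paste0("pd", b)]] <- a
  }
  if (cfg$extra_conv_blocks > 0)
    for (e in seq_len(cfg$extra_conv_blocks)) {
      z <- .conv_fwd(a, p[[paste0("x", e, "_w")]], p[[paste0("x", e, "_b")]],
                     1L)
      a <- relu(z)
      cache[[paste0("xa", e)]] <- a
    }
  d <- dim(a)
  N <- d[4]
  X <- matrix(a, nrow = prod(d[1:3]), ncol = N)
  cache$flat <- t(X)                      # N x flat
  h <- cache$flat %*% p$fc1_w
  h <- sweep(h, 2, p$fc1_b, "+")
  h <- relu(h)
  cache$h_pre_drop <- h
  if (!is.null(drop)) h <- h * drop[[4L]]
  cache$h <- h
  z2 <- sweep(h %*% p$fc2_w, 2, p$fc2_b, "+")
  list(logits = z2, cache = cache)
}

lwcnn_backward <- function(p, cache, cfg, dlogits, drop = NULL) {
  g <- list()
  g$fc2_w <- t(cache$h) %*% dlogits
  g$fc2_b <- colSums(dlogits)
  dh <- dlogits %*% t(p$fc2_w)
  if (!is.null(drop)) dh <- dh * drop[[4L]]
  dh <- relu_bwd(dh, cache$h_pre_drop)
  g$fc1_w <- t(cache$flat) %*% dh
  g$fc1_b <- colSums(dh)
  dflat <- dh %*% t(p$fc1_w)              # N x flat
  top <- cache$pd4
  if (cfg$extra_conv_blocks > 0) top <- cache[[paste0("xa",
                                                      cfg$extra_conv_blocks)]]
  d <- dim(top)
  da <- array(t(dflat), d)
  if (cfg$extra_conv_blocks > 0)
    for (e in rev(seq_len(cfg$extra_conv_blocks))) {
      da <- relu_bwd(da, cache[[paste0("xa", e)]])
      xin <- if (e == 1) cache$pd4 else cache[[paste0("xa", e - 1L)]]
      bw <- .conv_bwd(xin, p[[paste0("x", e, "_w")]], da, 1L)
      g[[paste0("x", e, "_w")]] <- bw$dw
      g[[paste0("x", e, "_b")]] <- bw$db
      da <- bw$dx
    }
  for (b in 4:1) {
    if (b >= 2 && !is.null(drop)) da <- da * drop[[b - 1L]]
    da <- .maxpool_bwd(da, cache[[paste0("pl", b)]]$which,
                       dim(cache[[paste0("a", b)]]))
    da <- relu_bwd(da, cache[[paste0("a", b)]])
    xin <- if (b == 1) cache$x else cache[[paste0("pd", b - 1L)]]
    bw <- .conv_bwd(xin, p[[paste0("c", b, "_w")]], da, 0L)
    g[[paste0("c", b, "_w")]] <- bw$dw
    g[[paste0("c", b, "_b")]] <- bw$db
    da <- bw$dx
  }
  g
}

lwcnn_drop_masks <- function(cfg, dims, N) {
  keep_c <- 1 - cfg$dropout_conv
  keep_d <- 1 - cfg$dropout_dense
  masks <- vector("list", 4L)
  for (i in 1:3) {
    d <- dims[[i]]
    masks[[i]] <- array((runif(prod(d) * N) < keep_c) / keep_c, c(d, N))
  }
  masks[[4L]] <- matrix((runif(N * cfg$dense) < keep_d) / keep_d, N,
                        cfg$dense)
  masks
}

# spatial dims of the three post-pool dropout sites for a given config
lwcnn_drop_dims <- function(cfg) {
  s <- cfg$input_size
  dims <- list()
  for (b in 1:4) {
    s <- (s - 2L) %/% 2L
    if (b >= 2) dims[[b - 1L]] <- c(s, s, cfg$filters[b])
  }
  dims
}

#' Stratified k-fold cross-validation splits
#'
#' The k test folds partition the sample index set with per-class
#' proportions preserved to within one sample; within each fold the
#' remaining data are split train:validation (default 75:25) per class.
#'
#' @param labels class label vector (factor or character).
#' @param k number of folds.
#' @param seed shuffling seed.
#' @param val_frac validation share of the non-test data.
#' @return list of `fold_split` objects with `fold`, `train`, `val`,
#'   `test` index vectors.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L, val_frac = 0.25) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has fewer than k = ", k,
         " samples")
  with_seed(seed, {
    # spread per-class remainders over the currently lightest folds so the
    # k test folds end up within one sample of n/k overall
    load <- rep(0L, k)
    chunks <- lapply(names(tab), function(cl) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      base <- n_c %/% k
      extra <- order(load, seq_len(k))[seq_len(n_c %% k)]
      sizes <- rep(base, k)
      sizes[extra] <- sizes[extra] + 1L
      load <<- load + sizes
      split(idx, rep(seq_len(k), times = sizes))
    })
    lapply(seq_len(k), function(fi) {
      test <- sort(unlist(lapply(chunks, `[[`, fi)))
      rest_by_class <- lapply(chunks, function(ch)
        unlist(ch[setdiff(seq_len(k), fi)], use.names = FALSE))
      val <- sort(unlist(lapply(rest_by_class, function(idx)
        idx[seq_len(max(1L, round(val_frac * length(idx))))])))
      train <- sort(setdiff(unlist(rest_by_class), val))
      structure(list(fold = fi, train = train, val = val, test = test),
                class = "fold_split")
    })
  })
}

classifier_epoch_metrics <- function(true, pred) {
  cm <- confusion_matrix(true, pred, levels = sort(unique(c(true, pred))))
  mm <- multiclass_metrics(cm)
  data.frame(accuracy = mm$accuracy, precision = mm$precision,
             recall = mm$recall, f1 = mm$f1)
}

#' Train the classifier under cross-validation
#'
#' Trains one model per fold on that fold's training split only (with
#' optional affine augmentation), monitors the validation split for early
#' stopping and learning-rate scheduling, and evaluates the fold's test
#' split. Per-epoch accuracy/loss/precision/recall/F1 on train and
#' validation are recorded. Folds sharing indices are rejected.
#'
#' @param model a [build_lwcnn()] model (template; each fold re-initializes
#'   from `seed + fold`).
#' @param x list of unit-scale `S x S x 3` arrays (or a 4D array).
#' @param y class label vector.
#' @param folds list of `fold_split`s from [stratified_kfold()].
#' @param policy a [training_policy()].
#' @param seed base seed; fold f uses `seed + f`.
#' @param verbose print progress.
#' @return an `lwcnn_cv` list: per-fold trained models, histories, test
#'   predictions, and a per-fold metrics data frame.
#' @export
train_classifier <- function(model, x, y, folds,
                             policy = training_policy(), seed = 1L,
                             verbose = FALSE) {
  stopifnot(inherits(model, "lwcnn_model"))
  if (is.array(x) && length(dim(x)) == 4L)
    x <- lapply(seq_len(dim(x)[4]), function(i) x[, , , i])
  y <- as.character(y)
  stopifnot(length(x) == length(y))
  for (fs in folds) {
    if (length(intersect(fs$train, fs$val)) || length(intersect(fs$train,
                                                                fs$test)) ||
        length(intersect(fs$val, fs$test)))
      stop("fold leakage: overlapping train/val/test indices in fold ",
           fs$fold)
  }
  cls <- model$classes
  onehot <- function(lab) {
    Y <- matrix(0, length(lab), length(cls))
    Y[cbind(seq_along(lab), match(lab, cls))] <- 1
    Y
  }
  dims <- lwcnn_drop_dims(model$cfg)
  out <- list()
  for (fs in folds) {
    if (length(fs$train) == 0L || length(fs$val) == 0L)
      stop("fold ", fs$fold, " has an empty train or validation split")
    fm <- build_lwcnn(model$cfg, seed = seed + fs$fold)
    p <- fm$params
    st <- adam_init(p)
    ctl <- policy_controller(policy)
    hist_rows <- list()
    with_seed(seed + 1000L * fs$fold, {
      for (epoch in seq_len(policy$max_epochs)) {
        ord <- sample(fs$train)
        ep_loss <- 0; nb <- 0L
        tr_pred <- character(0); tr_true <- character(0)
        for (s in seq(1, length(ord), by = policy$batch_size)) {
          bi <- ord[s:min(s + policy$batch_size - 1L, length(ord))]
          xs <- lapply(bi, function(i) {
            xi <- x[[i]]
            if (policy$augment) {
              tr <- sample_augmentation(sample.int(.Machine$integer.max, 1L))
              xi <- unclass(apply_augmentation(image_rgb(xi, "unit"), tr))
            }
            xi
          })
          xb <- stack_batch(xs)
          Yb <- onehot(y[bi])
          drop <- lwcnn_drop_masks(model$cfg, dims, length(bi))
          fw <- lwcnn_forward(p, xb, model$cfg, drop)
          l <- cce_from_logits(fw$logits, Yb)
          g <- lwcnn_backward(p, fw$cache, model$cfg, l$dz, drop)
          if (policy$l2 > 0)
            for (k in names(g))
              if (endsWith(k, "_w") && !startsWith(k, "fc"))
                g[[k]] <- g[[k]] + 2 * policy$l2 * p[[k]]
          up <- adam_step(p, g, st, ctl$lr, policy$beta1, policy$beta2,
                          policy$epsilon)
          p <- up$params; st <- up$state
          ep_loss <- ep_loss + l$loss; nb <- nb + 1L
          tr_pred <- c(tr_pred, cls[max.col(l$p)])
          tr_true <- c(tr_true, y[bi])
        }
        ev <- lwcnn_evaluate(p, x, y, fs$val, model$cfg, cls,
                             policy$batch_size)
        trm <- classifier_epoch_metrics(tr_true, tr_pred)
        hist_rows[[epoch]] <- cbind(
          data.frame(epoch = epoch, loss = ep_loss / nb,
                     val_loss = ev$loss, lr = ctl$lr),
          stats::setNames(trm, paste0("train_", names(trm))),
          stats::setNames(ev$metrics, paste0("val_", names(ev$metrics))))
        if (verbose)
          message(sprintf("fold %d epoch %d loss %.3f val %.3f acc %.3f",
                          fs$fold, epoch, ep_loss / nb, ev$loss,
                          ev$metrics$accuracy))
        ctl$update(epoch, ev$loss, p)
        if (ctl$stop) break
      }
    })
    if (!is.null(ctl$best_params)) p <- ctl$best_params
    fm$params <- p
    fm$history <- do.call(rbind, hist_rows)
    te <- lwcnn_evaluate(p, x, y, fs$test, model$cfg, cls,
                         policy$batch_size)
    out[[fs$fold]] <- list(model = fm, fold = fs$fold,
                           test_metrics = te$metrics,
                           test_pred = te$pred, test_true = y[fs$test],
                           test_proba = te$proba, test_idx = fs$test)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  per_fold <- do.call(rbind, lapply(out, function(o)
    cbind(data.frame(fold = o$fold), o$test_metrics)))
  structure(list(folds = out, per_fold = per_fold), class = "lwcnn_cv")
}

lwcnn_evaluate <- function(p, x, y, idx, cfg, cls, batch_size = 32L) {
  if (length(idx) == 0L) stop("empty evaluation index set")
  loss <- 0; nb <- 0L
  pred <- character(0)
  proba <- NULL
  onehot <- function(lab) {
    Y <- matrix(0, length(lab), length(cls))
    Y[cbind(seq_along(lab), match(lab, cls))] <- 1
    Y
  }
  for (s in seq(1, length(idx), by = batch_size)) {
    bi <- idx[s:min(s + batch_size - 1L, length(idx))]
    xb <- stack_batch(x[bi])
    fw <- lwcnn_forward(p, xb, cfg, drop = NULL)
    l <- cce_from_logits(fw$logits, onehot(y[bi]))
    loss <- loss + l$loss; nb <- nb + 1L
    pred <- c(pred, cls[max.col(l$p)])
    proba <- rbind(proba, l$p)
  }
  colnames(proba) <- cls
  list(loss = loss / nb, pred = pred, proba = proba,
       metrics = classifier_epoch_metrics(y[idx], pred))
}

#' Class probabilities for one region of interest
#'
#' @param model a trained `lwcnn_model` (or one fold's model from
#'   [train_classifier()]).
#' @param roi unit-scale `S x S x 3` array (or byte [image_rgb()], which is
#'   rescaled) at the model input size.
#' @return a `class_probabilities` numeric vector over the classes (sums to
#'   1), with attributes `predicted_class` and `confidence`.
#' @export
predict_proba <- function(model, roi) {
  a <- unclass(roi)
  if (img_scale(roi) == "byte" && max(a) > 1) a <- a / 255
  d <- dim(a)
  if (length(d) != 3L || d[1] != model$cfg$input_size ||
      d[2] != model$cfg$input_size)
    stop("ROI must be ", model$cfg$input_size, "x", model$cfg$input_size,
         "x3")
  x <- array(a, c(d, 1L))
  fw <- lwcnn_forward(model$params, x, model$cfg, drop = NULL)
  pr <- softmax_rows(fw$logits)[1, ]
  names(pr) <- model$classes
  structure(pr, class = "class_probabilities",
            predicted_class = model$classes[which.max(pr)],
            confidence = max(pr))
}
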