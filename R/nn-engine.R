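# Compact CNN engine shared by the U-Net and the lightweight classifier:
# He-initialized conv/dense parameters, Adam, BCE/CCE losses, and the
# training policy (early stopping with best-weight restore, learning-rate
# reduction on plateau with a floor).

he_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}
he_dense <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

relu <- function(x) x * (x > 0)
relu_bwd <- function(dy, x) dy * (x > 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# stable pixelwise binary cross-entropy from logits; returns loss and dL/dz
bce_from_logits <- function(z, y) {
  p <- sigmoid(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  list(loss = loss, dz = (p - y) / length(z))
}

# categorical cross-entropy from logits (rows = samples); one-hot Y
cce_from_logits <- function(z, Y) {
  p <- softmax_rows(z)
  loss <- -mean(log(pmax(rowSums(p * Y), 1e-12)))
  list(loss = loss, dz = (p - Y) / nrow(z), p = p)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (k in names(params)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + eps)
  }
  list(params = params, state = st)
}

#' Training policy
#'
#' Optimization and scheduling settings shared by the segmentation and
#' classification networks: Adam (learning rate 1e-3, beta1 0.9, beta2
#' 0.999, epsilon 1e-7), batch size 16, early stopping with patience 10
#' epochs and restoration of the best-validation-loss weights, learning-rate
#' reduction on plateau (factor 0.5, patience 5, floor 1e-5), and an L2
#' kernel penalty of 1e-4 on convolution weights.
#'
#' @param lr initial learning rate.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param es_patience early-stopping patience, epochs.
#' @param lr_factor,lr_patience,lr_floor plateau schedule.
#' @param l2 L2 kernel penalty on conv weights.
#' @param augment apply sampled affine augmentation to training batches.
#' @return a `training_policy` list.
#' @export
training_policy <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-7, batch_size = 16L,
                            max_epochs = 25L, es_patience = 10L,
                            lr_factor = 0.5, lr_patience = 5L,
                            lr_floor = 1e-5, l2 = 1e-4, augment = TRUE) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 es_patience = as.integer(es_patience),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 lr_floor = lr_floor, l2 = l2, augment = augment),
            class = "training_policy")
}

# plateau/early-stopping controller; monitors validation loss
policy_controller <- function(policy) {
  env <- new.env(parent = emptyenv())
  env$best <- Inf; env$best_epoch <- 0L; env$best_params <- NULL
  env$wait_es <- 0L; env$wait_lr <- 0L; env$lr <- policy$lr
  env$stop <- FALSE
  env$update <- function(epoch, val_loss, params) {
    if (val_loss < env$best - 1e-12) {
      env$best <- val_loss; env$best_epoch <- epoch
      env$best_params <- params
      env$wait_es <- 0L; env$wait_lr <- 0L
    } else {
      env$wait_es <- env$wait_es + 1L
      env$wait_lr <- env$wait_lr + 1L
      if (env$wait_lr >= policy$lr_patience) {
        env$lr <- max(env$lr * policy$lr_factor, policy$lr_floor)
        env$wait_lr <- 0L
      }
      if (env$wait_es >= policy$es_patience) env$stop <- TRUE
    }
  }
  env
}

# stack a list of H x W x C arrays into an H x W x C x N batch
stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , (c1 + 1):d[3], , drop = FALSE])
}
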