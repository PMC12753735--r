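test_that("the full U-Net reproduces the reference layer table", {
  m <- build_unet(unet_config())
  sp <- m$spec
  get <- function(nm) sp$params[sp$name == nm]
  expect_equal(get("Conv2D_1"), 1792)
  expect_equal(get("Conv2D_2"), 36928)
  expect_equal(get("Conv2D_10"), 9438208)
  expect_equal(get("Conv2D_11"), 7078400)
  expect_equal(get("Conv2D_13"), 1769728)
  expect_equal(get("Conv2D_15"), 442496)
  expect_equal(get("Conv2D_17"), 110656)
  expect_equal(get("Conv2D_19"), 65)
  expect_equal(sp$output_shape[sp$name == "InputLayer"],
               "(None, 256, 256, 3)")
  expect_equal(sp$output_shape[sp$name == "Concatenate_1"],
               "(None, 32, 32, 1536)")
  expect_equal(sp$output_shape[sp$name == "Conv2D_19"],
               "(None, 256, 256, 1)")
  expect_equal(sp$activation[sp$name == "Conv2D_19"], "Sigmoid")
  # every conv row matches the closed form kh*kw*cin*cout + cout;
  # pool/upsample/concat rows carry zero
  expect_true(all(sp$params[grepl("Pool|Up|Concat|Input", sp$name)] == 0))
  # parameter audit: initialized weights agree with the table's counts
  actual <- sum(vapply(m$params, length, 0L))
  expect_equal(actual, sum(sp$params))
})

test_that("count_trainable_params sums layer counts", {
  empty <- data.frame(name = "MaxPooling2D", output_shape = "", params = 0,
                      kernel = "", activation = "")
  expect_equal(count_trainable_params(empty), 0)
  one <- data.frame(name = "Conv2D", output_shape = "",
                    params = 3 * 3 * 3 * 64 + 64, kernel = "",
                    activation = "")
  expect_equal(count_trainable_params(one), 1792)
  expect_equal(count_trainable_params(build_lwcnn(lwcnn_config())), 653129)
})

test_that("indivisible input sizes are rejected with the rule stated", {
  expect_error(unet_config(input_size = c(100, 100)), "divisible by 16")
})

test_that("the plateau schedule halves the rate and respects the floor", {
  pol <- training_policy(lr = 1e-3, lr_patience = 2L, es_patience = 10L)
  ctl <- hemosmear:::policy_controller(pol)
  ctl$update(1, 1.0, list())           # best
  for (e in 2:5) ctl$update(e, 1.0 + e * 1e-3, list())  # plateau
  expect_equal(ctl$lr, 1e-3 * 0.5^2)   # two reductions -> 2.5e-4
  for (e in 6:9) ctl$update(e, 2, list())
  ctl$lr <- 2e-5
  ctl$update(10, 2, list()); ctl$update(11, 2, list())
  expect_gte(ctl$lr, 1e-5)             # never below the floor
})

test_that("early stopping restores the best-validation weights", {
  pol <- training_policy(es_patience = 3L)
  ctl <- hemosmear:::policy_controller(pol)
  ctl$update(1, 0.5, list(w = 1))
  ctl$update(2, 0.2, list(w = 2))      # best epoch
  ctl$update(3, 0.4, list(w = 3))
  ctl$update(4, 0.4, list(w = 4))
  ctl$update(5, 0.4, list(w = 5))
  expect_true(ctl$stop)
  expect_equal(ctl$best_epoch, 2L)
  expect_equal(ctl$best_params$w, 2)
})

test_that("binary cross-entropy vanishes at a perfect confident fit", {
  z <- array(20, c(4, 4, 1, 1))        # sigmoid(20) ~ 1
  y <- array(1, c(4, 4, 1, 1))
  expect_lt(hemosmear:::bce_from_logits(z, y)$loss, 1e-6)
})

test_that("predict_mask thresholds the probability map correctly", {
  cfg <- unet_config(input_size = c(16, 16), filters = c(2, 3, 4, 5),
                     bottleneck = 6)
  m <- build_unet(cfg, seed = 1)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  out <- predict_mask(m, image_rgb(img, "unit"), tau = 0.5)
  expect_equal(dim(out$prob), c(16L, 16L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_equal(out$mask, (out$prob >= 0.5) * 1L)
  # monotonicity: the foreground fraction never grows as tau rises
  fracs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(tau)
    mean(predict_mask(m, image_rgb(img, "unit"), tau)$mask), 0)
  expect_true(all(diff(fracs) <= 0))
  expect_error(predict_mask(m, image_rgb(img, "unit"), tau = 1.5),
               "tau")
  expect_error(predict_mask(m, image_rgb(array(0, c(32, 32, 3)), "unit")),
               "input size")
})

test_that("a tiny U-Net trains, logs history, and obeys the schedule", {
  set.seed(3)
  n <- 10
  imgs <- list(); msks <- list()
  for (i in 1:n) {
    m <- disc_mask(32, 32, sample(10:22, 1), sample(10:22, 1), 7)
    img <- array(0.2, c(32, 32, 3))
    img[, , 1] <- img[, , 1] + 0.6 * m
    imgs[[i]] <- img; msks[[i]] <- m
  }
  model <- build_unet(unet_config(input_size = c(32, 32),
                                  filters = c(4, 6, 8, 10),
                                  bottleneck = 12), seed = 1)
  pol <- training_policy(batch_size = 4L, max_epochs = 4L, augment = FALSE)
  expect_error(train_segmenter(model, imgs, msks[1:3], pol))
  expect_error(train_segmenter(model, imgs,
                               lapply(msks, function(m) m * 0.5), pol),
               "binary")
  fit <- train_segmenter(model, imgs, msks, pol, seed = 1)
  expect_s3_class(fit, "unet_model")
  h <- fit$history
  expect_true(all(c("epoch", "loss", "val_loss", "lr") %in% names(h)))
  expect_lte(nrow(h), 4L)
  expect_true(all(h$lr <= 1e-3 & h$lr >= 1e-5))
  # loss should drop on this trivially separable task
  expect_lt(h$loss[nrow(h)], h$loss[1])
})
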