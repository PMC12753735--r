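# End-to-end pipeline: synthesize -> preprocess -> segment -> separate ->
# classify -> evaluate, driven by a pipeline_config.

#' Run the full pipeline on synthetic data
#'
#' Executes the staged pipeline according to the config toggles: synthetic
#' smear generation, optional CLAHE, U-Net training and mask prediction,
#' watershed separation and ROI extraction (or direct ground-truth-centred
#' tiles when segmentation is toggled off), cross-validated classification,
#' and evaluation. Writes the resolved config snapshot, stage manifests,
#' metrics and logs into a timestamped run directory with a `latest`
#' pointer.
#'
#' @param cfg a `pipeline_config` (see [default_config()]).
#' @param out_dir parent directory for run outputs.
#' @return list with `metrics` (segmentation and classification),
#'   `run_dir`, and the per-stage objects, invisibly.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = tempfile("run")) {
  cfg <- validate_config(cfg)
  run_dir <- file.path(out_dir, format(Sys.time(), "run-%Y%m%d-%H%M%OS3"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(run_dir, file.path(out_dir, "latest"))
  save_config(cfg, file.path(run_dir, "config.yaml"))
  logf <- file.path(run_dir, "log.txt")
  log_stage <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS2"),
                   paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
  }

  # --- stage: synthetic data -------------------------------------------
  log_stage("synth: generating ", cfg$data$n_smears, " smears")
  cpc <- stats::setNames(rep(0L, 9L), CELL_CLASSES)
  cls_cycle <- rep(CELL_CLASSES, length.out = cfg$data$cells_per_smear)
  for (cl in cls_cycle) cpc[cl] <- cpc[cl] + 1L
  smears <- lapply(seq_len(cfg$data$n_smears), function(i)
    generate_smear(smear_spec(
      height = cfg$data$smear_size, width = cfg$data$smear_size,
      cells_per_class = cpc, overlap_fraction = cfg$data$overlap_fraction,
      illumination_gradient = cfg$data$illumination_gradient,
      noise_sigma = cfg$data$noise_sigma,
      seed = cfg$seed * 100L + i)))

  # --- stage: preprocessing --------------------------------------------
  pre <- lapply(smears, function(sm) {
    img <- sm$image
    if (cfg$toggles$clahe)
      img <- clahe_enhance(img, clahe_params(
        cfg$clahe$clip_limit, c(cfg$clahe$tile_rows, cfg$clahe$tile_cols),
        cfg$clahe$channels))
    unclass(normalize_unit(img))
  })
  gt_masks <- lapply(smears, function(sm) (sm$instances > 0) * 1)

  seg_metrics <- NULL
  pred_masks <- NULL
  rois <- list(); roi_labels <- character(0)
  if (cfg$toggles$segmentation) {
    # --- stage: segmentation -------------------------------------------
    log_stage("segment: training U-Net (width scale ",
              cfg$unet$width_scale, ")")
    sz <- cfg$data$smear_size
    if (sz %% 16L != 0L) stop("data.smear_size must be divisible by 16")
    model <- build_unet(unet_config(input_size = c(sz, sz),
                                    width_scale = cfg$unet$width_scale),
                        seed = cfg$seed)
    pol <- training_policy(lr = cfg$unet$lr,
                           batch_size = cfg$unet$batch_size,
                           max_epochs = cfg$unet$max_epochs,
                           augment = cfg$toggles$augmentation)
    model <- train_segmenter(model, pre, gt_masks, pol, seed = cfg$seed)
    utils::write.csv(model$history, file.path(run_dir, "unet_history.csv"),
                     row.names = FALSE)
    pred_masks <- lapply(pre, function(x)
      predict_mask(model, image_rgb(x, "unit"), cfg$unet$tau)$mask)
    seg_metrics <- as.list(segmentation_report(pred_masks, gt_masks))
    log_stage("segment: pooled IoU ", round(seg_metrics$iou, 4))

    # --- stage: extraction ---------------------------------------------
    wp <- watershed_params(profile = cfg$watershed$profile,
                           tau = cfg$watershed$tau,
                           dt_threshold_frac = cfg$watershed$dt_threshold_frac,
                           min_peak_distance = cfg$watershed$min_peak_distance,
                           bg_dilate_iters = cfg$watershed$bg_dilate_iters,
                           compactness = cfg$watershed$compactness,
                           area_min = cfg$watershed$area_min,
                           area_max = cfg$watershed$area_max,
                           circ_min = cfg$watershed$circ_min)
    region_rows <- list()
    for (i in seq_along(smears)) {
      sep <- separate_cells(pred_masks[[i]], wp)
      ex <- extract_cell_images(smears[[i]]$image, sep$labels, sep$props,
                                cfg$data$roi_size)
      for (roi in ex) {
        # label by majority ground-truth instance inside the region
        px <- sep$labels == roi$source_id
        gti <- smears[[i]]$instances[px]
        gti <- gti[gti > 0]
        if (length(gti) == 0) next
        id <- names(which.max(table(gti)))
        rois[[length(rois) + 1L]] <- unclass(roi$crop) / 255
        roi_labels <- c(roi_labels, unname(smears[[i]]$labels[id]))
      }
      region_rows[[i]] <- cbind(smear = i, sep$props)
    }
    utils::write.csv(do.call(rbind, region_rows),
                     file.path(run_dir, "regions.csv"), row.names = FALSE)
    log_stage("extract: ", length(rois), " ROIs")
  } else {
    # direct tiles: fixed-size crops centred on ground-truth instances,
    # background retained (no mask multiplication)
    log_stage("extract: direct tiles (segmentation off)")
    for (i in seq_along(smears)) {
      sm <- smears[[i]]
      pr <- region_properties(sm$instances)
      for (r in seq_len(nrow(pr))) {
        cr <- round(pr$crow[r]); cc <- round(pr$ccol[r])
        half <- cfg$data$roi_size %/% 2L
        sz <- dim(sm$instances)
        r0 <- min(max(cr - half + 1L, 1L), sz[1] - 2L * half + 1L)
        c0 <- min(max(cc - half + 1L, 1L), sz[2] - 2L * half + 1L)
        tile <- unclass(sm$image)[r0:(r0 + 2L * half - 1L),
                                  c0:(c0 + 2L * half - 1L), , drop = FALSE]
        tile <- resize_bilinear(image_rgb(tile, "byte"),
                                cfg$data$roi_size, cfg$data$roi_size)
        rois[[length(rois) + 1L]] <- unclass(tile) / 255
        roi_labels <- c(roi_labels,
                        unname(sm$labels[as.character(pr$instance_id[r])]))
      }
    }
  }

  # --- stage: classification -------------------------------------------
  # top up with rendered ROIs so every class clears the fold minimum
  min_needed <- max(cfg$lwcnn$folds * 2L, cfg$data$n_rois_per_class)
  specs <- default_cell_specs()
  for (cl in CELL_CLASSES) {
    have <- sum(roi_labels == cl)
    extra <- max(0L, min_needed - have)
    for (j in seq_len(extra)) {
      rois[[length(rois) + 1L]] <- unclass(render_roi(
        specs[[cl]], cfg$data$roi_size,
        seed = (cfg$seed * 977L + match(cl, CELL_CLASSES) * 131L + j) %%
          .Machine$integer.max)) / 255
      roi_labels <- c(roi_labels, cl)
    }
  }
  log_stage("classify: ", length(rois), " ROIs, ", cfg$lwcnn$folds,
            " folds")
  folds <- stratified_kfold(roi_labels, k = cfg$lwcnn$folds,
                            seed = cfg$seed)
  lcfg <- lwcnn_config(input_size = cfg$data$roi_size,
                       dropout_conv = cfg$lwcnn$dropout_conv,
                       dropout_dense = cfg$lwcnn$dropout_dense,
                       extra_conv_blocks = cfg$toggles$extra_conv_blocks)
  template <- build_lwcnn(lcfg, seed = cfg$seed)
  cpol <- training_policy(lr = cfg$lwcnn$lr,
                          batch_size = cfg$lwcnn$batch_size,
                          max_epochs = cfg$lwcnn$max_epochs,
                          augment = cfg$toggles$augmentation)
  cv <- train_classifier(template, rois, roi_labels, folds, cpol,
                         seed = cfg$seed)
  agg <- aggregate_folds(cv$per_fold)
  preds <- do.call(rbind, lapply(cv$folds, function(o)
    data.frame(fold = o$fold, true = o$test_true, predicted = o$test_pred,
               confidence = apply(o$test_proba, 1, max))))
  utils::write.csv(preds, file.path(run_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$per_fold, file.path(run_dir, "fold_metrics.csv"),
                   row.names = FALSE)

  metrics <- list(segmentation = seg_metrics,
                  classification = as.list(agg$mean),
                  classification_sd = as.list(agg$sd))
  jsonlite::write_json(metrics, file.path(run_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done")
  invisible(list(metrics = metrics, run_dir = run_dir, classifier = cv,
                 aggregate = agg))
}
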