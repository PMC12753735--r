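# Pipeline configuration: defaults, YAML round-trip, validation.

#' Default pipeline configuration
#'
#' Stage toggles (clahe, augmentation, segmentation, extra_conv_blocks)
#' mirror the ablation variants; parameter blocks carry the reference
#' values (tau 0.5, minimum peak distance 7, area bounds 80/6000,
#' minimum circularity 0.40, Adam 1e-3, batch 16, ...). Sizes default to
#' desk-scale synthetic runs.
#'
#' @return a nested `pipeline_config` list.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    toggles = list(clahe = TRUE, augmentation = TRUE, segmentation = TRUE,
                   extra_conv_blocks = 0L),
    data = list(synthetic = TRUE, n_smears = 24L, smear_size = 96L,
                cells_per_smear = 6L, overlap_fraction = 0.25,
                illumination_gradient = 0.15, noise_sigma = 4,
                n_rois_per_class = 12L, roi_size = 64L),
    clahe = list(clip_limit = 2, tile_rows = 8L, tile_cols = 8L,
                 channels = "luminance"),
    unet = list(width_scale = 8L, max_epochs = 3L, batch_size = 8L,
                lr = 1e-3, tau = 0.5),
    watershed = list(profile = "default", tau = 0.5,
                     dt_threshold_frac = 0.325, min_peak_distance = 7L,
                     bg_dilate_iters = 3L, compactness = 0.001,
                     area_min = 80, area_max = 6000, circ_min = 0.40),
    lwcnn = list(folds = 2L, max_epochs = 4L, batch_size = 16L, lr = 1e-3,
                 dropout_conv = 0.25, dropout_dense = 0.5)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys are filled from [default_config()]; unknown keys are
#' rejected. An empty file yields the full defaults.
#'
#' @param path YAML file path.
#' @return validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, prefix = character(0))
  validate_config(cfg)
}

merge_config <- function(base, user, prefix) {
  for (k in names(user)) {
    key <- paste(c(prefix, k), collapse = ".")
    if (!k %in% names(base))
      stop("unknown config key: ", key)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop("config key ", key, " must be a mapping")
      base[[k]] <- merge_config(base[[k]], user[[k]], c(prefix, k))
    } else base[[k]] <- user[[k]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks ranges; errors name the offending key and its allowed range.
#'
#' @param cfg a `pipeline_config` (or plain nested list).
#' @return the config, classed, invisibly on success.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, key, range)
    if (!ok) stop("config key ", key, " outside its allowed range ", range)
  chk(cfg$unet$tau > 0 && cfg$unet$tau < 1, "unet.tau", "(0, 1)")
  chk(cfg$watershed$tau > 0 && cfg$watershed$tau < 1, "watershed.tau",
      "(0, 1)")
  chk(cfg$watershed$dt_threshold_frac > 0 &&
        cfg$watershed$dt_threshold_frac < 1,
      "watershed.dt_threshold_frac", "(0, 1)")
  chk(cfg$watershed$area_min < cfg$watershed$area_max,
      "watershed.area_min", "< area_max")
  chk(cfg$watershed$circ_min > 0 && cfg$watershed$circ_min <= 1,
      "watershed.circ_min", "(0, 1]")
  chk(cfg$clahe$clip_limit > 0, "clahe.clip_limit", "> 0")
  chk(cfg$data$overlap_fraction >= 0 && cfg$data$overlap_fraction <= 1,
      "data.overlap_fraction", "[0, 1]")
  chk(cfg$toggles$extra_conv_blocks %in% c(0L, 2L),
      "toggles.extra_conv_blocks", "{0, 2}")
  chk(cfg$lwcnn$folds >= 1, "lwcnn.folds", ">= 1")
  structure(cfg, class = "pipeline_config")
}

#' Write a configuration to YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
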