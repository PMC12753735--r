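# Synthetic smear generator. Morphology parameters are fixture defaults
# chosen to make the nine classes separable by size, colour and nucleus
# count; they are NOT calibrated to real hematology.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Morphology specification for one cell class
#'
#' @param class_name class label.
#' @param radius_range length-2 numeric, cell radius bounds in px (> 0).
#' @param body_color RGB mean of the cytoplasm/body, on \[0, 255\].
#' @param color_jitter per-cell RGB jitter SD.
#' @param nucleus_lobes number of nucleus lobes (0 = anucleate).
#' @param nucleus_color RGB of the nucleus.
#' @param nucleus_frac nucleus radius relative to the cell radius.
#' @param granularity texture-noise amplitude in \[0, 1\].
#' @return a `cell_class_spec` list.
#' @export
cell_class_spec <- function(class_name, radius_range, body_color,
                            color_jitter = 8, nucleus_lobes = 0L,
                            nucleus_color = c(90, 55, 135),
                            nucleus_frac = 0.55, granularity = 0.1) {
  stopifnot(length(radius_range) == 2L, all(radius_range > 0),
            radius_range[1] <= radius_range[2],
            granularity >= 0, granularity <= 1, nucleus_lobes >= 0)
  structure(list(class_name = class_name, radius_range = radius_range,
                 body_color = body_color, color_jitter = color_jitter,
                 nucleus_lobes = as.integer(nucleus_lobes),
                 nucleus_color = nucleus_color, nucleus_frac = nucleus_frac,
                 granularity = granularity),
            class = "cell_class_spec")
}

#' Default morphology specs for the nine classes
#'
#' Pairwise distinguishable by radius range, body colour and nucleus lobe
#' count. Fixture values, not measurements.
#' @return named list of [cell_class_spec()] objects in [CELL_CLASSES] order.
#' @export
default_cell_specs <- function() {
  s <- list(
    cell_class_spec("erythrocyte", c(9, 12), c(232, 148, 138),
                    nucleus_lobes = 0, granularity = 0.05),
    cell_class_spec("erythroblast", c(10, 13), c(225, 162, 160),
                    nucleus_lobes = 1, nucleus_color = c(92, 50, 130),
                    nucleus_frac = 0.55, granularity = 0.1),
    cell_class_spec("neutrophil", c(13, 16), c(238, 210, 200),
                    nucleus_lobes = 3, nucleus_color = c(110, 70, 150),
                    nucleus_frac = 0.40, granularity = 0.15),
    cell_class_spec("basophil", c(12, 15), c(150, 120, 190),
                    nucleus_lobes = 2, nucleus_color = c(80, 50, 120),
                    nucleus_frac = 0.45, granularity = 0.5),
    cell_class_spec("eosinophil", c(13, 16), c(240, 150, 110),
                    nucleus_lobes = 2, nucleus_color = c(120, 70, 150),
                    nucleus_frac = 0.42, granularity = 0.45),
    cell_class_spec("lymphocyte", c(8, 11), c(170, 180, 230),
                    nucleus_lobes = 1, nucleus_color = c(70, 50, 140),
                    nucleus_frac = 0.75, granularity = 0.05),
    cell_class_spec("monocyte", c(15, 18), c(190, 195, 215),
                    nucleus_lobes = 1, nucleus_color = c(100, 80, 160),
                    nucleus_frac = 0.55, granularity = 0.1),
    cell_class_spec("immature_granulocyte", c(13, 17), c(200, 185, 225),
                    nucleus_lobes = 1, nucleus_color = c(95, 65, 145),
                    nucleus_frac = 0.65, granularity = 0.25),
    cell_class_spec("platelet", c(3, 5), c(180, 140, 200),
                    nucleus_lobes = 0, granularity = 0.3)
  )
  names(s) <- vapply(s, `[[`, "", "class_name")
  stopifnot(identical(names(s), CELL_CLASSES))
  s
}

#' Render one synthetic cell sprite
#'
#' Draws a disc-shaped cell with class-specific body colour, optional
#' multi-lobed nucleus and granular texture. Deterministic for a fixed
#' (spec, seed).
#'
#' @param spec a [cell_class_spec()].
#' @param seed integer seed.
#' @return list with `sprite` (byte-scale [image_rgb()]) and `mask`
#'   (integer matrix, 1 inside the cell).
#' @export
render_cell <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cell_class_spec"))
  if (any(spec$radius_range <= 0)) stop("degenerate radius range")
  with_seed(seed, {
    r <- runif(1, spec$radius_range[1], spec$radius_range[2])
    s <- 2L * ceiling(spec$radius_range[2]) + 3L
    ctr <- (s + 1) / 2
    gx <- matrix(seq_len(s), s, s)          # row index
    gy <- matrix(seq_len(s), s, s, byrow = TRUE)
    d2 <- (gx - ctr)^2 + (gy - ctr)^2
    mask <- (d2 <= r^2) * 1L
    body <- spec$body_color + rnorm(3, 0, spec$color_jitter)
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) img[, , ch] <- mask * body[ch]
    if (spec$granularity > 0) {
      tex <- matrix(runif(s * s, -1, 1) * spec$granularity * 45, s, s) * mask
      for (ch in 1:3) img[, , ch] <- img[, , ch] + tex
    }
    k <- spec$nucleus_lobes
    if (k > 0) {
      ncol_ <- spec$nucleus_color + rnorm(3, 0, 4)
      nr <- spec$nucleus_frac * r / max(1, sqrt(k) * 0.85)
      off <- if (k == 1) 0.15 * r else 0.42 * r
      phase <- runif(1, 0, 2 * pi)
      for (l in seq_len(k)) {
        a <- phase + 2 * pi * (l - 1) / k
        cx <- ctr + off * cos(a)
        cy <- ctr + off * sin(a)
        nm <- ((gx - cx)^2 + (gy - cy)^2 <= nr^2) & (mask > 0)
        for (ch in 1:3)
          img[, , ch][nm] <- ncol_[ch] +
            if (spec$granularity > 0) runif(sum(nm), -1, 1) *
              spec$granularity * 25 else 0
      }
    }
    img <- pmin(pmax(img, 0), 255)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * mask
    list(sprite = image_rgb(img, "byte"), mask = mask)
  })
}

#' Scene specification for a synthetic smear
#'
#' Defaults are the package's standard synthetic study conditions: a
#' 128 x 128 frame, one cell per class, a quarter of cells overlapping,
#' 15% relative illumination change across the frame and Gaussian pixel
#' noise with SD 4 on the byte scale.
#'
#' @param height,width frame size in px.
#' @param cells_per_class named integer vector, cells requested per class.
#' @param overlap_fraction target fraction of cells whose mask intersects
#'   another, in \[0, 1\].
#' @param illumination_gradient max relative brightness change across the
#'   frame.
#' @param noise_sigma additive Gaussian SD on the \[0, 255\] scale.
#' @param seed integer seed.
#' @return a `smear_spec` list.
#' @export
smear_spec <- function(height = 128L, width = 128L,
                       cells_per_class = stats::setNames(rep(1L, 9L),
                                                         CELL_CLASSES),
                       overlap_fraction = 0.25,
                       illumination_gradient = 0.15,
                       noise_sigma = 4, seed = 1L) {
  stopifnot(all(cells_per_class >= 0),
            overlap_fraction >= 0, overlap_fraction <= 1, noise_sigma >= 0)
  if (is.null(names(cells_per_class)))
    names(cells_per_class) <- CELL_CLASSES[seq_along(cells_per_class)]
  stopifnot(all(names(cells_per_class) %in% CELL_CLASSES))
  structure(list(height = as.integer(height), width = as.integer(width),
                 cells_per_class = cells_per_class,
                 overlap_fraction = overlap_fraction,
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "smear_spec")
}

BACKGROUND_RGB <- c(235, 228, 220)

#' Generate a synthetic smear with ground truth
#'
#' Composites seeded cell sprites onto a background frame by rejection
#' sampling of centres (at most `max_attempts` per cell), realising the
#' target overlap fraction by relaxing the pairwise centre-distance
#' constraint for a chosen subset of cells; applies an illumination gradient
#' and Gaussian noise after compositing. The instance map records, per
#' pixel, the topmost sprite that contributed the pixel's pre-noise colour.
#'
#' @param spec a [smear_spec()].
#' @param specs class morphology specs, default [default_cell_specs()].
#' @param max_attempts placement attempts per cell before failing.
#' @return a `synthetic_smear`: list with `image` ([image_rgb()]),
#'   `instances` (integer label matrix), `labels` (named character vector,
#'   instance id to class), and `overlap_achieved`.
#' @export
generate_smear <- function(spec, specs = default_cell_specs(),
                           max_attempts = 100L) {
  stopifnot(inherits(spec, "smear_spec"))
  H <- spec$height; W <- spec$width
  counts <- spec$cells_per_class
  classes <- rep(names(counts), counts)
  n <- length(classes)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- BACKGROUND_RGB[ch]
  inst <- matrix(0L, H, W)
  labels <- character(0)
  overlap_achieved <- 0
  if (n > 0) {
    with_seed(spec$seed, {
      # large cells first (ties broken randomly): packs far more reliably
      rmaxs <- vapply(classes, function(cl) specs[[cl]]$radius_range[2], 0)
      ord <- order(-rmaxs, sample.int(n))
      classes <- classes[ord]
      n_ov_pairs <- round(spec$overlap_fraction * n / 2)
      ov_idx <- if (n_ov_pairs > 0 && n > 1)
        sample(2:n, min(n_ov_pairs, n - 1)) else integer(0)
      placed <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                           r = numeric(0))
      overlapped <- logical(n)
      cell_seeds <- sample.int(.Machine$integer.max, n)
      for (i in seq_len(n)) {
        cs <- specs[[classes[i]]]
        rc <- render_cell(cs, cell_seeds[i])
        sdim <- nrow(rc$mask)
        ri <- sqrt(sum(rc$mask) / pi)
        half <- (sdim - 1) / 2
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          # overlappers fall back to clear placement late in their budget
          want_overlap <- i %in% ov_idx && nrow(placed) > 0 &&
            att <= ceiling(max_attempts / 2)
          if (want_overlap) {
            # pair with a not-yet-overlapped cell so each cell is bitten at
            # most once (keeps every occluded remainder connected)
            free <- placed[!overlapped[placed$id], , drop = FALSE]
            pool <- if (nrow(free) > 0) free else placed
            j <- pool[sample.int(nrow(pool), 1L), ]
            dmin <- max(0.55 * (ri + j$r), abs(ri - j$r) + 2)
            dmax <- max(0.85 * (ri + j$r), dmin + 1)
            dd <- runif(1, dmin, dmax)
            a <- runif(1, 0, 2 * pi)
            cx <- round(j$x + dd * cos(a)); cy <- round(j$y + dd * sin(a))
            # keep full clearance from every other placed cell
            others <- placed[placed$id != j$id, , drop = FALSE]
            if (nrow(others) > 0) {
              dsts <- sqrt((others$x - cx)^2 + (others$y - cy)^2)
              if (any(dsts < others$r + ri + 2)) next
            }
          } else {
            cx <- round(runif(1, half + 1, H - half))
            cy <- round(runif(1, half + 1, W - half))
          }
          if (cx - half < 1 || cx + half > H || cy - half < 1 ||
              cy + half > W) next
          if (!want_overlap && nrow(placed) > 0) {
            dsts <- sqrt((placed$x - cx)^2 + (placed$y - cy)^2)
            if (any(dsts < placed$r + ri + 2)) next
          }
          ok <- TRUE
          break
        }
        if (!ok) stop("could not place a cell of class '", classes[i],
                      "' after ", max_attempts, " attempts")
        rows <- (cx - half):(cx + half); cols <- (cy - half):(cy + half)
        mk <- rc$mask > 0
        sub <- inst[rows, cols]
        hit <- unique(sub[mk & sub > 0])
        if (length(hit) > 0) { overlapped[i] <- TRUE; overlapped[hit] <- TRUE }
        sub[mk] <- i
        inst[rows, cols] <- sub
        for (ch in 1:3) {
          pane <- img[rows, cols, ch]
          pane[mk] <- rc$sprite[, , ch][mk]
          img[rows, cols, ch] <- pane
        }
        placed <- rbind(placed, data.frame(id = i, x = cx, y = cy, r = ri))
      }
      labels <- stats::setNames(classes, as.character(seq_len(n)))
      overlap_achieved <- sum(overlapped) / n
    })
  }
  # drop ids fully occluded (cannot happen under the distance guard, but be safe)
  present <- sort(unique(inst[inst > 0]))
  labels <- labels[as.character(present)]
  if (spec$illumination_gradient > 0) {
    u <- matrix(seq(0, 1, length.out = H), H, W)
    v <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
    plane <- 1 + spec$illumination_gradient * ((u + v) / 2 - 0.5)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * plane
  }
  if (spec$noise_sigma > 0) {
    with_seed(spec$seed + 1L, {
      img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))
    })
  }
  img <- pmin(pmax(img, 0), 255)
  structure(list(image = image_rgb(img, "byte"), instances = inst,
                 labels = labels, overlap_achieved = overlap_achieved,
                 spec = spec),
            class = "synthetic_smear")
}

#' Render one background-zeroed single-cell ROI
#'
#' In-memory counterpart of the ROI dataset writer: one cell of the given
#' class centred (with positional jitter) on a black canvas, with noise
#' applied inside the cell mask only.
#'
#' @param spec a [cell_class_spec()].
#' @param roi_size output size in px.
#' @param seed integer seed.
#' @param noise_sigma Gaussian SD on byte scale, applied inside the mask.
#' @return byte-scale [image_rgb()] of size `roi_size x roi_size`.
#' @export
render_roi <- function(spec, roi_size = 64L, seed = 1L, noise_sigma = 4) {
  if (roi_size < 2 * ceiling(spec$radius_range[2]) + 3)
    stop("roi_size ", roi_size, " smaller than the largest '",
         spec$class_name, "' cell")
  rc <- render_cell(spec, seed)
  s <- nrow(rc$mask)
  out <- array(0, c(roi_size, roi_size, 3))
  with_seed(seed + 13L, {
    jmax <- max(0L, floor((roi_size - s) / 2) - 1L)
    off <- floor((roi_size - s) / 2) +
      sample(seq(-min(jmax, 3L), min(jmax, 3L)), 2L, replace = TRUE)
    rows <- (off[1] + 1):(off[1] + s); cols <- (off[2] + 1):(off[2] + s)
    noise <- array(rnorm(s * s * 3, 0, noise_sigma), c(s, s, 3))
    for (ch in 1:3)
      out[rows, cols, ch] <- pmin(pmax(
        (rc$sprite[, , ch] + noise[, , ch]) * rc$mask, 0), 255)
  })
  image_rgb(out, "byte")
}

#' Generate a balanced on-disk single-cell ROI dataset
#'
#' Writes `n_per_class` background-zeroed single-cell PNG crops per class
#' under `root/rois/<class>/` plus a `manifest.csv` (path, class,
#' instance_id, seed). Class balance is exact; regeneration with the same
#' seed reproduces identical files.
#'
#' @param root output directory.
#' @param n_per_class crops per class; either a single integer or a named
#'   vector over classes (e.g. proportional to [REFERENCE_CLASS_COUNTS]).
#' @param roi_size crop size in px.
#' @param seed integer seed.
#' @param specs class morphology specs.
#' @return the manifest data frame, invisibly.
#' @export
generate_roi_dataset <- function(root, n_per_class, roi_size = 64L,
                                 seed = 1L, specs = default_cell_specs()) {
  stopifnot(all(n_per_class >= 1))
  if (length(n_per_class) == 1L)
    n_per_class <- stats::setNames(rep(as.integer(n_per_class),
                                       length(specs)), names(specs))
  if (is.null(names(n_per_class)))
    stop("n_per_class must be named by class when giving per-class counts")
  stopifnot(all(names(n_per_class) %in% names(specs)))
  rmax <- max(vapply(specs[names(n_per_class)],
                     function(s) s$radius_range[2], 0))
  if (roi_size < 2 * ceiling(rmax) + 3)
    stop("roi_size smaller than the largest cell (needs >= ",
         2 * ceiling(rmax) + 3, ")")
  dir.create(file.path(root, "rois"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cls in names(n_per_class)) {
    cdir <- file.path(root, "rois", cls)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(n_per_class[[cls]])) {
      sd_i <- (seed * 131071 + match(cls, names(specs)) * 8191 + i) %%
        .Machine$integer.max
      roi <- render_roi(specs[[cls]], roi_size, sd_i)
      p <- file.path(cdir, sprintf("%s_%04d.png", cls, i))
      write_image(roi, p)
      rows[[length(rows) + 1L]] <- data.frame(
        path = p, class = cls, instance_id = i, seed = sd_i,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
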