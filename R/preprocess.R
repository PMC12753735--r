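# Preprocessing: bilinear resize, unit rescaling, CLAHE contrast
# enhancement, and the affine augmentation operators.

#' Bilinear image resize
#'
#' Separable linear interpolation with half-pixel-centred sampling: output
#' pixel centre (i + 0.5)/H_out maps to source coordinate
#' x = (i + 0.5) * H_in / H_out - 0.5, and the intensity is the convex
#' combination (1 - a) I(x1) + a I(x2) of the two neighbouring source
#' pixels, where a is the fractional part of x; applied along rows then
#' columns. Output intensities therefore never leave the source range.
#'
#' @param img an [image_rgb()] (or plain matrix/array).
#' @param out_height,out_width target size in px (>= 1).
#' @return resized image with the input's scale flag.
#' @export
resize_bilinear <- function(img, out_height, out_width) {
  if (out_height < 1 || out_width < 1) stop("zero-sized resize target")
  was_mat <- is.matrix(img)
  a <- if (was_mat) array(img, c(dim(img), 1L)) else unclass(img)
  d <- dim(a)
  if (d[1] == out_height && d[2] == out_width)
    return(if (was_mat) img else img)
  interp_axis <- function(n_in, n_out) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    x <- pmin(pmax(x, 0), n_in - 1)
    x1 <- floor(x)
    list(i1 = as.integer(x1) + 1L,
         i2 = pmin(as.integer(x1) + 2L, n_in),
         a = x - x1)
  }
  rw <- interp_axis(d[1], out_height)
  cw <- interp_axis(d[2], out_width)
  out <- array(0, c(out_height, out_width, d[3]))
  for (ch in seq_len(d[3])) {
    m <- matrix(a[, , ch], d[1], d[2])
    tmp <- m[rw$i1, , drop = FALSE] * (1 - rw$a) +
      m[rw$i2, , drop = FALSE] * rw$a
    out[, , ch] <- tmp[, cw$i1, drop = FALSE] *
      rep(1 - cw$a, each = out_height) +
      tmp[, cw$i2, drop = FALSE] * rep(cw$a, each = out_height)
  }
  if (was_mat) matrix(out[, , 1], out_height, out_width)
  else restore_img(out, img)
}

#' Rescale a byte image to the unit interval
#'
#' Divides every pixel by 255 and flips the scale flag; refuses input that
#' is already unit-scaled (double-normalization guard).
#'
#' @param img a byte-scale [image_rgb()].
#' @return unit-scale [image_rgb()].
#' @export
normalize_unit <- function(img) {
  if (img_scale(img) == "unit")
    stop("image is already unit-scaled; refusing to normalize twice")
  restore_img(unclass(img) / 255, img, scale = "unit")
}

#' CLAHE parameters
#'
#' @param clip_limit histogram clip threshold (> 0). Default 2, the widely
#'   used default.
#' @param tile_grid integer length-2, (rows, cols) of local tiles.
#' @param channels `"luminance"` (equalize a luma channel and rescale RGB
#'   proportionally, avoiding hue shifts) or `"rgb"` (per channel).
#' @return a `clahe_params` list.
#' @export
clahe_params <- function(clip_limit = 2, tile_grid = c(8L, 8L),
                         channels = c("luminance", "rgb")) {
  stopifnot(clip_limit > 0, length(tile_grid) == 2L, all(tile_grid >= 1))
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 channels = match.arg(channels)),
            class = "clahe_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile histogram equalization with clipped histograms and bilinear
#' blending between adjacent tiles. A constant image is returned unchanged
#' (no contrast to redistribute).
#'
#' @param img byte-scale [image_rgb()].
#' @param p a [clahe_params()].
#' @return byte-scale [image_rgb()] with values in \[0, 255\].
#' @export
clahe_enhance <- function(img, p = clahe_params()) {
  if (img_scale(img) != "byte") stop("clahe_enhance expects a byte image")
  d <- dim(img)
  if (any(p$tile_grid > d[1:2]))
    stop("tile grid larger than image dimensions")
  a <- unclass(img) / 255
  rng <- range(a)
  if (diff(rng) < 1e-12) return(img)
  run <- function(m) EBImage::clahe(m, nx = p$tile_grid[2],
                                    ny = p$tile_grid[1],
                                    limit = p$clip_limit)
  if (p$channels == "rgb") {
    out <- a
    for (ch in 1:3) out[, , ch] <- run(a[, , ch])
  } else {
    y <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    y2 <- run(y)
    ratio <- ifelse(y > 1e-6, y2 / y, 1)
    out <- a
    for (ch in 1:3) out[, , ch] <- a[, , ch] * ratio
  }
  restore_img(pmin(pmax(out, 0), 1) * 255, img)
}

#' Sample an affine augmentation configuration
#'
#' Draws each parameter uniformly from the study's closed intervals:
#' rotation \[-20, 20\] degrees, width/height shift \[-0.05, 0.05\] of the
#' image size, shear \[0, 0.05\], zoom factors \[1, 1.05\] (a zoom range of
#' 0 to 0.05), and a fair-coin horizontal flip.
#'
#' @param seed integer seed (same seed, same draw).
#' @param rotation_range,shift_range,shear_range,zoom_range interval bounds.
#' @param flip if `FALSE` the flip is never drawn.
#' @return an `affine_augment` list usable with [apply_augmentation()].
#' @export
sample_augmentation <- function(seed = 1L,
                                rotation_range = c(-20, 20),
                                shift_range = c(-0.05, 0.05),
                                shear_range = c(0, 0.05),
                                zoom_range = c(1, 1.05),
                                flip = TRUE) {
  with_seed(seed, {
    affine_augment(
      rotation_deg = runif(1, rotation_range[1], rotation_range[2]),
      shift_frac = runif(2, shift_range[1], shift_range[2]),
      shear = runif(1, shear_range[1], shear_range[2]),
      zoom = runif(2, zoom_range[1], zoom_range[2]),
      horizontal_flip = flip && runif(1) < 0.5)
  })
}

#' Construct an affine augmentation configuration
#'
#' @param rotation_deg rotation angle in degrees.
#' @param shift_frac length-2 (row, col) shift as a fraction of image size.
#' @param shear shear factor.
#' @param zoom length-2 positive scale factors (width, height).
#' @param horizontal_flip logical.
#' @return an `affine_augment` list.
#' @export
affine_augment <- function(rotation_deg = 0, shift_frac = c(0, 0),
                           shear = 0, zoom = c(1, 1),
                           horizontal_flip = FALSE) {
  if (any(zoom == 0)) stop("non-invertible zoom factor 0")
  structure(list(rotation_deg = rotation_deg, shift_frac = shift_frac,
                 shear = shear, zoom = zoom,
                 horizontal_flip = horizontal_flip),
            class = "affine_augment")
}

identity_augment <- function() affine_augment()

#' Apply an affine augmentation to an image
#'
#' Composes rotation, shear, zoom and shift into a single affine map about
#' the image centre, optionally followed by a horizontal flip. Pixels are
#' sampled by inverse mapping with nearest-neighbour lookup; source
#' coordinates falling outside the frame are clamped to the nearest edge
#' pixel (nearest-neighbour fill). Output dimensions equal input dimensions,
#' and the identity configuration reproduces the input bit for bit.
#'
#' @param img an [image_rgb()] or a matrix (e.g. a mask, transformed with
#'   the same configuration as its image).
#' @param t an `affine_augment` from [sample_augmentation()] or
#'   [affine_augment()].
#' @return transformed image of the same type and dimensions.
#' @export
apply_augmentation <- function(img, t) {
  stopifnot(inherits(t, "affine_augment"))
  if (any(t$zoom == 0)) stop("non-invertible zoom factor 0")
  was_mat <- is.matrix(img)
  a <- if (was_mat) array(img, c(dim(img), 1L)) else unclass(img)
  d <- dim(a)
  H <- d[1]; W <- d[2]
  th <- t$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, t$shear, 1), 2, 2)
  Z <- diag(t$zoom)
  A <- Z %*% S %*% R
  shift <- c(t$shift_frac[1] * H, t$shift_frac[2] * W)
  if (identical(unname(A), diag(2)) && all(shift == 0) &&
      !t$horizontal_flip) return(img)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  Ainv <- solve(A)
  xo <- matrix(seq_len(H), H, W) - ctr[1] - shift[1]
  yo <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2] - shift[2]
  xs <- Ainv[1, 1] * xo + Ainv[1, 2] * yo + ctr[1]
  ys <- Ainv[2, 1] * xo + Ainv[2, 2] * yo + ctr[2]
  xi <- pmin(pmax(round(xs), 1), H)
  yi <- pmin(pmax(round(ys), 1), W)
  idx <- cbind(as.vector(xi), as.vector(yi))
  out <- array(0, d)
  for (ch in seq_len(d[3]))
    out[, , ch] <- matrix(a[, , ch][idx], H, W)
  if (t$horizontal_flip) out <- out[, W:1, , drop = FALSE]
  if (was_mat) out[, , 1] else restore_img(out, img)
}
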