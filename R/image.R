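#' RGB image container
#'
#' Images are plain `H x W x 3` numeric arrays carrying an explicit scale
#' flag: `"byte"` for intensities on \[0, 255\] and `"unit"` for \[0, 1\].
#' All package functions preserve the flag; [normalize_unit()] is the only
#' sanctioned byte-to-unit conversion.
#'
#' @param data numeric `H x W x 3` array (or `H x W` matrix, replicated to
#'   three channels).
#' @param scale `"byte"` or `"unit"`.
#' @return the array with class `image_rgb` and a `scale` attribute.
#' @export
image_rgb <- function(data, scale = c("byte", "unit")) {
  scale <- match.arg(scale)
  if (is.matrix(data)) data <- array(rep(data, 3L), c(dim(data), 3L))
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[3] == 3L)
  structure(data, class = "image_rgb", scale = scale)
}

img_scale <- function(img) {
  s <- attr(img, "scale")
  if (is.null(s)) "byte" else s
}

restore_img <- function(data, template, scale = img_scale(template)) {
  structure(data, class = "image_rgb", scale = scale)
}

#' @export
print.image_rgb <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_rgb %d x %d, scale=%s, range [%.3f, %.3f]>\n",
              d[1], d[2], img_scale(x), min(x), max(x)))
  invisible(x)
}

#' Read an RGB image from PNG/JPEG/TIFF
#'
#' @param path file path; format chosen by extension.
#' @return an [image_rgb()] on byte scale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  image_rgb(a * 255, scale = "byte")
}

#' Write an RGB image as PNG
#'
#' @param img an [image_rgb()].
#' @param path output path.
#' @export
write_image <- function(img, path) {
  a <- unclass(img)
  if (img_scale(img) == "byte") a <- a / 255
  png::writePNG(pmin(pmax(a, 0), 1), path)
  invisible(path)
}

#' Read / write instance label maps
#'
#' Label maps (0 = background, k >= 1 = instance k) are stored as 16-bit
#' single-channel TIFF, which round-trips integer ids up to 65535 losslessly.
#'
#' @param labels integer matrix of instance ids.
#' @param path file path.
#' @return `read_label_map` returns an integer matrix.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
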