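# Shared fixtures: simple rasters and small cached datasets.

disc_mask <- function(H, W, cx, cy, r) {
  gx <- matrix(seq_len(H), H, W)
  gy <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((gx - cx)^2 + (gy - cy)^2 <= r^2) * 1
}

const_image <- function(H = 8, W = 8, value = 100) {
  image_rgb(array(value, c(H, W, 3)), "byte")
}

# a pair of overlapping discs with mask-overlap (intersection over the
# smaller disc) inside [lo, hi]; returns the union mask
overlapping_pair <- function(r1, r2, f, H = 120) {
  dd <- f * (r1 + r2)
  d1 <- disc_mask(H, H, 60, 60 - dd / 2, r1)
  d2 <- disc_mask(H, H, 60, 60 + dd / 2, r2)
  list(mask = (d1 + d2 > 0) * 1,
       overlap = sum(d1 & d2) / min(sum(d1), sum(d2)))
}

# small cached ROI fixture (built once per test run)
roi_fixture <- local({
  cache <- NULL
  function(n_per_class = 12, roi_size = 48L) {
    key <- paste(n_per_class, roi_size)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$data)
    specs <- default_cell_specs()
    x <- list(); y <- character(0)
    for (cl in CELL_CLASSES) for (i in seq_len(n_per_class)) {
      sd <- 5000 + match(cl, CELL_CLASSES) * 500 + i
      x[[length(x) + 1L]] <- unclass(render_roi(specs[[cl]], roi_size,
                                                sd)) / 255
      y <- c(y, cl)
    }
    cache <<- list(key = key, data = list(x = x, y = y))
    cache$data
  }
})
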