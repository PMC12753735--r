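test_that("clean_mask removes specks, keeps blocks, fills holes", {
  m <- matrix(0, 20, 20)
  m[3, 3] <- 1                          # isolated speck: opened away
  m[8:17, 8:17] <- 1                    # solid 10x10: invariant
  out <- clean_mask(m, watershed_params(fill_holes = FALSE))
  expect_equal(out[3, 3], 0)
  expect_true(all(out[8:17, 8:17] == 1))
  expect_equal(sum(out), 100)

  holed <- matrix(0, 15, 15)
  holed[4:12, 4:12] <- 1
  holed[8, 8] <- 0
  filled <- clean_mask(holed, watershed_params(fill_holes = TRUE))
  expect_equal(filled[8, 8], 1)
  open_only <- clean_mask(holed, watershed_params(fill_holes = FALSE))
  # a 1-px hole is also closed by the 3x3 closing itself
  expect_equal(open_only[8, 8], 1)
})

test_that("euclidean distance map matches brute force on small masks", {
  expect_true(all(euclidean_distance_map(matrix(0, 6, 6)) == 0))

  m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1   # solid 5x5 block
  d <- euclidean_distance_map(m)
  expect_equal(d[5, 5], 3)                 # centre: 3 px to background
  expect_equal(d[3, 3], 1)                 # foreground adjacent to bg
  expect_true(all(d[m == 0] == 0))
  # brute force over all background pixels
  bg <- which(m == 0)
  bi <- (bg - 1) %% 9 + 1; bj <- (bg - 1) %/% 9 + 1
  for (px in which(m == 1)) {
    i <- (px - 1) %% 9 + 1; j <- (px - 1) %/% 9 + 1
    expect_equal(d[i, j], min(sqrt((bi - i)^2 + (bj - j)^2)))
  }
})

test_that("marker selection finds one marker per well-separated cell", {
  m <- disc_mask(100, 100, 30, 30, 12) + disc_mask(100, 100, 30, 70, 12)
  d <- euclidean_distance_map(m)
  mk <- select_markers(d, m)
  expect_equal(mk$n_foreground, 2L)
  # background has its own label, unknown is the rest
  expect_true(any(mk$markers == 1))
  expect_true(all(sort(unique(as.vector(mk$markers))) == c(0, 1, 2, 3)))

  # two peaks 3 px apart collapse to one marker
  d2 <- matrix(0, 30, 30)
  d2[15, 14] <- 5; d2[15, 17] <- 4.5
  m2 <- (d2 > 0) * 1
  m2[14:16, 13:18] <- 1
  mk2 <- select_markers(d2, m2)
  expect_equal(mk2$n_foreground, 1L)

  empty <- select_markers(matrix(0, 10, 10), matrix(0, 10, 10))
  expect_equal(empty$n_foreground, 0L)
})

test_that("raising the threshold never increases the marker count", {
  set.seed(5)
  sm <- generate_smear(smear_spec(seed = 21))
  m <- (sm$instances > 0) * 1
  d <- euclidean_distance_map(m)
  counts <- vapply(c(0.2, 0.3, 0.4, 0.55, 0.7, 0.9), function(fr)
    select_markers(d, m, watershed_params(dt_threshold_frac = fr))$n_foreground,
    0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("flooding respects markers, masks, and splits dumbbells", {
  blob <- disc_mask(40, 40, 20, 20, 10)
  mk <- matrix(0L, 40, 40); mk[20, 20] <- 2L
  lab <- apply_watershed(blob, mk)
  expect_equal((lab > 0) * 1, blob)     # region equals the blob
  expect_equal(max(lab), 1L)

  pair <- overlapping_pair(11, 11, 0.7)
  sep <- separate_cells(pair$mask)
  expect_equal(max(sep$labels), 2L)
  expect_equal((sep$labels > 0) * 1, clean_mask(pair$mask))
  # the split boundary crosses the neck: both regions are substantial
  expect_true(all(table(sep$labels[sep$labels > 0]) > 100))
  # labels never outside the mask
  expect_true(all(sep$labels[clean_mask(pair$mask) == 0] == 0))

  expect_warning(apply_watershed(blob, matrix(0L, 40, 40)),
                 "no foreground markers")
})

test_that("flooding matches the brute-force minimax oracle", {
  set.seed(11)
  for (case in 1:6) {
    H <- sample(25:50, 1)
    m <- matrix(0, H, H)
    for (b in 1:3) {
      r <- sample(4:8, 1)
      m <- m + disc_mask(H, H, sample(r:(H - r), 1), sample(r:(H - r), 1), r)
    }
    m <- (m > 0) * 1
    d <- euclidean_distance_map(m)
    mk <- select_markers(d, m, watershed_params(dt_threshold_frac = 0.4))
    if (mk$n_foreground == 0) next
    fg <- mk$markers * (m > 0)
    remap <- matrix(0L, H, H)
    ids <- sort(unique(fg[fg > 1]))
    for (k in seq_along(ids)) remap[fg == ids[k]] <- k
    mi <- matrix(as.integer(m > 0), H, H)
    # plain flood: strict agreement away from exact ties
    got0 <- hemosmear:::.ws_flood(-d, remap, mi, 0)
    orc0 <- ws_oracle(-d, remap, m, 0, tol = 1e-9)
    cmp0 <- m > 0 & !orc0$tie
    expect_true(all(got0[cmp0] == orc0$labels[cmp0]))
    # compact flood: agreement outside the compactness perturbation margin
    got1 <- hemosmear:::.ws_flood(-d, remap, mi, 0.001)
    orc1 <- ws_oracle(-d, remap, m, 0.001, tol = 0.001 * 2 * H)
    cmp1 <- m > 0 & !orc1$tie
    expect_true(all(got1[cmp1] == orc1$labels[cmp1]))
  }
})

test_that("region properties measure area, perimeter and circularity", {
  sq <- matrix(0, 10, 10); sq[4:7, 4:7] <- 1
  pr <- region_properties(sq)
  expect_equal(pr$area, 16)
  expect_false(pr$touches_border)

  # a region whose perimeter satisfies P = 2*sqrt(pi*A) has circularity 1
  expect_equal(4 * pi * 300 / (2 * sqrt(pi * 300))^2, 1.0)

  # rasterized discs of radius >= 10: circularity in [0.9, 1.0]
  for (r in c(10, 15, 25)) {
    dm <- disc_mask(2 * r + 11, 2 * r + 11, r + 6, r + 6, r)
    expect_gte(region_properties(dm)$circularity, 0.9)
    expect_lte(region_properties(dm)$circularity, 1.0)
  }
  # a large square sits near the continuous-limit value pi/4
  big <- matrix(0, 60, 60); big[11:50, 11:50] <- 1
  expect_lt(abs(region_properties(big)$circularity - pi / 4), 0.15)
})

test_that("filter_regions applies each gate with the right reason", {
  p <- watershed_params()
  props <- data.frame(instance_id = 1:4,
                      area = c(50, 7000, 500, 500),
                      perimeter = c(30, 320, 85, 300),
                      circularity = c(0.7, 0.86, 0.87, 0.07),
                      rmin = 5, rmax = 9, cmin = 5, cmax = 9,
                      touches_border = c(FALSE, FALSE, FALSE, FALSE),
                      crow = 7, ccol = 7)
  out <- filter_regions(props, p)
  expect_equal(out$reasons, c("too_small", "too_large", "",
                              "low_circularity"))
  expect_equal(out$kept, c(FALSE, FALSE, TRUE, FALSE))
  # label conservation
  expect_equal(sum(out$kept) + sum(!out$kept), 4L)
})

test_that("extracted ROIs are background-zeroed and id-disjoint", {
  sm <- generate_smear(smear_spec(overlap_fraction = 0, noise_sigma = 0,
                                  seed = 13))
  lab <- sm$instances
  props <- filter_regions(region_properties(lab), watershed_params())
  rois <- extract_cell_images(sm$image, lab, props, roi_size = 32L)
  expect_gt(length(rois), 1)
  ids <- vapply(rois, function(r) r$props$instance_id, 0)
  expect_equal(anyDuplicated(ids), 0L)
  for (r in rois) {
    outside <- r$mask == 0
    for (ch in 1:3) expect_true(all(r$crop[, , ch][outside] == 0))
    expect_equal(dim(r$crop)[1:2], c(32L, 32L))
  }
  # a region spanning the whole frame crops to (a resized copy of) the image
  allfg <- matrix(1L, 16, 16)
  img <- const_image(16, 16, 200)
  pr <- filter_regions(region_properties(allfg),
                       watershed_params(drop_border = FALSE,
                                        area_min = 1, area_max = 1e6,
                                        circ_min = 0.01))
  roi <- extract_cell_images(img, allfg, pr, roi_size = 16L)
  expect_equal(length(roi), 1L)
  expect_equal(unclass(roi[[1]]$crop), unclass(img))
})
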