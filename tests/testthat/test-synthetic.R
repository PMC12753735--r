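test_that("render_cell draws a constant disc when textureless and anucleate", {
  spec <- cell_class_spec("plain", c(8, 8), c(120, 60, 200),
                          color_jitter = 0, nucleus_lobes = 0,
                          granularity = 0)
  rc <- render_cell(spec, seed = 3)
  vals <- rc$sprite[, , 1][rc$mask > 0]
  expect_equal(length(unique(vals)), 1L)
  vals_g <- rc$sprite[, , 2][rc$mask > 0]
  expect_equal(length(unique(vals_g)), 1L)
  # outside the mask everything is zero
  expect_true(all(rc$sprite[, , 1][rc$mask == 0] == 0))
})

test_that("render_cell is deterministic and respects the radius range", {
  spec <- default_cell_specs()$neutrophil
  a <- render_cell(spec, seed = 11)
  b <- render_cell(spec, seed = 11)
  expect_identical(a$sprite, b$sprite)
  expect_identical(a$mask, b$mask)
  # fixed radius 10: area between the r=9 and r=11 discs
  fixed <- cell_class_spec("fixed", c(10, 10), c(200, 100, 100))
  area <- sum(render_cell(fixed, seed = 2)$mask)
  expect_gte(area, pi * 9^2)
  expect_lte(area, pi * 11^2)
  expect_error(cell_class_spec("bad", c(0, 5), c(1, 2, 3)))
})

test_that("render_cell mask is one 8-connected blob", {
  for (cl in c("erythrocyte", "neutrophil", "platelet", "monocyte")) {
    rc <- render_cell(default_cell_specs()[[cl]], seed = 4)
    lab <- hemosmear:::.cc_label8(matrix(as.integer(rc$mask),
                                         nrow(rc$mask), ncol(rc$mask)))
    expect_equal(max(lab), 1L)
  }
})

test_that("generate_smear honours counts, overlap and determinism", {
  # no cells: pure background
  empty <- generate_smear(smear_spec(cells_per_class =
                                       stats::setNames(rep(0L, 9),
                                                       CELL_CLASSES),
                                     noise_sigma = 0, seed = 1))
  expect_true(all(empty$instances == 0))
  expect_equal(length(empty$labels), 0L)

  # zero overlap: no two instance masks share a pixel and none were clipped
  s0 <- generate_smear(smear_spec(overlap_fraction = 0, seed = 3))
  expect_equal(s0$overlap_achieved, 0)
  areas <- table(s0$instances[s0$instances > 0])
  expect_equal(length(areas), length(s0$labels))

  # 9 classes x 5 cells: 45 distinct ids, one label each
  s45 <- generate_smear(smear_spec(height = 256, width = 256,
                                   cells_per_class =
                                     stats::setNames(rep(5L, 9),
                                                     CELL_CLASSES),
                                   seed = 7))
  ids <- sort(unique(s45$instances[s45$instances > 0]))
  expect_equal(length(ids), 45L)
  expect_equal(sort(as.integer(names(s45$labels))), ids)
  expect_equal(unname(table(s45$labels)[CELL_CLASSES]),
               rep(5L, 9), ignore_attr = TRUE)
  # achieved overlap within 0.1 of the target
  expect_lt(abs(s45$overlap_achieved - 0.25), 0.1)

  a <- generate_smear(smear_spec(seed = 9))
  b <- generate_smear(smear_spec(seed = 9))
  expect_identical(a$image, b$image)
  expect_identical(a$instances, b$instances)
})

test_that("instance masks stay 8-connected under occlusion", {
  for (sd in c(2, 5, 8)) {
    sm <- generate_smear(smear_spec(height = 192, width = 192,
                                    cells_per_class =
                                      stats::setNames(rep(3L, 9),
                                                      CELL_CLASSES),
                                    overlap_fraction = 0.4, seed = sd))
    for (id in unique(sm$instances[sm$instances > 0])) {
      lab <- hemosmear:::.cc_label8(matrix(as.integer(sm$instances == id),
                                           192, 192))
      expect_equal(max(lab), 1L)
    }
  }
})

test_that("placement failure names the class", {
  crowded <- smear_spec(height = 48L, width = 48L,
                        cells_per_class = c(monocyte = 12L), seed = 1)
  expect_error(generate_smear(crowded), "monocyte")
})

test_that("generate_roi_dataset writes a balanced, reproducible manifest", {
  root <- withr::local_tempdir()
  mf <- generate_roi_dataset(root, n_per_class = 2, roi_size = 48L,
                             seed = 4)
  expect_equal(nrow(mf), 18L)
  expect_equal(unname(table(mf$class)[CELL_CLASSES]), rep(2L, 9),
               ignore_attr = TRUE)
  # conservation: every manifest row has its file on disk, and vice versa
  expect_true(all(file.exists(mf$path)))
  expect_equal(length(list.files(file.path(root, "rois"), recursive = TRUE)),
               nrow(mf))
  h1 <- tools::md5sum(mf$path)
  root2 <- withr::local_tempdir()
  mf2 <- generate_roi_dataset(root2, n_per_class = 2, roi_size = 48L,
                              seed = 4)
  h2 <- tools::md5sum(mf2$path)
  expect_equal(unname(h1), unname(h2))

  expect_error(generate_roi_dataset(withr::local_tempdir(),
                                    n_per_class = 1, roi_size = 16L),
               "roi_size")
})

test_that("ROI counts can follow the reference class distribution", {
  root <- withr::local_tempdir()
  # proportional to the published distribution, scaled to tiny counts
  want <- stats::setNames(pmax(1L, round(REFERENCE_CLASS_COUNTS / 400)),
                          names(REFERENCE_CLASS_COUNTS))
  mf <- generate_roi_dataset(root, n_per_class = want, roi_size = 48L,
                             seed = 2)
  got <- table(mf$class)
  expect_equal(unname(got[names(want)]), unname(want), ignore_attr = TRUE)
  # the emulated ratio mirrors the source: erythrocyte 1200 vs basophil 969
  expect_equal(REFERENCE_CLASS_COUNTS[["erythrocyte"]], 1200L)
  expect_equal(REFERENCE_CLASS_COUNTS[["basophil"]], 969L)
})
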