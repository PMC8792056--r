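# Deterministic image quantification.

test_that("dual-channel cell counting recovers planted counts and boundaries", {
  im <- simulate_image(sim_image_config(height_px = 320, width_px = 320,
                                        n_cells = 12, n_nuclei_only = 3,
                                        p_agg = 0, seed = 1))
  dc <- detect_cells(im$image, nuc_threshold = 100, stain_threshold = 100,
                     min_cell_area_um2 = 50)
  expect_identical(dc$n_cells, 12L)

  # blank image: zero cells, valid empty mask
  blank <- mc_image_from(matrix(0, 32, 32), matrix(0, 32, 32), matrix(0, 32, 32))
  dc0 <- detect_cells(blank, 50, 50, 10)
  expect_identical(dc0$n_cells, 0L)
  expect_true(all(dc0$mask == 0))

  # area boundary: one pixel below the minimum is excluded, at it included
  nuc <- matrix(0, 32, 32); nuc[10:16, 10:16] <- 255
  stn <- matrix(0, 32, 32); stn[10:16, 10:16] <- 255   # 49 px at 1 um/px
  img49 <- mc_image_from(nuc, stn, stn, pixel_size_um = 1)
  expect_identical(detect_cells(img49, 50, 50, min_cell_area_um2 = 50)$n_cells, 0L)
  expect_identical(detect_cells(img49, 50, 50, min_cell_area_um2 = 49)$n_cells, 1L)
  expect_error(detect_cells(mc_image_from(nuc, nuc), 50, 50, 10), "stain")
})

test_that("aggregate segmentation recovers planted areas and splits touching blobs", {
  im <- simulate_image(sim_image_config(n_cells = 4, p_agg = 1,
                                        agg_area_um2 = c(6, 10),
                                        pixel_size_um = 0.5, seed = 2))
  sa <- segment_aggregates(im$image, intensity_threshold = 252, min_agg_area_um2 = 1)
  expect_identical(nrow(sa$table), 8L)
  expect_equal(sort(unique(sa$table$area_um2)), c(6, 10))

  # two touching equal discs are separated by the watershed
  m <- matrix(0, 64, 64)
  for (ctr in list(c(32, 23), c(32, 41))) {
    for (r in 1:64) for (c in 1:64) {
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 81) m[r, c] <- 255
    }
  }
  sa2 <- segment_aggregates(m, intensity_threshold = 200, min_agg_area_um2 = 1,
                            pixel_size_um = 0.5)
  expect_identical(nrow(sa2$table), 2L)
  expect_lt(abs(sa2$table$area_um2[1] - sa2$table$area_um2[2]), 1)

  # uniform sub-threshold image: empty table
  sub <- segment_aggregates(matrix(100, 32, 32), intensity_threshold = 252,
                            min_agg_area_um2 = 1, pixel_size_um = 1)
  expect_identical(nrow(sub$table), 0L)

  # determinism: identical image in, identical table out
  expect_identical(segment_aggregates(m, 200, 1, 0.5), sa2)
})

test_that("nuclear/extranuclear partition conserves aggregate area", {
  px <- 1
  labels <- matrix(0L, 40, 40)
  labels[10:12, 10:12] <- 1L   # inside the nucleus
  labels[30:32, 30:32] <- 2L   # far outside
  labels[10:12, 18:20] <- 3L   # straddling the dilated boundary
  tab <- data.frame(label = 1:3, area_um2 = 9,
                    centroid_row = c(11, 31, 11), centroid_col = c(11, 31, 19))
  agg <- list(labels = labels, table = tab)
  nucleus <- matrix(FALSE, 40, 40); nucleus[5:17, 5:17] <- TRUE
  cells <- matrix(0L, 40, 40); cells[1:25, 1:25] <- 1L

  loc <- localize_aggregates(agg, nucleus, pixel_size_um = px,
                             perinuclear_radius_um = 2, cell_labels = cells)
  expect_equal(loc$nuclear_area_um2[1], 9)
  expect_equal(loc$extranuclear_area_um2[1], 0)
  expect_equal(loc$nuclear_area_um2[2], 0)
  expect_equal(loc$extranuclear_area_um2[2], 9)
  expect_true(loc$nuclear_area_um2[3] > 0 && loc$extranuclear_area_um2[3] > 0)
  # conservation for every object, to within one pixel-area
  expect_true(all(abs(loc$nuclear_area_um2 + loc$extranuclear_area_um2 -
                        loc$area_um2) <= px^2))
  # parent assignment: objects 1 and 3 sit in cell 1; object 2 is orphaned
  expect_identical(loc$parent_cell[1], 1L)
  expect_true(loc$orphan[2] || loc$parent_cell[2] == 1L)
})

test_that("neuron z-stack pipeline applies projection and strict thresholds", {
  im <- simulate_image(sim_image_config(height_px = 512, width_px = 512,
                                        n_z = 15, n_cells = 20, p_agg = 0.3,
                                        neuron_mode = TRUE, seed = 3))
  res <- neuron_batch(list(im$image), n_slices = 15)
  expect_identical(res$n_cells, 20L)
  expect_equal(res$f_agg, 0.30)

  # too few slices are refused
  expect_error(neuron_batch(list(im$image), n_slices = 16), "slices")

  # strict boundary behaviour at the 240 intensity and 5 um^2 aggregate rules
  cellbody <- matrix(0, 64, 64)
  cellbody[20:29, 20:29] <- 250            # 100 um^2 cell at 1 um/px
  agg5 <- cellbody; agg5[22, 22:26] <- 255 # exactly 5 um^2 of aggregate
  img5 <- mc_image_from(matrix(0, 64, 64), agg5)
  r5 <- neuron_batch(list(img5), n_slices = 1)
  expect_identical(r5$n_agg_cells, 0L)     # 5 um^2 is not > 5 um^2

  agg6 <- cellbody; agg6[22, 22:27] <- 255
  r6 <- neuron_batch(list(mc_image_from(matrix(0, 64, 64), agg6)), n_slices = 1)
  expect_identical(r6$n_agg_cells, 1L)

  at240 <- matrix(0, 64, 64); at240[20:29, 20:29] <- 240
  r240 <- neuron_batch(list(mc_image_from(matrix(0, 64, 64), at240)), n_slices = 1)
  expect_identical(r240$n_cells, 0L)       # 240 is not > 240

  # cell size rule is strict at 50 um^2
  sq50 <- matrix(0, 64, 64); sq50[20:29, 20:24] <- 250  # exactly 50 um^2
  r50 <- neuron_batch(list(mc_image_from(matrix(0, 64, 64), sq50)), n_slices = 1)
  expect_identical(r50$n_cells, 0L)

  # an aggregate present in a single slice survives the maximum projection
  sl <- im$truth$agg_z
  agg_mask <- im$truth$agg_labels[, , sl] > 0
  mip <- apply(im$image$channels$reporter, c(1, 2), max)
  expect_true(all(mip[agg_mask] == 255))
})

test_that("batch comparison normalizes per experiment and tests conditions", {
  fa <- data.frame(image_id = sprintf("a%d", 1:4), experiment = "e1",
                   f_agg = c(0.30, 0.32, 0.28, 0.30))
  fb <- data.frame(image_id = sprintf("b%d", 1:4), experiment = "e1",
                   f_agg = c(0.22, 0.24, 0.20, 0.22))
  bc <- batch_compare(fa, fb)
  expect_equal(mean(bc$per_image$norm_f_agg), 1)
  expect_lt(bc$per_experiment$p, 0.05)

  # identical condition sets: t = 0, p = 1
  bc0 <- batch_compare(fa, transform(fa, image_id = paste0(image_id, "_b")))
  expect_identical(bc0$per_experiment$t, 0)
  expect_identical(bc0$per_experiment$p, 1)

  # power at a planted 26% relative difference with per-image counting noise
  hits <- 0L
  for (s in 1:10) {
    withr::with_seed(4000 + s, {
      n_img <- 24
      fA <- rbinom(n_img, 100, 0.300) / 100
      fB <- rbinom(n_img, 100, 0.222) / 100
    })
    res <- batch_compare(
      data.frame(image_id = sprintf("A%d", 1:24), experiment = "e", f_agg = fA),
      data.frame(image_id = sprintf("B%d", 1:24), experiment = "e", f_agg = fB))
    if (res$per_experiment$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("multi-channel TIFF round-trips with pixel-size metadata", {
  im <- simulate_image(sim_image_config(n_cells = 4, n_z = 3, seed = 5))
  path <- withr::local_tempfile(fileext = ".tiff")
  write_mc_tiff(im$image, path)
  back <- read_mc_tiff(path)
  expect_equal(back$pixel_size_um, im$image$pixel_size_um)
  expect_equal(back$channels$reporter, im$image$channels$reporter)
  expect_equal(names(back$channels), names(im$image$channels))
})
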