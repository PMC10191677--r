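# The scene generator must be a trustworthy oracle: its masks, distances and
# areas have to agree with the spec that produced them, bit-identically under
# a fixed seed.

test_that("ground-truth masks reproduce the specified geometry", {
  sp <- small_spec(seed = 3L)
  sc <- generate_scene(sp)
  gt <- sc$truth

  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(gt$post_mask_true * 1)))),
    nrow(gt$post_mask_true))
  expect_identical(max(lab), 2L)

  # pixel-snapped tip distance: mask measurement equals the recorded truth,
  # and the truth is within one pixel of the requested distance
  td <- tip_distance(gt$post_mask_true, 5.4)
  expect_equal(td$px, gt$tip_distance_true_px)
  expect_lt(abs(gt$tip_distance_true_um - sp$true_tip_distance), 5.4)

  # analytic band area (on the spec) matches the rasterised mask within 2%
  expect_lt(abs(gt$tissue_area_true_mm2 - sp$tissue_area_true) /
              sp$tissue_area_true, 0.02)
})

test_that("centroid separation matches the brute-force mask measurement", {
  sp <- scene_spec(true_tip_distance = 2000, pixel_size = 10, cap_radius = 150,
                   tile_px = 160L, field_grid = c(2L, 2L), tile_overlap = 0.1,
                   noise_sd = 0, shading_amplitude = 0, seed = 5L)
  sc <- generate_scene(sp, channels = "brightfield")
  gt <- sc$truth
  # edge-to-edge by exhaustive pixel-pair search
  expect_equal(brute_force_tip_distance(gt$post_mask_true), 200)
  # centroid-to-centroid = edge distance + both cap radii, within a pixel
  lab <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(
    EBImage::Image(gt$post_mask_true * 1)))), nrow(gt$post_mask_true))
  cx <- tapply(which(lab > 0, arr.ind = TRUE)[, 2], lab[lab > 0], mean)
  expect_lt(abs(abs(diff(cx)) - (200 + 2 * 150 / 10)), 1)
})

test_that("identical spec and seed render bit-identical scenes", {
  sp <- small_spec(seed = 21L)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$images$channels, b$images$channels)
  expect_identical(a$truth$post_mask_true, b$truth$post_mask_true)
  # a different seed changes the noise realisation
  sp2 <- small_spec(seed = 22L)
  expect_false(identical(generate_scene(sp2)$images$channels[[1]][[1]],
                         a$images$channels[[1]][[1]]))
})

test_that("increasing contraction strictly decreases the rendered distance", {
  d0 <- 1800
  dists <- vapply(c(0, 25, 50, 75), function(cpct) {
    sp <- small_spec(d0 * (1 - cpct / 100), seed = 8L)
    generate_scene(sp, channels = "brightfield")$truth$tip_distance_true_px
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("invalid scene specifications are rejected", {
  expect_error(small_spec(true_tip_distance = 0), class = "invalid_spec")
  expect_error(small_spec(true_tip_distance = -50), class = "invalid_spec")
  expect_error(scene_spec(pixel_size = 0), class = "invalid_spec")
  expect_error(small_spec(shading_amplitude = 1), class = "invalid_spec")
  expect_error(small_spec(tile_overlap = 0.6), class = "invalid_spec")
  # scene too large for the mosaic
  expect_error(scene_spec(true_tip_distance = 5000, pixel_size = 5.4,
                          tile_px = 288L), class = "invalid_spec")
})

test_that("well image sets round-trip through TIFF + JSON sidecar", {
  sp <- small_spec(seed = 31L, tile_px = 96L, true_tip_distance = 300,
                   cap_radius = 60, n_zplanes = 2L)
  sc <- generate_scene(sp)
  dir <- withr::local_tempdir()
  write_well_images(sc, dir, "A1")
  back <- read_well_images(dir, "A1")
  expect_equal(back$pixel_size, sp$pixel_size)
  expect_equal(back$grid, sp$field_grid)
  # 16-bit quantisation: intensities agree to 1/65535
  orig <- clipv(sc$images$channels$brightfield[[1]][, , 1], 0, 1)
  expect_lt(max(abs(back$channels$brightfield[[1]][, , 1] - orig)), 1 / 65000)
  expect_equal(attr(back, "truth")$tip_distance_true_um,
               sc$truth$tip_distance_true_um)
})

test_that("screen simulation honours the effect model and exclusion truth", {
  conds <- data.frame(
    condition = c("control", "inhibitorA"),
    mean_contraction = c(67, 67), sd_contraction = c(0, 0),
    n_wells = c(6L, 6L))
  des <- plate_design(conds, "control", dead_wells = "A3",
                      damaged_wells = "A5", seed = 9L)
  sim <- simulate_screen(des)
  tab <- sim$table
  # zero variance: every non-dead well sits exactly at the condition mean
  expect_true(all(tab$true_contraction_pct[!tab$dead] == 67))
  expect_true(tab$dead[tab$well_id == "A3"])
  expect_true(tab$damaged[tab$well_id == "A5"])
  # distances back-computed from sampled contraction
  expect_equal(tab$dt_um, tab$d0_um * (1 - tab$true_contraction_pct / 100))
  # excluded wells never survive into the analysed set
  agg <- aggregate_and_exclude(tab)
  kept <- agg$wells$well_id[!agg$wells$excluded]
  expect_length(intersect(kept, c("A3", "A5")), 0)
  # same seed, same table
  expect_identical(simulate_screen(des)$table, tab)
})

test_that("screen simulation rejects conditions without an effect model", {
  conds <- data.frame(condition = "control", mean_contraction = 67,
                      sd_contraction = 2, n_wells = 4L)
  des <- plate_design(conds, "control")
  des$wells$condition[1] <- "mystery"
  expect_error(simulate_screen(des), class = "config_error")
  expect_error(plate_design(conds, "missing"), class = "config_error")
  conds$n_wells <- 120L
  expect_error(plate_design(conds, "control"), class = "config_error")
})
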