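# Mask-to-readout conversions: tip distance metrology, contraction, force,
# area, viability.

test_that("tip distance matches hand geometry", {
  # single-pixel components at (0,0) and (3,4): a 3-4-5 triangle
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE
  m[4, 5] <- TRUE
  res <- tip_distance(m, pixel_size = 2, witness = TRUE)
  expect_equal(res$px, 5)
  expect_equal(res$um, 10)
  expect_equal(unname(res$pair), rbind(c(0, 0), c(3, 4)))

  # two filled discs, radius 10, centres 100 apart: edge-to-edge 80
  rows <- seq_len(60); cols <- seq_len(160)
  d1 <- outer((rows - 30)^2, (cols - 30)^2, "+") <= 100
  d2 <- outer((rows - 30)^2, (cols - 130)^2, "+") <= 100
  expect_equal(tip_distance(d1 | d2)$px, 80)
})

test_that("tip distance equals the exhaustive pixel-pair minimum", {
  set.seed(101)
  for (i in 1:25) {
    m <- random_blob_pair()
    expect_identical(max(micropost:::label_components(m)), 2L)
    expect_equal(tip_distance(m)$px, brute_force_tip_distance(m))
  }
})

test_that("tip distance is invariant to intensity-preserving mask sources", {
  # rescaling intensities upstream cannot change a mask-based measurement;
  # encode the mask as 0/1 numerics vs logicals to check input tolerance
  m <- random_blob_pair()
  expect_equal(tip_distance(m)$px, tip_distance(m * 1)$px)
})

test_that("tip distance reports component-count failures with qc context", {
  err <- tryCatch(tip_distance(matrix(FALSE, 5, 5)), error = identity)
  expect_s3_class(err, "measurement_error")
  expect_identical(err$qc, "no_posts")
  m <- matrix(FALSE, 10, 10); m[1, 1] <- TRUE; m[5, 5] <- TRUE; m[9, 9] <- TRUE
  err <- tryCatch(tip_distance(m), error = identity)
  expect_identical(err$n_components, 3L)
})

test_that("contraction percentages follow 100 (d0 - dt) / d0", {
  expect_equal(contraction_percent(100, 100), 0)
  expect_equal(contraction_percent(100, 33), 67)
  expect_equal(contraction_percent(2000, 500), 75)
  expect_equal(acute_response(1500, 1350), 10)
  expect_error(contraction_percent(0, 10), class = "input_error")
  expect_error(acute_response(-5, 1), class = "input_error")
})

test_that("force follows k times half the displacement, clamped at zero", {
  expect_equal(as.numeric(deflection_to_force(1000, 1000)), 0)
  # 20 um total displacement at k = 0.109: delta 10 um, force 1.09 uN
  expect_equal(as.numeric(deflection_to_force(1000, 980, k = 0.109)), 1.09)
  # linear and homogeneous in the displacement
  f1 <- as.numeric(deflection_to_force(1000, 980))
  f2 <- as.numeric(deflection_to_force(1000, 960))
  expect_equal(f2, 2 * f1)
  expect_warning(f <- deflection_to_force(1000, 1010), "relax")
  expect_equal(as.numeric(f), 0)
  expect_true(attr(f, "relaxed"))
  expect_error(deflection_to_force(10, 5, k = 0), class = "input_error")
})

test_that("tissue area counts pixels and converts units", {
  rows <- seq_len(120); cols <- seq_len(120)
  disc <- outer((rows - 60)^2, (cols - 60)^2, "+") <= 50^2
  a <- tissue_area(disc, pixel_size = 1)
  expect_lt(abs(a$px2 - pi * 50^2) / (pi * 50^2), 0.02)
  # 1000 px at 1.3 um/px -> 1.69e-3 mm^2
  m <- matrix(FALSE, 40, 40); m[seq_len(1000)] <- TRUE
  expect_equal(tissue_area(m, 1.3)$mm2, 1.69e-3)
  z <- tissue_area(matrix(FALSE, 5, 5), 1)
  expect_equal(z$px2, 0)
  expect_identical(z$status, "tissue_absent")
})

test_that("rendered scene area is recovered within 5% of truth", {
  sc <- generate_scene(small_spec(1300, TRUE, seed = 44L))
  fa <- preprocess_well(sc$images, "factin", bin = 4L,
                        shading_method = "none")
  seg <- segment_tissue(fa, NULL)
  a <- tissue_area(seg$tissue_mask, attr(fa, "pixel_size"))
  expect_lt(abs(a$mm2 - sc$truth$tissue_area_true_mm2) /
              sc$truth$tissue_area_true_mm2, 0.05)
})

test_that("viability interpolates linearly between the reference levels", {
  mask <- matrix(TRUE, 4, 4)
  img <- function(v) matrix(v, 4, 4)
  expect_equal(viability_score(img(0.6), mask)$score, 1)
  expect_equal(viability_score(img(0.1), mask)$score, 0)
  expect_equal(viability_score(img(0.35), mask)$score, 0.5)
  expect_identical(viability_score(img(0.1), mask)$status, "dead")
  expect_identical(viability_score(img(0.5), mask)$status, "live")
  expect_identical(viability_score(img(1), matrix(FALSE, 4, 4))$status,
                   "no_tissue")
  expect_error(viability_score(img(1), mask, live_ref = 0.1, dead_ref = 0.6),
               class = "reference_error")
})

test_that("an acute stimulus shift is recovered end to end", {
  clf <- test_classifier()
  pre <- generate_scene(small_spec(1500, TRUE, seed = 61L),
                        channels = "brightfield")
  post <- generate_scene(small_spec(1350, TRUE, seed = 62L),
                         channels = "brightfield")
  cap_area <- pi * (200 / 5.4)^2
  d <- function(sc) tip_distance(segment_posts(
    preprocess_well(sc$images, "brightfield"), clf, cap_area)$post_mask,
    5.4)$um
  measured <- acute_response(d(pre), d(post))
  truth <- acute_response(pre$truth$tip_distance_true_um,
                          post$truth$tip_distance_true_um)
  expect_lt(abs(measured - truth), 2)
})
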