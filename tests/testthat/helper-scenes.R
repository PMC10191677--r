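# Shared fixtures: all synthetic, generated in code at test time.

# Desk-scale scene: 2x2 tiles of 288 px at 10% overlap (547 px mosaic),
# 5.4 um/px, the same cap geometry as the full-scale default.
small_spec <- function(true_tip_distance = 1800, tissue_present = TRUE,
                       seed = 1L, noise_sd = 0.01, shading_amplitude = 0.15,
                       cap_radius = 200, pixel_size = 5.4, tile_px = 288L,
                       tile_overlap = 0.1, n_zplanes = 3L, ...) {
  scene_spec(true_tip_distance = true_tip_distance, cap_radius = cap_radius,
             pixel_size = pixel_size, tile_px = tile_px,
             field_grid = c(2L, 2L), tile_overlap = tile_overlap,
             n_zplanes = n_zplanes, tissue_present = tissue_present,
             noise_sd = noise_sd, shading_amplitude = shading_amplitude,
             seed = seed, ...)
}

label_image_from_truth <- function(truth) {
  l <- matrix(0L, nrow(truth$post_mask_true), ncol(truth$post_mask_true))
  l[truth$post_mask_true] <- 1L
  l[truth$tissue_mask_true] <- 2L
  l
}

# Train the reference classifier once per test run and cache it.
.test_cache <- new.env(parent = emptyenv())
test_classifier <- function() {
  if (is.null(.test_cache$clf)) {
    scenes <- lapply(list(
      small_spec(1800, TRUE, seed = 11L),
      small_spec(900, TRUE, seed = 12L),
      small_spec(1400, FALSE, seed = 13L)
    ), generate_scene)
    imgs <- lapply(scenes, function(s)
      preprocess_well(s$images, "brightfield"))
    labs <- lapply(scenes, function(s) label_image_from_truth(s$truth))
    .test_cache$clf <- train_pixel_classifier(imgs, labs, seed = 42L)
  }
  .test_cache$clf
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Exhaustive pixel-pair minimum distance between the two components of a
# mask: the independent metrology oracle.
brute_force_tip_distance <- function(mask) {
  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image((mask != 0) * 1)))), nrow(mask))
  pa <- which(lab == 1L, arr.ind = TRUE)
  pb <- which(lab == 2L, arr.ind = TRUE)
  sqrt(min(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2))
}

# A connected random blob: a chain of overlapping discs inside a column band.
random_blob <- function(h, w, col_range, n_discs = 4L, r_max = 5) {
  mask <- matrix(FALSE, h, w)
  cy <- runif(1, r_max + 1, h - r_max)
  cx <- runif(1, col_range[1] + r_max, col_range[2] - r_max)
  rows <- seq_len(h); cols <- seq_len(w)
  for (i in seq_len(n_discs)) {
    r <- runif(1, 1.5, r_max)
    mask <- mask | outer((rows - cy)^2, (cols - cx)^2, "+") <= r^2
    # next centre inside the current disc keeps the blob connected
    ang <- runif(1, 0, 2 * pi)
    cy <- clipv(cy + 0.9 * r * sin(ang), r_max + 1, h - r_max)
    cx <- clipv(cx + 0.9 * r * cos(ang),
                col_range[1] + r_max, col_range[2] - r_max)
  }
  mask
}

clipv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Two connected blobs in disjoint column bands: exactly two components.
random_blob_pair <- function(h = 60, w = 80) {
  m <- random_blob(h, w, c(1, floor(w / 2) - 2)) |
    random_blob(h, w, c(ceiling(w / 2) + 2, w))
  m
}
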