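# Synthetic well scenes with known ground truth.
#
# A scene is one well of a cantilever-post contractility assay: two dark
# elastomer post caps on a bright background (brightfield), optionally bridged
# by a microtissue band, plus an F-actin channel that delimits tissue area and
# a TMRM channel whose in-tissue intensity encodes viability. The scene is
# rendered as overlapping tiles (fields of view) with per-tile multiplicative
# vignetting and additive Gaussian noise, and a small z-stack per tile, so the
# full conditioning chain (shading correction, stitching, projection) can be
# exercised against exact ground truth.

#' Specify a synthetic well scene
#'
#' Builds a validated generative description of a single well. The defaults
#' describe the study-scale acquisition this generator emulates: a 2x2 grid of
#' 1137x1137 px fields at 10% overlap (a 2160x2160 px stitched mosaic), a
#' 1.35 um/px pixel size, two post caps of 200 um radius separated by an
#' 1800 um edge-to-edge tip distance, and a tissue band bridging the caps.
#'
#' @param true_tip_distance Edge-to-edge distance between the two cap masks,
#'   in micrometres. Snapped to the nearest whole pixel at render time.
#' @param cap_radius Post-cap radius in micrometres.
#' @param cap_depth_contrast Brightfield intensity drop of the caps relative
#'   to background (intensities are on a 0-1 scale).
#' @param tissue_present Logical; render a tissue band bridging the caps?
#' @param tissue_width Full tissue width at the anchor points, micrometres.
#' @param waist_frac Waist width as a fraction of `tissue_width`; tightened
#'   tissues have narrower waists. The half-width profile is quadratic.
#' @param tissue_contrast Brightfield intensity drop of the tissue band.
#' @param shading_amplitude Peak fractional loss of the per-tile vignetting
#'   gain field (0 = flat illumination). Must lie in [0, 1).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param field_grid Integer vector `c(rows, cols)` of tiled fields of view.
#' @param tile_px Side length of one square field, pixels.
#' @param tile_overlap Per-seam overlap as a fraction of `tile_px`, in
#'   [0, 0.5).
#' @param n_zplanes Number of z-planes per field.
#' @param pixel_size Pixel size, micrometres per pixel.
#' @param background Brightfield background intensity.
#' @param viability_true True tissue viability in [0, 1]; sets the TMRM
#'   in-tissue intensity between the dead and live reference levels.
#' @param seed Integer seed; identical specs render bit-identical images.
#'
#' @return An object of class `scene_spec`. The analytic tissue area implied
#'   by the band geometry is available as `$tissue_area_true` (mm^2).
#' @export
scene_spec <- function(true_tip_distance = 1800,
                       cap_radius = 200,
                       cap_depth_contrast = 0.45,
                       tissue_present = TRUE,
                       tissue_width = 500,
                       waist_frac = 0.65,
                       tissue_contrast = 0.18,
                       shading_amplitude = 0.15,
                       noise_sd = 0.01,
                       field_grid = c(2L, 2L),
                       tile_px = 1137L,
                       tile_overlap = 0.1,
                       n_zplanes = 3L,
                       pixel_size = 1.35,
                       background = 0.75,
                       viability_true = 1.0,
                       seed = 1L) {
  spec <- structure(
    list(
      true_tip_distance = true_tip_distance, cap_radius = cap_radius,
      cap_depth_contrast = cap_depth_contrast,
      tissue_present = isTRUE(tissue_present), tissue_width = tissue_width,
      waist_frac = waist_frac, tissue_contrast = tissue_contrast,
      shading_amplitude = shading_amplitude, noise_sd = noise_sd,
      field_grid = as.integer(field_grid), tile_px = as.integer(tile_px),
      tile_overlap = tile_overlap, n_zplanes = as.integer(n_zplanes),
      pixel_size = pixel_size, background = background,
      viability_true = viability_true, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
  spec$tissue_area_true <- scene_tissue_area_mm2(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (!is.finite(spec$pixel_size) || spec$pixel_size <= 0)
    mp_stop("pixel_size must be > 0", "invalid_spec")
  if (!is.finite(spec$true_tip_distance) || spec$true_tip_distance <= 0)
    mp_stop("caps overlap: true_tip_distance must be > 0 (edge-to-edge)",
            "invalid_spec")
  if (spec$cap_radius <= 0)
    mp_stop("cap_radius must be > 0", "invalid_spec")
  if (spec$shading_amplitude < 0 || spec$shading_amplitude >= 1)
    mp_stop("shading_amplitude must lie in [0, 1)", "invalid_spec")
  if (spec$tile_overlap < 0 || spec$tile_overlap >= 0.5)
    mp_stop("tile_overlap must lie in [0, 0.5)", "invalid_spec")
  if (any(spec$field_grid < 1L) || length(spec$field_grid) != 2L)
    mp_stop("field_grid must be c(rows, cols) of positive counts",
            "invalid_spec")
  if (spec$n_zplanes < 1L) mp_stop("n_zplanes must be >= 1", "invalid_spec")
  m <- mosaic_size(spec$tile_px, spec$field_grid, spec$tile_overlap)
  span <- round(spec$true_tip_distance / spec$pixel_size) +
    4 * spec$cap_radius / spec$pixel_size
  if (span > min(m) - 4)
    mp_stop(sprintf(
      "scene does not fit: caps span %.0f px but mosaic is %d x %d px",
      span, m[1], m[2]), "invalid_spec")
  invisible(spec)
}

#' Nominal stitched mosaic size for a tile grid
#'
#' `step = tile - round(overlap * tile)`; the mosaic spans
#' `(grid - 1) * step + tile` pixels along each axis.
#'
#' @param tile_px Tile side length, px.
#' @param grid Integer vector `c(rows, cols)`.
#' @param overlap Per-seam overlap fraction of the tile size.
#' @return Integer vector `c(height, width)` in pixels.
#' @export
mosaic_size <- function(tile_px, grid, overlap) {
  step <- tile_px - as.integer(round(overlap * tile_px))
  as.integer((grid - 1L) * step + tile_px)
}

# Analytic area (mm^2) of the quadratic-waist tissue band.
scene_tissue_area_mm2 <- function(spec) {
  if (!spec$tissue_present) return(0)
  ps <- spec$pixel_size
  g_px <- round(spec$true_tip_distance / ps)
  len <- g_px - 1                       # rasterised columns strictly between caps
  w_px <- spec$tissue_width / ps
  wf <- spec$waist_frac
  area_px2 <- w_px * len * (wf + (1 - wf) / 3)
  area_px2 * (ps * 1e-3)^2
}

# Scene geometry in mosaic pixel coordinates (1-based rows/cols internally).
scene_geometry <- function(spec) {
  ps <- spec$pixel_size
  m <- mosaic_size(spec$tile_px, spec$field_grid, spec$tile_overlap)
  g_px <- as.integer(round(spec$true_tip_distance / ps))
  rc <- spec$cap_radius / ps
  a <- floor((m[2] - g_px) / 2)         # inner edge column of left cap
  b <- a + g_px                         # inner edge column of right cap
  cy <- floor((m[1] + 1) / 2)
  list(m = m, g_px = g_px, rc = rc, a = a, b = b, cy = cy,
       centers = rbind(left = c(cy, a - rc), right = c(cy, b + rc)))
}

rasterize_caps <- function(geo) {
  m <- geo$m
  rows <- seq_len(m[1]); cols <- seq_len(m[2])
  mask <- matrix(FALSE, m[1], m[2])
  for (k in 1:2) {
    cyx <- geo$centers[k, ]
    dy2 <- (rows - cyx[1])^2
    dx2 <- (cols - cyx[2])^2
    # tolerance keeps the innermost boundary pixel (placed at exactly rc)
    # inside the cap despite floating-point rounding
    mask <- mask | outer(dy2, dx2, "+") <= geo$rc^2 + 1e-6
  }
  mask
}

rasterize_tissue <- function(spec, geo) {
  m <- geo$m
  mask <- matrix(FALSE, m[1], m[2])
  if (!spec$tissue_present || geo$g_px < 3) return(mask)
  xs <- (geo$a + 1L):(geo$b - 1L)
  u <- (xs - geo$a) / geo$g_px
  w_px <- spec$tissue_width / spec$pixel_size
  h <- (w_px / 2) * (spec$waist_frac + (1 - spec$waist_frac) * (2 * u - 1)^2)
  rows <- seq_len(m[1])
  for (i in seq_along(xs)) {
    # area-consistent rasterisation: a column of half-width h covers ~2h px
    mask[abs(rows - geo$cy) <= h[i] - 0.5, xs[i]] <- TRUE
  }
  mask
}

# TMRM reference intensities shared by the generator and the viability readout.
TMRM_LIVE_REF <- 0.6
TMRM_DEAD_REF <- 0.1

#' Render a synthetic well
#'
#' Rasterises the scene onto the stitched-mosaic frame, then cuts overlapping
#' tiles, applies an identical per-tile vignetting gain (quadratic radial
#' fall-off of amplitude `shading_amplitude`), builds a z-stack per tile
#' (out-of-focus planes are uniformly dimmed), and adds Gaussian noise.
#' Identical `(spec, seed)` produce bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @param channels Channels to render, subset of
#'   `c("brightfield", "factin", "tmrm")`.
#' @return A list with components
#'   * `images`: a `well_image_set` — per-channel lists of row-major tile
#'     arrays of dimension `tile_px x tile_px x n_zplanes`, plus acquisition
#'     metadata (`grid`, `tile_px`, `overlap`, `pixel_size`, `mosaic_dim`);
#'   * `truth`: a `ground_truth` — `post_mask_true` and `tissue_mask_true` in
#'     the mosaic frame, `tip_distance_true_px` / `tip_distance_true_um`
#'     (pixel-snapped), `tissue_area_true_px2` / `tissue_area_true_mm2`
#'     (counted on the mask), and `viability_true`.
#' @export
generate_scene <- function(spec,
                           channels = c("brightfield", "factin", "tmrm")) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  channels <- match.arg(channels, several.ok = TRUE)
  geo <- scene_geometry(spec)
  post <- rasterize_caps(geo)
  tissue <- rasterize_tissue(spec, geo) & !post

  clean <- list()
  if ("brightfield" %in% channels) {
    clean$brightfield <- matrix(spec$background, geo$m[1], geo$m[2]) -
      spec$cap_depth_contrast * post - spec$tissue_contrast * tissue
  }
  if ("factin" %in% channels) {
    clean$factin <- matrix(0.05, geo$m[1], geo$m[2]) + 0.6 * tissue
  }
  if ("tmrm" %in% channels) {
    lvl <- TMRM_DEAD_REF +
      clip(spec$viability_true, 0, 1) * (TMRM_LIVE_REF - TMRM_DEAD_REF)
    clean$tmrm <- matrix(0.02, geo$m[1], geo$m[2]) + lvl * tissue
  }

  t_px <- spec$tile_px
  step <- t_px - as.integer(round(spec$tile_overlap * t_px))
  gain <- vignette_gain(t_px, spec$shading_amplitude)
  focus <- ceiling(spec$n_zplanes / 2)
  zscale <- 1 - 0.03 * abs(seq_len(spec$n_zplanes) - focus)

  images <- with_seed(spec$seed, {
    lapply(clean, function(ch) {
      tiles <- vector("list", prod(spec$field_grid))
      k <- 1L
      for (r in seq_len(spec$field_grid[1])) {
        for (cc in seq_len(spec$field_grid[2])) {
          y0 <- (r - 1L) * step
          x0 <- (cc - 1L) * step
          base <- ch[y0 + seq_len(t_px), x0 + seq_len(t_px)]
          arr <- array(0, dim = c(t_px, t_px, spec$n_zplanes))
          for (z in seq_len(spec$n_zplanes)) {
            plane <- base * zscale[z] * gain
            if (spec$noise_sd > 0)
              plane <- plane + matrix(stats::rnorm(t_px * t_px,
                                                   sd = spec$noise_sd),
                                      t_px, t_px)
            arr[, , z] <- plane
          }
          tiles[[k]] <- arr
          k <- k + 1L
        }
      }
      tiles
    })
  })

  ws <- structure(
    list(channels = images, grid = spec$field_grid, tile_px = t_px,
         overlap = spec$tile_overlap, pixel_size = spec$pixel_size,
         mosaic_dim = geo$m),
    class = "well_image_set"
  )
  gt <- structure(
    list(post_mask_true = post, tissue_mask_true = tissue,
         tip_distance_true_px = geo$g_px,
         tip_distance_true_um = geo$g_px * spec$pixel_size,
         tissue_area_true_px2 = sum(tissue),
         tissue_area_true_mm2 = sum(tissue) * (spec$pixel_size * 1e-3)^2,
         viability_true = spec$viability_true),
    class = "ground_truth"
  )
  list(images = ws, truth = gt)
}

# Per-tile multiplicative vignetting: quadratic radial fall-off, unit gain at
# the tile centre, (1 - amplitude) at the corners.
vignette_gain <- function(t_px, amplitude) {
  if (amplitude == 0) return(matrix(1, t_px, t_px))
  u <- (seq_len(t_px) - (t_px + 1) / 2) / ((t_px - 1) / 2)
  rho2 <- (outer(u^2, u^2, "+")) / 2
  1 - amplitude * rho2
}

#' @export
print.scene_spec <- function(x, ...) {
  m <- mosaic_size(x$tile_px, x$field_grid, x$tile_overlap)
  cat(sprintf(
    paste0("scene_spec: tip distance %.0f um, cap radius %.0f um, ",
           "%s tissue\n  %dx%d tiles of %d px (overlap %.0f%%) -> ",
           "%d x %d px mosaic @ %.3g um/px, %d z-planes, seed %d\n"),
    x$true_tip_distance, x$cap_radius,
    if (x$tissue_present) "with" else "no",
    x$field_grid[1], x$field_grid[2], x$tile_px, 100 * x$tile_overlap,
    m[1], m[2], x$pixel_size, x$n_zplanes, x$seed))
  invisible(x)
}
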