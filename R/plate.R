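# Plate-level simulation: condition effects, damaged and dead wells.

#' Design a simulated screening plate
#'
#' Lays out wells on a standard 8x12 (96-well) grid and assigns each a
#' condition with a contraction effect model, mirroring a compound screen in
#' which every condition has a known mean percent contraction and
#' well-to-well standard deviation, and some wells are damaged (tissue torn
#' or detached) or dead.
#'
#' @param conditions Data frame with columns `condition`, `mean_contraction`
#'   (percent), `sd_contraction` (percent, >= 0) and `n_wells` (wells to
#'   allocate per condition). An optional `n_replicates` column overrides the
#'   global replicate count per condition (e.g. every control well its own
#'   biological replicate, compound wells paired into technical duplicates).
#' @param control_label The condition acting as the treated control; must
#'   appear in `conditions`.
#' @param damaged_wells,dead_wells Character vectors of well ids (e.g. "B6")
#'   flagged as damaged / dead in the simulated truth.
#' @param n_replicates Number of biological replicates to cycle wells
#'   through within each condition.
#' @param seed Integer seed used by [simulate_screen()].
#' @return A `plate_design`: the per-well layout plus the effect model.
#' @export
plate_design <- function(conditions, control_label,
                         damaged_wells = character(),
                         dead_wells = character(),
                         n_replicates = 2L,
                         seed = 1L) {
  req <- c("condition", "mean_contraction", "sd_contraction", "n_wells")
  if (!is.data.frame(conditions) || !all(req %in% names(conditions)))
    mp_stop(paste("conditions needs columns:", paste(req, collapse = ", ")),
            "config_error")
  if (!control_label %in% conditions$condition)
    mp_stop(sprintf("control label '%s' not among conditions", control_label),
            "config_error")
  if (any(conditions$sd_contraction < 0))
    mp_stop("sd_contraction must be >= 0", "config_error")
  n_total <- sum(conditions$n_wells)
  if (n_total > 96L)
    mp_stop(sprintf("%d wells requested; a plate holds at most 96", n_total),
            "config_error")
  ids <- well_ids_96()[seq_len(n_total)]
  cond <- rep(conditions$condition, conditions$n_wells)
  nrep <- conditions$n_replicates %||% rep(n_replicates, nrow(conditions))
  repl <- unlist(Map(function(n, k) rep_len(seq_len(k), n),
                     conditions$n_wells, nrep))
  wells <- data.frame(well_id = ids, condition = cond, replicate = repl,
                      stringsAsFactors = FALSE)
  unknown <- setdiff(c(damaged_wells, dead_wells), wells$well_id)
  if (length(unknown))
    mp_stop(paste("flagged wells not on the plate:",
                  paste(unknown, collapse = ", ")), "config_error")
  structure(
    list(wells = wells, control_label = control_label,
         effect_model = conditions,
         damaged_wells = unique(damaged_wells),
         dead_wells = unique(dead_wells), seed = as.integer(seed)),
    class = "plate_design"
  )
}

#' Well ids of an 8x12 plate in row-major order (A1 ... H12)
#' @return Character vector of length 96.
#' @export
well_ids_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Canonical replicated 96-well screen design
#'
#' One plate: a treated-control group of `n_control` wells (each well its own
#' biological replicate, as the robust control dispersion is computed over
#' control wells), plus compound conditions laid out as two biological
#' replicates of three technical wells each (6 wells per compound; biological
#' values are means of at least three technical replicates in replicated
#' screening practice). `n_inhibitors` conditions carry a strong
#' contraction-suppressing effect; `n_inactive` sit at the control level.
#' The defaults fill the plate exactly: 18 control wells plus 13 compounds
#' of 6 wells.
#'
#' @param n_inhibitors,n_inactive Number of active / inactive compound
#'   conditions (6 wells each).
#' @param n_control Control wells.
#' @param control_mean,control_sd Control contraction effect model (percent).
#' @param inhibitor_mean Mean contraction of active compounds (percent).
#' @param damaged_wells,dead_wells Passed through to [plate_design()].
#' @param seed Simulation seed.
#' @return A [plate_design()].
#' @export
kinase_screen_design <- function(n_inhibitors = 5L, n_inactive = 8L,
                                 n_control = 18L, control_mean = 67,
                                 control_sd = 2, inhibitor_mean = 30,
                                 damaged_wells = character(),
                                 dead_wells = character(), seed = 1L) {
  conds <- data.frame(
    condition = c("TGFB1", sprintf("inhibitor%02d", seq_len(n_inhibitors)),
                  sprintf("compound%02d", seq_len(n_inactive))),
    mean_contraction = c(control_mean, rep(inhibitor_mean, n_inhibitors),
                         rep(control_mean, n_inactive)),
    sd_contraction = control_sd,
    n_wells = c(n_control, rep(6L, n_inhibitors + n_inactive)),
    n_replicates = c(n_control, rep(2L, n_inhibitors + n_inactive)))
  plate_design(conds, "TGFB1", damaged_wells = damaged_wells,
               dead_wells = dead_wells, seed = seed)
}

#' Simulate a screening plate
#'
#' Draws each well's true percent contraction from its condition's
#' `(mean, sd)` effect model and back-computes the rendered tip distance from
#' the baseline spacing. Dead wells keep their sampled contraction at a
#' collapsed level and receive a near-zero viability; damaged wells carry a
#' `damaged` QC flag. In tabular mode (default) no images are rendered; with
#' `render = TRUE` each well also receives a rendered scene whose true tip
#' distance matches its sampled contraction.
#'
#' @param design A [plate_design()].
#' @param scene_template A [scene_spec()] providing baseline geometry (its
#'   `true_tip_distance` is the unseeded spacing D0). Required when
#'   `render = TRUE`; defaults to `scene_spec()` otherwise.
#' @param render Render per-well images?
#' @return A list with `table` — one row per well: `well_id`, `condition`,
#'   `replicate`, `true_contraction_pct`, `d0_um`, `dt_um`,
#'   `viability_score`, `damaged`, `dead`, `qc_flags` — and, when rendering,
#'   `scenes`, a named list of [generate_scene()] outputs.
#' @export
simulate_screen <- function(design, scene_template = NULL, render = FALSE) {
  stopifnot(inherits(design, "plate_design"))
  if (is.null(scene_template)) scene_template <- scene_spec()
  em <- design$effect_model
  unknown <- setdiff(design$wells$condition, em$condition)
  if (length(unknown))
    mp_stop(paste("conditions without an effect model:",
                  paste(unknown, collapse = ", ")), "config_error")
  d0 <- scene_template$true_tip_distance
  w <- design$wells
  idx <- match(w$condition, em$condition)

  tab <- with_seed(design$seed, {
    contraction <- stats::rnorm(nrow(w), em$mean_contraction[idx],
                                em$sd_contraction[idx])
    contraction <- clip(contraction, 0, 99)
    dead <- w$well_id %in% design$dead_wells
    damaged <- w$well_id %in% design$damaged_wells
    # dead tissues relax toward baseline and lose TMRM signal
    contraction[dead] <- clip(stats::rnorm(sum(dead), 5, 2), 0, 99)
    viability <- clip(stats::rnorm(nrow(w), 0.92, 0.03), 0, 1)
    viability[dead] <- clip(stats::rnorm(sum(dead), 0.05, 0.02), 0, 1)
    data.frame(
      well_id = w$well_id, condition = w$condition, replicate = w$replicate,
      true_contraction_pct = contraction,
      # tabular mode: the "measured" contraction is the simulated truth
      contraction_pct = contraction,
      d0_um = d0, dt_um = d0 * (1 - contraction / 100),
      viability_score = viability, damaged = damaged, dead = dead,
      qc_flags = ifelse(damaged, "damaged", ""),
      stringsAsFactors = FALSE
    )
  })

  out <- list(table = tab)
  if (render) {
    out$scenes <- lapply(seq_len(nrow(tab)), function(i) {
      sp <- scene_template
      sp$true_tip_distance <- tab$dt_um[i]
      sp$viability_true <- tab$viability_score[i]
      sp$seed <- (design$seed + i) %% .Machine$integer.max
      sp$tissue_area_true <- scene_tissue_area_mm2(sp)
      validate_scene_spec(sp)
      generate_scene(sp)
    })
    names(out$scenes) <- tab$well_id
  }
  out
}

#' Write a rendered well to disk
#'
#' One multi-page TIFF per channel (pages ordered tile-major, then z-plane)
#' plus a JSON sidecar carrying pixel size, tiling metadata and the scalar
#' ground truth.
#'
#' @param scene Output of [generate_scene()].
#' @param dir Output directory (created if needed).
#' @param well_id Stem used for file names.
#' @return Invisibly, the paths written.
#' @export
write_well_images <- function(scene, dir, well_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ws <- scene$images
  paths <- character()
  for (ch in names(ws$channels)) {
    pages <- list()
    for (tile in ws$channels[[ch]])
      for (z in seq_len(dim(tile)[3]))
        pages[[length(pages) + 1L]] <- clip(tile[, , z], 0, 1)
    p <- file.path(dir, sprintf("%s_%s.tif", well_id, ch))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  gt <- scene$truth
  meta <- list(
    well_id = well_id, pixel_size_um = ws$pixel_size,
    grid = ws$grid, tile_px = ws$tile_px, overlap = ws$overlap,
    n_zplanes = dim(ws$channels[[1]][[1]])[3],
    channels = names(ws$channels),
    truth = list(tip_distance_true_um = gt$tip_distance_true_um,
                 tip_distance_true_px = gt$tip_distance_true_px,
                 tissue_area_true_mm2 = gt$tissue_area_true_mm2,
                 viability_true = gt$viability_true)
  )
  mp <- file.path(dir, sprintf("%s_meta.json", well_id))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read a well written by [write_well_images()]
#' @param dir Directory containing the files.
#' @param well_id Well file-name stem.
#' @return A `well_image_set` with a `truth` attribute holding the scalar
#'   ground truth from the sidecar.
#' @export
read_well_images <- function(dir, well_id) {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", well_id)),
                              simplifyVector = TRUE)
  nz <- meta$n_zplanes
  channels <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", well_id, ch)),
                            all = TRUE)
    n_tiles <- length(pages) / nz
    tiles <- vector("list", n_tiles)
    for (k in seq_len(n_tiles)) {
      arr <- array(0, dim = c(dim(pages[[1]]), nz))
      for (z in seq_len(nz)) arr[, , z] <- pages[[(k - 1L) * nz + z]]
      tiles[[k]] <- arr
    }
    channels[[ch]] <- tiles
  }
  structure(
    list(channels = channels, grid = meta$grid, tile_px = meta$tile_px,
         overlap = meta$overlap, pixel_size = meta$pixel_size_um,
         mosaic_dim = mosaic_size(meta$tile_px, meta$grid, meta$overlap)),
    class = "well_image_set", truth = meta$truth
  )
}

#' Write the simulated plate truth table as CSV
#' @param sim Output of [simulate_screen()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_plate_csv <- function(sim, path) {
  utils::write.csv(sim$table, path, row.names = FALSE)
  invisible(path)
}
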