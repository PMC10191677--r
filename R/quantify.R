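# Mask-to-readout conversion: inter-post tip distance, percent contraction,
# cantilever force, tissue area, acute response and viability.

#' Minimum edge-to-edge distance between the two post caps
#'
#' Computes the minimum Euclidean distance between pixel centres of the two
#' connected components of `post_mask` via an exact Euclidean distance
#' transform of one component sampled on the other (equivalent to, and tested
#' against, the exhaustive pixel-pair minimum). Coordinates are 0-based,
#' row-major; the reported witness pair is the lexicographically smallest
#' minimiser for reproducible debugging overlays.
#'
#' @param post_mask Binary matrix with exactly two connected components.
#' @param pixel_size Pixel size, um/px.
#' @param witness Also locate the minimising pixel pair?
#' @return List with `px`, `um`, and (when `witness`) `pair`, a 2x2 matrix of
#'   0-based (row, col) coordinates, one row per component.
#' @export
tip_distance <- function(post_mask, pixel_size = 1, witness = FALSE) {
  if (!is_binary_mask(post_mask))
    mp_stop("post_mask must be a binary matrix", "input_error")
  lab <- label_components(post_mask)
  n <- max(lab)
  if (n != 2L)
    mp_stop(sprintf("post mask has %d components; need exactly 2", n),
            "measurement_error", n_components = n,
            qc = if (n == 0L) "no_posts" else "wrong_count")
  a <- lab == 1L
  b <- lab == 2L
  # EDT of the complement of A: value at a pixel = distance to nearest A pixel
  dmap <- matrix(as.numeric(EBImage::imageData(
    EBImage::distmap(EBImage::Image((!a) * 1), metric = "euclidean"))),
    nrow(post_mask))
  d <- min(dmap[b])
  out <- list(px = d, um = d * pixel_size)
  if (witness) {
    qb <- which(b & abs(dmap - d) < 1e-9, arr.ind = TRUE)
    pa <- which(a, arr.ind = TRUE)
    best <- NULL
    for (i in seq_len(nrow(qb))) {
      dd <- (pa[, 1] - qb[i, 1])^2 + (pa[, 2] - qb[i, 2])^2
      hit <- which(abs(sqrt(dd) - d) < 1e-9)
      for (j in hit) {
        cand <- c(pa[j, ] - 1L, qb[i, ] - 1L)  # 0-based
        if (is.null(best) || lex_less(cand, best)) best <- cand
      }
    }
    out$pair <- matrix(best, 2, 2, byrow = TRUE,
                       dimnames = list(c("component_1", "component_2"),
                                       c("row", "col")))
  }
  out
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Percent tissue contraction
#'
#' `100 * (d0 - dt) / d0`: tip deflection expressed as a percentage of the
#' original (unseeded) inter-post spacing D0.
#'
#' @param d0 Baseline (unseeded) tip distance, um; must be > 0.
#' @param dt Tip distance at readout, um.
#' @return Percent contraction (vectorised).
#' @export
contraction_percent <- function(d0, dt) {
  if (any(!is.finite(d0)) || any(d0 <= 0))
    mp_stop("d0 must be finite and > 0", "input_error")
  100 * (d0 - dt) / d0
}

#' Acute (pre/post stimulus) contraction response
#'
#' Additional contraction relative to the pre-stimulus state,
#' `100 * (d_pre - d_post) / d_pre`, as in an acute agonist challenge
#' (e.g. bradykinin, default dose 100 uM in the config) where a well is
#' imaged before and minutes after dosing.
#'
#' @param d_pre Pre-stimulus tip distance, um; > 0.
#' @param d_post Post-stimulus tip distance, um.
#' @return Percent additional contraction.
#' @export
acute_response <- function(d_pre, d_post) contraction_percent(d_pre, d_post)

#' Convert tip displacement to per-post force
#'
#' Under the symmetric-deflection assumption each cantilever bends by half
#' the total change in spacing, `delta = share * (d0 - dt)` with
#' `share = 0.5`, and the per-post force is `k * delta`. Negative deflections
#' (relaxation beyond baseline) are clamped to zero force and flagged.
#'
#' @param d0,dt Tip distances, um.
#' @param k Cantilever spring constant, uN/um (default 0.109, the device
#'   calibration used throughout).
#' @param share Fraction of the total displacement carried by one post.
#' @return Per-post force in uN (vectorised); attribute `relaxed` marks
#'   entries whose raw deflection was negative.
#' @export
deflection_to_force <- function(d0, dt, k = 0.109, share = 0.5) {
  if (any(!is.finite(k)) || any(k <= 0))
    mp_stop("spring constant k must be > 0", "input_error")
  delta <- share * (d0 - dt)
  relaxed <- delta < 0
  if (any(relaxed))
    warning("negative deflection clamped to zero force (relaxation)")
  f <- k * pmax(delta, 0)
  attr(f, "relaxed") <- relaxed
  f
}

#' Tissue area in pixels and square millimetres
#' @param tissue_mask Binary matrix.
#' @param pixel_size Pixel size um/px of the (possibly binned) mask frame.
#' @return List with `px2`, `mm2` and `status` (`"ok"` or `"tissue_absent"`).
#' @export
tissue_area <- function(tissue_mask, pixel_size) {
  if (!is_binary_mask(tissue_mask))
    mp_stop("tissue_mask must be a binary matrix", "input_error")
  px2 <- sum(as_mask(tissue_mask))
  list(px2 = px2, mm2 = px2 * (pixel_size * 1e-3)^2,
       status = if (px2 == 0) "tissue_absent" else "ok")
}

#' Tissue viability from TMRM intensity
#'
#' Mean in-mask TMRM intensity rescaled linearly between a dead reference
#' (staurosporine-killed control) and a live reference, clipped to [0, 1].
#'
#' @param tmrm_image 2D TMRM intensity image.
#' @param tissue_mask Binary tissue mask, same shape.
#' @param live_ref,dead_ref Reference mean intensities; `live_ref` must
#'   exceed `dead_ref`.
#' @param dead_cutoff Scores below this are called dead (default 0.2).
#' @return List with `score` in [0, 1] and `status`
#'   (`"live"`, `"dead"`, or `"no_tissue"` with `NA` score).
#' @export
viability_score <- function(tmrm_image, tissue_mask,
                            live_ref = TMRM_LIVE_REF,
                            dead_ref = TMRM_DEAD_REF,
                            dead_cutoff = 0.2) {
  if (live_ref <= dead_ref)
    mp_stop("live_ref must exceed dead_ref", "reference_error")
  m <- as_mask(tissue_mask)
  if (!any(m)) return(list(score = NA_real_, status = "no_tissue"))
  s <- clip((mean(tmrm_image[m]) - dead_ref) / (live_ref - dead_ref), 0, 1)
  list(score = s, status = if (s < dead_cutoff) "dead" else "live")
}

#' Quantify one well end to end
#'
#' Runs the full chain on a baseline (unseeded, day 0) and a readout image
#' set: shading-correct each tile, stitch, project, segment the posts,
#' measure D0 and Dt, and derive percent contraction and per-post force.
#' When the readout set carries F-actin / TMRM channels, tissue area
#' (fluorescence threshold segmentation on the F-actin channel, 4x4-binned
#' path) and viability are also reported. QC failures are returned as
#' exclusion flags, never as silent drops.
#'
#' @param baseline `well_image_set` for D0, or a single number giving an
#'   already-measured D0 in micrometres (the unseeded plate is imaged once at
#'   day 0, so batch runs reuse that measurement).
#' @param readout `well_image_set` for Dt.
#' @param clf Post/tissue `pixel_classifier` (or `NULL` for the threshold
#'   baseline backend).
#' @param cap_radius_um Expected cap radius, for the segmentation size gate.
#' @param k Spring constant, uN/um.
#' @param bin_area Bin factor for the tissue-area path (default 4).
#' @param shading_method Passed to [preprocess_well()].
#' @return One-row data frame: `d0_um`, `dt_um`, `contraction_pct`,
#'   `force_un`, `area_px2`, `area_mm2`, `viability`, `excluded`,
#'   `exclusion_reason`.
#' @export
quantify_well <- function(baseline, readout, clf, cap_radius_um,
                          k = 0.109, bin_area = 4L,
                          shading_method = "poly") {
  ps <- readout$pixel_size
  cap_area <- pi * (cap_radius_um / ps)^2
  if (is.numeric(baseline)) {
    d0_given <- baseline
    seg0 <- NULL
  } else {
    d0_given <- NULL
    img0 <- preprocess_well(baseline, "brightfield",
                            shading_method = shading_method)
    seg0 <- segment_posts(img0, clf, cap_area)
  }
  imgt <- preprocess_well(readout, "brightfield",
                          shading_method = shading_method)
  segt <- segment_posts(imgt, clf, cap_area)
  flags <- unique(c(if (!is.null(seg0)) paste0("d0_", seg0$qc_flags),
                    paste0("dt_", segt$qc_flags)))
  flags <- flags[!flags %in% c("d0_", "dt_")]
  row <- data.frame(
    d0_um = NA_real_, dt_um = NA_real_, contraction_pct = NA_real_,
    force_un = NA_real_, area_px2 = NA_real_, area_mm2 = NA_real_,
    viability = NA_real_, excluded = FALSE, exclusion_reason = "",
    stringsAsFactors = FALSE
  )
  d0_ok <- !is.null(d0_given) || seg0$n_post_components == 2L
  if (d0_ok && segt$n_post_components == 2L) {
    d0_um <- d0_given %||% tip_distance(seg0$post_mask, ps)$um
    dt <- tip_distance(segt$post_mask, ps)
    row$d0_um <- d0_um
    row$dt_um <- dt$um
    row$contraction_pct <- contraction_percent(d0_um, dt$um)
    row$force_un <- as.numeric(deflection_to_force(d0_um, dt$um, k = k))
  } else {
    row$excluded <- TRUE
    row$exclusion_reason <- "damaged"
  }
  if ("factin" %in% names(readout$channels)) {
    fa <- preprocess_well(readout, "factin", bin = bin_area,
                          shading_method = "none")
    segf <- segment_tissue(fa, clf = NULL)
    ta <- tissue_area(segf$tissue_mask, attr(fa, "pixel_size"))
    row$area_px2 <- ta$px2
    row$area_mm2 <- ta$mm2
    if ("tissue_touches_border" %in% segf$qc_flags) {
      row$excluded <- TRUE
      row$exclusion_reason <- "damaged"
      flags <- c(flags, "tissue_touches_border")
    }
    if ("tmrm" %in% names(readout$channels)) {
      tm <- preprocess_well(readout, "tmrm", shading_method = "none")
      tmb <- bin_image(tm, bin_area)
      v <- viability_score(tmb, segf$tissue_mask)
      row$viability <- v$score
      if (identical(v$status, "dead")) {
        row$excluded <- TRUE
        row$exclusion_reason <- "dead"
      }
    }
  }
  attr(row, "qc_flags") <- flags
  row
}
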