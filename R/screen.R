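# Plate-level analytics: QC exclusion, replicate aggregation, robust MAD hit
# calling, and the fold-change / p-value gene-table filter.

DAMAGE_FLAGS <- c("damaged", "detached", "tissue_touches_border",
                  "no_posts", "wrong_count")

#' Aggregate a screen table and apply QC exclusions
#'
#' Wells whose QC flags indicate damage or detachment, or whose tissue is
#' dead (explicit `dead` column, or `viability_score` below `dead_cutoff`),
#' are excluded with a recorded reason. Technical replicates are averaged
#' (arithmetic mean) into one value per biological replicate, and
#' per-condition summaries (median, raw MAD, n) are computed over biological
#' replicates. Conditions left with no surviving replicate are reported as
#' fully excluded, never silently dropped.
#'
#' @param table Data frame with columns `well_id`, `condition`,
#'   `contraction_pct`, and optionally `replicate` (biological replicate id;
#'   wells sharing one id are technical replicates), `qc_flags`
#'   (";"-separated), `viability_score`, `dead`, `damaged`.
#' @param dead_cutoff Viability score below which a well is dead.
#' @return List with `wells` (input plus `excluded`, `exclusion_reason`),
#'   `biological` (one row per condition x replicate), `conditions` (columns
#'   `condition`, `median`, `mad`, `n`) and `fully_excluded` (character).
#' @export
aggregate_and_exclude <- function(table, dead_cutoff = 0.2) {
  req <- c("well_id", "condition", "contraction_pct")
  if (!all(req %in% names(table)))
    mp_stop(paste("screen table needs columns:", paste(req, collapse = ", ")),
            "input_error")
  tab <- as.data.frame(table)
  if (is.null(tab$replicate)) tab$replicate <- 1L
  flags <- strsplit(as.character(tab$qc_flags %||% rep("", nrow(tab))), ";",
                    fixed = TRUE)
  damaged <- vapply(flags, function(f)
    any(sub("^d[0t]_", "", f) %in% DAMAGE_FLAGS), logical(1))
  if (!is.null(tab$damaged)) damaged <- damaged | tab$damaged
  dead <- rep(FALSE, nrow(tab))
  if (!is.null(tab$viability_score))
    dead <- dead | (!is.na(tab$viability_score) &
                      tab$viability_score < dead_cutoff)
  if (!is.null(tab$dead)) dead <- dead | tab$dead
  bad_value <- !is.finite(tab$contraction_pct)
  tab$excluded <- damaged | dead | bad_value
  tab$exclusion_reason <- ifelse(dead, "dead",
                          ifelse(damaged, "damaged",
                          ifelse(bad_value, "unmeasured", "")))
  keep <- tab[!tab$excluded, , drop = FALSE]
  bio <- stats::aggregate(contraction_pct ~ condition + replicate,
                          data = keep, FUN = mean)
  med <- stats::aggregate(contraction_pct ~ condition, data = bio,
                          FUN = stats::median)
  madv <- stats::aggregate(contraction_pct ~ condition, data = bio,
                           FUN = mad_raw)
  nn <- stats::aggregate(contraction_pct ~ condition, data = bio, FUN = length)
  cond <- data.frame(condition = med$condition, median = med$contraction_pct,
                     mad = madv$contraction_pct, n = nn$contraction_pct,
                     stringsAsFactors = FALSE)
  list(wells = tab, biological = bio, conditions = cond,
       fully_excluded = setdiff(unique(tab$condition), cond$condition))
}

#' Raw (unscaled) median absolute deviation
#'
#' `median(|x - median(x)|)` with no normal-consistency factor; this is the
#' dispersion entering the screening threshold.
#' @param x Numeric vector.
#' @return The raw MAD.
#' @export
mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

#' Call screening hits by the robust MAD rule
#'
#' The hit threshold is `control_median - k_mad * MAD`, with the MAD the raw
#' median absolute deviation of the treated-control biological-replicate
#' values. A condition is a hit iff its summary contraction (median over
#' biological replicates) falls strictly below the threshold — a one-sided
#' rule, since the screen looks for suppressed hypercontractility.
#'
#' @param aggregated Output of [aggregate_and_exclude()], or a raw screen
#'   table (which is aggregated first).
#' @param control_label Treated-control condition label.
#' @param k_mad Threshold multiplier (default 3).
#' @return A `hit_report`: `control_median`, `control_mad`, `threshold`,
#'   `hits` (condition labels, most contracted-suppressed first),
#'   `per_condition_stats`.
#' @export
call_hits <- function(aggregated, control_label, k_mad = 3) {
  if (is.data.frame(aggregated))
    aggregated <- aggregate_and_exclude(aggregated)
  if (control_label %in% aggregated$fully_excluded)
    mp_stop(sprintf("control '%s' fully excluded; cannot set a threshold",
                    control_label), "control_error")
  bio <- aggregated$biological
  ctrl <- bio$contraction_pct[bio$condition == control_label]
  if (length(ctrl) < 2L)
    mp_stop(sprintf(
      "control '%s' has %d surviving value(s); need >= 2", control_label,
      length(ctrl)), "control_error")
  ctrl_med <- stats::median(ctrl)
  ctrl_mad <- mad_raw(ctrl)
  threshold <- ctrl_med - k_mad * ctrl_mad
  stats <- aggregated$conditions
  is_hit <- stats$median < threshold & stats$condition != control_label
  hits <- stats$condition[is_hit][order(stats$median[is_hit])]
  structure(
    list(control_median = ctrl_med, control_mad = ctrl_mad,
         threshold = threshold, k_mad = k_mad, hits = hits,
         per_condition_stats = stats,
         fully_excluded = aggregated$fully_excluded),
    class = "hit_report"
  )
}

#' @export
print.hit_report <- function(x, ...) {
  cat(sprintf(
    paste0("hit_report: control median %.2f%%, MAD %.2f, threshold %.2f%% ",
           "(median - %g x MAD)\n%d hit(s): %s\n"),
    x$control_median, x$control_mad, x$threshold, x$k_mad,
    length(x$hits), paste(x$hits, collapse = ", ")))
  if (length(x$fully_excluded))
    cat("fully excluded conditions:",
        paste(x$fully_excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write a hit report as CSV + JSON
#' @param report A `hit_report`.
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return Invisibly, the paths written.
#' @export
write_hit_report <- function(report, stem) {
  stats <- report$per_condition_stats
  stats$hit <- stats$condition %in% report$hits
  csv <- paste0(stem, ".csv")
  utils::write.csv(stats, csv, row.names = FALSE)
  js <- paste0(stem, ".json")
  jsonlite::write_json(
    list(control_median = report$control_median,
         control_mad = report$control_mad, threshold = report$threshold,
         k_mad = report$k_mad, hits = report$hits,
         fully_excluded = report$fully_excluded),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Filter a differential-expression table by p-value and fold change
#'
#' Retains rows with `p < p_thresh` and `|log2fc| > log2(fc_thresh)` (both
#' strict; a fold-change cutoff of 1.5 corresponds to |log2 fold change|
#' above 0.585). Rows with non-finite `log2fc` or `p_value` outside [0, 1]
#' are rejected per row and counted on the `n_rejected` attribute.
#'
#' @param gene_table Data frame with columns `gene_id`, `log2fc`, `p_value`.
#' @param p_thresh P-value cutoff (strict).
#' @param fc_thresh Fold-change cutoff on the linear scale (strict on
#'   `|log2fc|`).
#' @return The retained rows; attribute `n_rejected` counts malformed rows.
#' @export
filter_deg_table <- function(gene_table, p_thresh = 0.05, fc_thresh = 1.5) {
  req <- c("gene_id", "log2fc", "p_value")
  if (!all(req %in% names(gene_table)))
    mp_stop(paste("gene table needs columns:", paste(req, collapse = ", ")),
            "input_error")
  ok <- is.finite(gene_table$log2fc) & is.finite(gene_table$p_value) &
    gene_table$p_value >= 0 & gene_table$p_value <= 1
  n_rejected <- sum(!ok)
  if (n_rejected)
    message(n_rejected, " malformed row(s) rejected")
  tab <- gene_table[ok, , drop = FALSE]
  out <- tab[tab$p_value < p_thresh &
               abs(tab$log2fc) > log2(fc_thresh), , drop = FALSE]
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Plate heatmap of contraction and exclusions
#'
#' Optional 8x12 overview figure: fill encodes percent contraction, excluded
#' wells are outlined by exclusion reason. Requires ggplot2.
#'
#' @param wells The `wells` component of [aggregate_and_exclude()].
#' @return A ggplot object.
#' @export
plot_plate <- function(wells) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    mp_stop("plot_plate needs ggplot2", "input_error")
  df <- wells
  df$row <- factor(substr(df$well_id, 1, 1), levels = rev(LETTERS[1:8]))
  df$col <- as.integer(sub("^[A-H]", "", df$well_id))
  df$reason <- ifelse(df$excluded, df$exclusion_reason, "included")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$contraction_pct),
                       colour = "grey30") +
    ggplot2::geom_point(data = df[df$excluded, , drop = FALSE],
                        ggplot2::aes(shape = .data$reason), size = 3) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% contraction",
                  shape = "excluded") +
    ggplot2::theme_minimal()
}
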