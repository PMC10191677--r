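# Plate analytics: exclusion, aggregation, MAD hit calling, DEG filter.

screen_table <- function(cond, values, replicate = seq_along(values), ...) {
  data.frame(well_id = paste0("A", seq_along(values)), condition = cond,
             replicate = replicate, contraction_pct = values, ...,
             stringsAsFactors = FALSE)
}

test_that("technical replicates average into biological values", {
  tab <- screen_table("drugA", c(60, 62, 64, 66), replicate = c(1, 1, 1, 1))
  agg <- aggregate_and_exclude(tab)
  expect_equal(agg$biological$contraction_pct, 63)
  expect_equal(agg$conditions$median, 63)
  expect_equal(agg$conditions$n, 1)
})

test_that("damaged and dead wells are excluded with reasons, never dropped", {
  tab <- rbind(
    screen_table("ctrl", c(65, 66, 67)),
    screen_table("gone", c(50, 51)))
  tab$qc_flags <- c("", "tissue_touches_border", "", "damaged", "damaged")
  tab$viability_score <- c(0.9, 0.9, 0.05, 0.9, 0.9)
  agg <- aggregate_and_exclude(tab)
  expect_equal(agg$wells$exclusion_reason,
               c("", "damaged", "dead", "damaged", "damaged"))
  expect_identical(agg$fully_excluded, "gone")
  # prefixed per-timepoint flags also count as damage
  tab2 <- screen_table("x", c(60, 61))
  tab2$qc_flags <- c("dt_wrong_count", "")
  expect_true(aggregate_and_exclude(tab2)$wells$excluded[1])
})

test_that("hit threshold follows the hand-computed median and MAD", {
  ctrl <- screen_table("control", c(60, 62, 64, 66, 68))
  tab <- rbind(ctrl,
               screen_table("strong", c(50, 50)),
               screen_table("weak", c(59, 59)))
  rep_ids <- ave(seq_len(nrow(tab)), tab$condition, FUN = seq_along)
  tab$replicate <- rep_ids
  rep <- call_hits(tab, "control", k_mad = 3)
  expect_equal(rep$control_median, 64)
  expect_equal(rep$control_mad, 2)        # raw MAD, no 1.4826 scaling
  expect_equal(rep$threshold, 58)
  expect_identical(rep$hits, "strong")    # 50 < 58; 59 is not a hit
})

test_that("zero control dispersion yields no hits at the median (strict)", {
  tab <- rbind(screen_table("control", c(67, 67, 67)),
               screen_table("at_median", c(67, 67)))
  tab$replicate <- ave(seq_len(nrow(tab)), tab$condition, FUN = seq_along)
  rep <- call_hits(tab, "control")
  expect_equal(rep$control_mad, 0)
  expect_equal(rep$threshold, rep$control_median)
  expect_length(rep$hits, 0)
})

test_that("hit calling is invariant to row order and to excluded rows", {
  set.seed(33)
  tab <- rbind(screen_table("control", rnorm(8, 67, 2)),
               screen_table("inh1", rnorm(4, 40, 2)),
               screen_table("inh2", rnorm(4, 66, 2)))
  tab$replicate <- ave(seq_len(nrow(tab)), tab$condition, FUN = seq_along)
  tab$qc_flags <- ""
  base <- call_hits(tab, "control")
  perm <- tab[sample(nrow(tab)), ]
  expect_identical(call_hits(perm, "control")$hits, base$hits)
  extra <- tab[1, ]
  extra$condition <- "inh1"
  extra$contraction_pct <- 5
  extra$qc_flags <- "damaged"
  expect_identical(call_hits(rbind(tab, extra), "control")$hits, base$hits)
  expect_equal(call_hits(rbind(tab, extra), "control")$threshold,
               base$threshold)
})

test_that("raising k_mad never adds hits", {
  set.seed(34)
  tab <- rbind(screen_table("control", rnorm(10, 67, 2)),
               screen_table("a", rnorm(3, 55, 2)),
               screen_table("b", rnorm(3, 45, 2)),
               screen_table("c", rnorm(3, 66, 2)))
  tab$replicate <- ave(seq_len(nrow(tab)), tab$condition, FUN = seq_along)
  hits_by_k <- lapply(c(1, 2, 3, 5), function(k)
    call_hits(tab, "control", k_mad = k)$hits)
  for (i in seq_len(length(hits_by_k) - 1))
    expect_true(all(hits_by_k[[i + 1]] %in% hits_by_k[[i]]))
})

test_that("a fully excluded control is a hard error downstream", {
  tab <- rbind(screen_table("control", c(67, 67)),
               screen_table("drug", c(40, 41)))
  tab$replicate <- ave(seq_len(nrow(tab)), tab$condition, FUN = seq_along)
  tab$viability_score <- c(0.05, 0.02, 0.9, 0.9)
  agg <- aggregate_and_exclude(tab)
  expect_identical(agg$fully_excluded, "control")
  expect_error(call_hits(agg, "control"), class = "control_error")
  # a single surviving control value is also insufficient
  tab$viability_score <- c(0.9, 0.02, 0.9, 0.9)
  expect_error(call_hits(tab, "control"), class = "control_error")
})

test_that("DEG filter applies strict p and fold-change cutoffs", {
  tab <- data.frame(
    gene_id = c("up", "under", "down", "edge_p", "weak_p"),
    log2fc = c(0.60, 0.58, -0.9, 1.0, 2.0),
    p_value = c(0.01, 0.01, 0.001, 0.05, 0.2))
  out <- filter_deg_table(tab)
  expect_identical(out$gene_id, c("up", "down"))
  # the linear cutoff 1.5 equals |log2fc| > log2(1.5); independently derived
  expect_identical(filter_deg_table(
    data.frame(gene_id = "g", log2fc = log2(1.5), p_value = 0.01))$gene_id,
    character(0))
  expect_identical(filter_deg_table(
    data.frame(gene_id = "g", log2fc = log2(1.5) + 1e-9,
               p_value = 0.01))$gene_id, "g")
})

test_that("DEG filter rejects malformed rows and is idempotent", {
  tab <- data.frame(gene_id = letters[1:5],
                    log2fc = c(1, NA, Inf, -2, 0.7),
                    p_value = c(0.01, 0.01, 0.01, 1.5, 0.002))
  expect_message(out <- filter_deg_table(tab), "3 malformed")
  expect_identical(attr(out, "n_rejected"), 3L)
  expect_identical(out$gene_id, c("a", "e"))
  again <- suppressMessages(filter_deg_table(out))
  expect_identical(again$gene_id, out$gene_id)
  expect_true(all(out$gene_id %in% tab$gene_id))
})
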