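# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Error with a machine-readable class, carrying optional context fields.
#' @noRd
mp_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "micropost_error")))
}

is_binary_mask <- function(x) {
  is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1)))
}

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  matrix(x != 0, nrow = nrow(x))
}

#' Connected-component labelling (8-connectivity) of a binary mask.
#' Thin wrapper so all modules share one labelling convention.
#' @noRd
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(as_mask(mask) * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
}

component_areas <- function(lab) {
  if (max(lab) == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = max(lab))
}

component_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  idx <- which(lab > 0L, arr.ind = TRUE)
  lb <- lab[lab > 0L]
  cbind(
    row = tapply(idx[, 1], lb, mean),
    col = tapply(idx[, 2], lb, mean)
  )
}
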