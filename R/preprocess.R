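# Image conditioning: retrospective flat-field shading correction, tile
# stitching with integer-shift refinement, maximum-intensity projection, and
# mean binning. The chain order (correct each tile, stitch, project, bin)
# follows standard high-content practice.

#' Retrospective single-image flat-field (shading) correction
#'
#' Estimates a smooth multiplicative illumination gain from the image itself
#' and divides it out. The default estimator fits a low-order (quadratic)
#' polynomial surface with one robust reweighting pass that discards
#' foreground outliers, which is exact for the parabolic vignetting typical
#' of microscope optics and unbiased at the image borders. Heavy Gaussian
#' smoothing (`sigma = min(dim)/8`, edge-corrected by normalised convolution)
#' is available as an alternative for gain fields that are smooth but not
#' polynomial. The estimated gain is normalised to mean 1, so the corrected
#' image keeps the original global mean to within a percent.
#'
#' @param image Numeric matrix of finite intensities.
#' @param method `"poly"` (default) or `"gaussian"`.
#' @param sigma Smoothing scale in px; default `min(dim(image)) / 8`.
#' @param poly_degree Degree of the polynomial surface (default 2).
#' @return List with `corrected` (matrix) and `model`, a `flat_field_model`
#'   holding `gain_surface` (mean 1), `offset_surface` (zero here) and a
#'   `degenerate` flag set when the image is constant (identity model).
#' @export
correct_shading <- function(image,
                            method = c("poly", "gaussian"),
                            sigma = NULL, poly_degree = 2L) {
  method <- match.arg(method)
  if (!is.matrix(image) || length(image) == 0L || !all(is.finite(image)))
    mp_stop("image must be a non-empty finite numeric matrix", "input_error")
  if (stats::sd(image) < 1e-12 * max(abs(image), 1)) {
    model <- flat_field_model(matrix(1, nrow(image), ncol(image)),
                              degenerate = TRUE)
    warning("constant image: returning identity flat-field model")
    return(list(corrected = image, model = model))
  }
  sigma <- sigma %||% (min(dim(image)) / 8)
  est <- switch(method,
    gaussian = gauss_smooth(image, sigma),
    poly = fit_poly_surface(image, poly_degree, robust = TRUE)
  )
  est <- pmax(est, 1e-6 * mean(est))
  gain <- est / mean(est)
  list(corrected = image / gain, model = flat_field_model(gain))
}

flat_field_model <- function(gain, offset = NULL, degenerate = FALSE) {
  structure(list(gain_surface = gain,
                 offset_surface = offset %||% matrix(0, nrow(gain), ncol(gain)),
                 degenerate = degenerate),
            class = "flat_field_model")
}

# Gaussian smoothing with normalised convolution so image borders are not
# biased toward zero padding. FFT-based via EBImage::filter2.
gauss_smooth <- function(image, sigma) {
  size <- min(2L * ceiling(3 * sigma) + 1L,
              (min(dim(image)) - 2L) %/% 2L * 2L + 1L)
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  num <- EBImage::filter2(EBImage::Image(image), k, boundary = 0)
  den <- EBImage::filter2(EBImage::Image(matrix(1, nrow(image), ncol(image))),
                          k, boundary = 0)
  matrix(as.numeric(EBImage::imageData(num) / EBImage::imageData(den)),
         nrow(image))
}

# Least-squares polynomial surface z ~ poly(row, col, degree), sampled on a
# grid when the image is large. With robust = TRUE one reweighting pass
# discards pixels far off the first fit (dark caps / bright debris), so the
# surface tracks the illumination rather than the foreground.
fit_poly_surface <- function(image, degree = 2L, robust = FALSE) {
  h <- nrow(image); w <- ncol(image)
  ry <- seq_len(h) / h - 0.5
  rx <- seq_len(w) / w - 0.5
  sub_y <- if (h > 200) round(seq(1, h, length.out = 200)) else seq_len(h)
  sub_x <- if (w > 200) round(seq(1, w, length.out = 200)) else seq_len(w)
  df <- data.frame(z = as.vector(image[sub_y, sub_x]),
                   y = rep(ry[sub_y], times = length(sub_x)),
                   x = rep(rx[sub_x], each = length(sub_y)))
  fml <- z ~ stats::poly(y, x, degree = degree, raw = TRUE)
  fit <- stats::lm(fml, data = df)
  if (robust) {
    r <- stats::residuals(fit)
    s <- stats::mad(r)
    keep <- abs(r) <= 2.5 * max(s, 1e-12)
    if (sum(keep) > 10 * (degree + 1)^2 && mean(keep) > 0.5)
      fit <- stats::lm(fml, data = df[keep, , drop = FALSE])
  }
  full <- data.frame(y = rep(ry, times = w), x = rep(rx, each = h))
  matrix(stats::predict(fit, newdata = full), h, w)
}

#' Stitch tiled fields of view into one mosaic
#'
#' Tiles are placed at their nominal offsets
#' (`step = tile - round(overlap * tile)`), then each tile's offset is
#' refined by exhaustive integer-shift cross-correlation against its
#' already-placed left/top neighbour within `max_shift` px; when the overlap
#' carries too little structure for a trustworthy peak the nominal offset is
#' kept. Overlaps are blended by a feathered (linear-ramp) weighted average.
#'
#' @param tiles List of equally sized numeric matrices, row-major tile order.
#' @param grid Integer vector `c(rows, cols)`.
#' @param overlap Per-seam overlap fraction of the tile size.
#' @param refine Refine offsets by cross-correlation?
#' @param max_shift Maximum refinement shift, px.
#' @return Numeric matrix of the nominal mosaic size; attribute `offsets`
#'   holds the placed (row, col) origin of each tile (0-based).
#' @export
stitch_fields <- function(tiles, grid, overlap, refine = TRUE,
                          max_shift = 5L) {
  grid <- as.integer(grid)
  if (length(tiles) != prod(grid))
    mp_stop(sprintf("expected %d tiles for a %dx%d grid, got %d",
                    prod(grid), grid[1], grid[2], length(tiles)),
            "input_error")
  dims <- vapply(tiles, dim, integer(2))
  if (any(dims != dims[, 1]))
    mp_stop("all tiles must share one shape", "input_error")
  t_px <- dims[, 1]
  step <- t_px - as.integer(round(overlap * t_px))
  ov <- t_px - step
  m <- (grid - 1L) * step + t_px
  pad <- if (refine) as.integer(max_shift) else 0L  # room for edge shifts
  acc <- matrix(0, m[1] + 2L * pad, m[2] + 2L * pad)
  wt <- matrix(0, m[1] + 2L * pad, m[2] + 2L * pad)
  feather <- outer(feather_ramp(t_px[1], ov[1]), feather_ramp(t_px[2], ov[2]))
  offsets <- matrix(0L, prod(grid), 2)

  k <- 0L
  for (r in seq_len(grid[1])) {
    for (cc in seq_len(grid[2])) {
      k <- k + 1L
      tile <- tiles[[k]]
      nominal <- c((r - 1L) * step[1], (cc - 1L) * step[2])
      off <- nominal
      if (refine && (r > 1L || cc > 1L) && all(ov > 0)) {
        sh <- refine_shift(acc, wt, tile, nominal + pad, max_shift)
        off <- nominal + sh
      }
      ys <- pad + off[1] + seq_len(t_px[1])
      xs <- pad + off[2] + seq_len(t_px[2])
      acc[ys, xs] <- acc[ys, xs] + tile * feather
      wt[ys, xs] <- wt[ys, xs] + feather
      offsets[k, ] <- off
    }
  }
  out <- acc
  nz <- wt > 0
  out[nz] <- acc[nz] / wt[nz]
  out <- out[pad + seq_len(m[1]), pad + seq_len(m[2])]
  attr(out, "offsets") <- offsets
  out
}

# Linear feather: weight ramps from 1/(ov+1) at the tile edge to 1 past the
# overlap band; constant 1 when there is no overlap.
feather_ramp <- function(t_px, ov) {
  if (ov <= 0) return(rep(1, t_px))
  i <- seq_len(t_px)
  pmin(1, pmin(i, t_px - i + 1) / (ov + 1))
}

# Exhaustive integer-shift normalised cross-correlation of a tile against the
# mosaic assembled so far. Returns c(dy, dx); c(0, 0) when the peak is
# ambiguous. A non-zero shift is accepted only when it beats the nominal
# placement by a clear correlation margin: content that is uniform along one
# axis (e.g. a band crossing a seam) correlates equally well at many shifts
# along that axis, and must not drag the tile.
refine_shift <- function(acc, wt, tile, nominal, max_shift, margin = 0.05) {
  t_px <- dim(tile)
  m <- dim(acc)
  shifts <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  best <- c(0L, 0L); best_cor <- -Inf; cor0 <- NA_real_
  ref <- acc
  nz <- wt > 0
  ref[nz] <- acc[nz] / wt[nz]
  for (i in seq_len(nrow(shifts))) {
    off <- nominal + c(shifts$dy[i], shifts$dx[i])
    if (off[1] < 0 || off[2] < 0 ||
        off[1] + t_px[1] > m[1] || off[2] + t_px[2] > m[2]) next
    ys <- off[1] + seq_len(t_px[1]); xs <- off[2] + seq_len(t_px[2])
    cov <- nz[ys, xs]
    if (sum(cov) < 100) next
    a <- ref[ys, xs][cov]; b <- tile[cov]
    if (stats::sd(a) < 1e-9 || stats::sd(b) < 1e-9) next
    cr <- stats::cor(a, b)
    if (shifts$dy[i] == 0L && shifts$dx[i] == 0L) cor0 <- cr
    if (cr > best_cor) { best_cor <- cr; best <- c(shifts$dy[i], shifts$dx[i]) }
  }
  if (!is.finite(best_cor) || best_cor < 0.5) return(c(0L, 0L))
  if (is.na(cor0) || best_cor < cor0 + margin) return(c(0L, 0L))
  as.integer(best)
}

#' Maximum-intensity projection of a z-stack
#' @param zstack 3D array `(rows, cols, planes)` with at least one plane.
#' @return Matrix of per-pixel maxima over planes.
#' @export
max_project <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  if (!is.array(zstack) || length(dim(zstack)) != 3L || dim(zstack)[3] < 1L)
    mp_stop("zstack must be a (rows, cols, planes) array with >= 1 plane",
            "input_error")
  Reduce(pmax, lapply(seq_len(dim(zstack)[3]), function(z) zstack[, , z]))
}

#' Mean-pool (bin) an image by an integer factor
#'
#' Each output pixel is the arithmetic mean of its `factor x factor` block,
#' so intensity scale (and hence thresholds) are preserved across binned and
#' unbinned paths, and the global mean is conserved exactly. Trailing rows or
#' columns that do not fill a block are cropped first.
#'
#' @param image Numeric matrix.
#' @param factor Positive integer bin factor.
#' @return Matrix of dimension `floor(dim(image) / factor)`.
#' @export
bin_image <- function(image, factor) {
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    mp_stop("factor must be a positive integer", "input_error")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  h <- (nrow(image) %/% factor) * factor
  w <- (ncol(image) %/% factor) * factor
  if (h < factor || w < factor)
    mp_stop("image smaller than one bin", "input_error")
  x <- image[seq_len(h), seq_len(w)]
  # pool rows, then columns
  x <- matrix(colSums(matrix(x, nrow = factor)), nrow = h %/% factor)
  x <- t(matrix(colSums(matrix(t(x), nrow = factor)), nrow = w %/% factor))
  x / factor^2
}

#' Condition one channel of a tiled, z-stacked well
#'
#' Applies the standard chain to a [generate_scene()] `well_image_set`:
#' per-tile, per-plane shading correction, per-plane stitching, maximum
#' intensity projection over planes, and optional binning. The returned
#' image carries a `pixel_size` attribute rescaled by the bin factor.
#'
#' @param well A `well_image_set`.
#' @param channel Channel name.
#' @param bin 4 for the tissue-area path, 1 (default) for metrology.
#' @param shading_method Passed to [correct_shading()]; `"none"` skips it.
#' @param refine Passed to [stitch_fields()].
#' @return 2D image with attribute `pixel_size` (um/px).
#' @export
preprocess_well <- function(well, channel, bin = 1L,
                            shading_method = "poly",
                            refine = TRUE) {
  stopifnot(inherits(well, "well_image_set"))
  tiles <- well$channels[[channel]]
  if (is.null(tiles))
    mp_stop(sprintf("channel '%s' not present", channel), "input_error")
  nz <- dim(tiles[[1]])[3]
  planes <- lapply(seq_len(nz), function(z) {
    tz <- lapply(tiles, function(a) {
      img <- a[, , z]
      if (!identical(shading_method, "none"))
        img <- correct_shading(img, method = shading_method)$corrected
      img
    })
    stitch_fields(tz, well$grid, well$overlap, refine = refine)
  })
  proj <- Reduce(pmax, planes)
  ps <- well$pixel_size
  if (bin > 1L) {
    proj <- bin_image(proj, bin)
    ps <- ps * bin
  }
  attr(proj, "pixel_size") <- ps
  proj
}
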