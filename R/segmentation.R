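# Pixel classification and rule-based segmentation QC.
#
# The segmentation contract is backend-agnostic: any predictor returning
# per-pixel class probabilities over {background, post, tissue} can drive the
# downstream cleanup. The canonical desk-scale backend is a random-forest
# pixel classifier over a multiscale feature bank (Gaussian, gradient
# magnitude, Laplacian-of-Gaussian, difference-of-Gaussians). A deep
# encoder-decoder backend can fill the same slot; its published training
# hyperparameters are kept as configuration defaults in
# `unet_backend_defaults()` but no GPU training is performed here.

SEG_CLASSES <- c("background", "post", "tissue")

#' Default multiscale feature recipe
#' @return Data frame of (operator, sigma) pairs.
#' @export
default_feature_recipe <- function() {
  data.frame(
    op = c("gaussian", "gaussian", "gaussian",
           "gradmag", "gradmag", "log", "log", "dog"),
    sigma = c(1, 2, 4, 1, 2, 2, 4, 1),
    sigma2 = c(NA, NA, NA, NA, NA, NA, NA, 4),
    stringsAsFactors = FALSE
  )
}

#' Published training defaults for the optional deep-learning backend
#'
#' Recorded for configuration fidelity only; the desk-scale pipeline uses the
#' random-forest backend.
#' @return Named list of hyperparameters.
#' @export
unet_backend_defaults <- function() {
  list(architecture = "residual U-Net", residual_units = 2L, layers = 5L,
       loss = "Dice", crop_px = c(192L, 192L), samples_per_image = 40L,
       batch_size = 32L, epochs = 500L, optimizer = "Adam", lr = 1e-3,
       validation_fraction = 0.2)
}

#' Compute the pixel feature bank for an image
#' @param image Numeric matrix.
#' @param recipe A recipe as from [default_feature_recipe()].
#' @return Numeric matrix, `length(image)` rows (column-major pixel order),
#'   one column per feature plus the raw intensity.
#' @export
pixel_features <- function(image, recipe = default_feature_recipe()) {
  h <- nrow(image)
  feats <- list(raw = as.vector(image))
  smooth_cache <- new.env(parent = emptyenv())
  smoothed <- function(s) {
    key <- sprintf("s%g", s)
    if (is.null(smooth_cache[[key]]))
      smooth_cache[[key]] <- gauss_smooth(image, s)
    smooth_cache[[key]]
  }
  for (i in seq_len(nrow(recipe))) {
    op <- recipe$op[i]; s <- recipe$sigma[i]
    g <- smoothed(s)
    val <- switch(op,
      gaussian = g,
      gradmag = {
        gy <- (rbind(g[-1, , drop = FALSE], g[h, ]) -
               rbind(g[1, ], g[-h, , drop = FALSE])) / 2
        gx <- (cbind(g[, -1, drop = FALSE], g[, ncol(g)]) -
               cbind(g[, 1], g[, -ncol(g), drop = FALSE])) / 2
        sqrt(gy^2 + gx^2)
      },
      log = laplacian(g),
      dog = g - smoothed(recipe$sigma2[i]),
      mp_stop(sprintf("unknown feature operator '%s'", op), "config_error")
    )
    feats[[sprintf("%s_s%g", op, s)]] <- as.vector(val)
  }
  do.call(cbind, feats)
}

laplacian <- function(g) {
  h <- nrow(g); w <- ncol(g)
  up <- rbind(g[1, ], g[-h, , drop = FALSE])
  dn <- rbind(g[-1, , drop = FALSE], g[h, ])
  lf <- cbind(g[, 1], g[, -w, drop = FALSE])
  rt <- cbind(g[, -1, drop = FALSE], g[, w])
  up + dn + lf + rt - 4 * g
}

#' Train the random-forest pixel classifier
#'
#' Labels follow the convention 0 = background, 1 = post, 2 = tissue; all
#' three classes must be present across the label images. A fixed number of
#' labelled pixels per class per image is sampled, featurised, and split into
#' training and held-out sets; held-out pixel accuracy is stored on the
#' returned object.
#'
#' @param images List of 2D images.
#' @param labels List of integer label images aligned with `images`.
#' @param recipe Feature recipe; see [default_feature_recipe()].
#' @param seed Integer seed; fixes sampling and forest growth, so identical
#'   inputs give identical predictions.
#' @param n_per_class Pixels sampled per class per image.
#' @param num_trees Forest size.
#' @param holdout_frac Fraction of sampled pixels held out for accuracy.
#' @return A `pixel_classifier`.
#' @export
train_pixel_classifier <- function(images, labels,
                                   recipe = default_feature_recipe(),
                                   seed = 1L, n_per_class = 1500L,
                                   num_trees = 100L, holdout_frac = 0.2) {
  if (length(images) != length(labels) || length(images) == 0L)
    mp_stop("images and labels must be non-empty aligned lists",
            "training_error")
  present <- sort(unique(unlist(lapply(labels, unique))))
  if (!all(0:2 %in% present))
    mp_stop(sprintf(
      "all classes 0/1/2 must appear in the labels; saw {%s}",
      paste(present, collapse = ",")), "training_error")

  with_seed(seed, {
    xs <- list(); ys <- list()
    for (i in seq_along(images)) {
      f <- pixel_features(images[[i]], recipe)
      lab <- as.vector(labels[[i]])
      for (cl in 0:2) {
        idx <- which(lab == cl)
        if (!length(idx)) next
        idx <- idx[sample.int(length(idx), min(n_per_class, length(idx)))]
        xs[[length(xs) + 1L]] <- f[idx, , drop = FALSE]
        ys[[length(ys) + 1L]] <- rep(cl, length(idx))
      }
    }
    x <- do.call(rbind, xs)
    y <- factor(SEG_CLASSES[unlist(ys) + 1L], levels = SEG_CLASSES)
    n <- length(y)
    hold <- sample.int(n, max(1L, round(holdout_frac * n)))
    df <- data.frame(x)
    df$.class <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = df[-hold, ],
      num.trees = num_trees, probability = TRUE,
      seed = seed, num.threads = 1L
    )
    pred <- predict(fit, data = df[hold, ], num.threads = 1L)$predictions
    acc <- mean(SEG_CLASSES[max.col(pred, ties.method = "first")] ==
                  as.character(y[hold]))
    structure(
      list(model = fit, recipe = recipe, classes = SEG_CLASSES,
           feature_names = colnames(x), train_seed = seed,
           holdout_accuracy = acc),
      class = "pixel_classifier"
    )
  })
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "pixel_classifier: %d features, %d trees, held-out accuracy %.3f\n",
    length(x$feature_names), x$model$num.trees, x$holdout_accuracy))
  invisible(x)
}

#' Per-pixel class probabilities
#' @param clf A `pixel_classifier`.
#' @param image Numeric matrix.
#' @return Matrix `length(image) x 3` of probabilities (columns background,
#'   post, tissue), rows in column-major pixel order; rows sum to 1.
#' @export
predict_pixel_probs <- function(clf, image) {
  stopifnot(inherits(clf, "pixel_classifier"))
  f <- pixel_features(image, clf$recipe)
  df <- data.frame(f)
  p <- predict(clf$model, data = df, num.threads = 1L,
               seed = clf$train_seed)$predictions
  p[, SEG_CLASSES, drop = FALSE]
}

# argmax class map; ties resolved toward the first (background-most) class.
class_map <- function(probs, dims) {
  matrix(max.col(probs, ties.method = "first") - 1L, dims[1], dims[2])
}

#' Save / load a trained pixel classifier
#'
#' The classifier is serialised as a single portable file containing the
#' recipe, the forest and the training seed.
#' @param clf A `pixel_classifier`.
#' @param path File path.
#' @return `save_pixel_classifier` invisibly returns `path`;
#'   `load_pixel_classifier` returns the classifier.
#' @export
save_pixel_classifier <- function(clf, path) {
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  clf <- readRDS(path)
  stopifnot(inherits(clf, "pixel_classifier"))
  clf
}

seg_result <- function(post_mask, tissue_mask, qc_flags, dims) {
  structure(
    list(post_mask = post_mask %||% matrix(FALSE, dims[1], dims[2]),
         tissue_mask = tissue_mask %||% matrix(FALSE, dims[1], dims[2]),
         n_post_components = if (is.null(post_mask)) 0L else
           max(label_components(post_mask)),
         qc_flags = unique(qc_flags)),
    class = "segmentation_result"
  )
}

#' Segment the two post caps
#'
#' Predicts the `post` class (random-forest backend by default; with
#' `clf = NULL` a simple dark-object threshold at the intensity midpoint is
#' used as baseline), fills holes, removes components whose area falls
#' outside `[min_area_frac, max_area_frac] x expected_cap_area`, and keeps
#' the two largest survivors. Failures are reported through `qc_flags`
#' (`no_posts`, `wrong_count`, `undersized`, `oversized`), never by dropping
#' the well silently.
#'
#' @param image Preprocessed 2D image.
#' @param clf A `pixel_classifier`, or `NULL` for the threshold baseline.
#' @param expected_cap_area Expected single-cap area in px^2 (e.g.
#'   `pi * (cap_radius_um / pixel_size)^2`).
#' @param min_area_frac,max_area_frac Size gate relative to
#'   `expected_cap_area`; defaults 0.25 and 4 tolerate defocus growth
#'   without admitting tissue fragments.
#' @return A `segmentation_result` with `post_mask`, `n_post_components` and
#'   `qc_flags`.
#' @export
segment_posts <- function(image, clf, expected_cap_area,
                          min_area_frac = 0.25, max_area_frac = 4) {
  dims <- dim(image)
  raw <- if (is.null(clf)) {
    image < (min(image) + max(image)) / 2
  } else {
    class_map(predict_pixel_probs(clf, image), dims) == 1L
  }
  if (!any(raw)) return(seg_result(NULL, NULL, "no_posts", dims))
  filled <- as_mask(matrix(
    as.numeric(EBImage::imageData(EBImage::fillHull(EBImage::Image(raw * 1)))),
    dims[1]))
  lab <- label_components(filled)
  areas <- component_areas(lab)
  lo <- min_area_frac * expected_cap_area
  hi <- max_area_frac * expected_cap_area
  keepable <- which(areas >= lo & areas <= hi)
  flags <- character()
  if (!length(keepable)) {
    if (any(areas < lo)) flags <- c(flags, "undersized")
    if (any(areas > hi)) flags <- c(flags, "oversized")
    return(seg_result(NULL, NULL, c("no_posts", flags), dims))
  }
  if (length(keepable) != 2L) flags <- c(flags, "wrong_count")
  keep <- keepable[order(-areas[keepable])]
  if (length(keep) > 2L) {
    # tie-break equal areas by proximity to the horizontal midline,
    # where the posts hang by construction
    second <- keep[-1]
    tied <- second[areas[second] == areas[keep[2]]]
    if (length(tied) > 1L) {
      cen <- component_centroids(lab)
      mid <- (dims[1] + 1) / 2
      tied <- tied[order(abs(cen[tied, "row"] - mid))]
      keep <- c(keep[1], tied[1])
    } else keep <- keep[1:2]
  }
  seg_result(matrix(lab %in% keep, dims[1]), NULL, flags, dims)
}

#' Segment the tissue
#'
#' Predicts the `tissue` class, keeps the largest connected component, and
#' flags `tissue_absent` (area below `min_area`) and `tissue_touches_border`
#' (detachment QC).
#'
#' @param image Preprocessed 2D image (typically the F-actin channel).
#' @param clf A `pixel_classifier`, or `NULL` for a bright-object threshold
#'   baseline.
#' @param min_area Minimum credible tissue area, px^2.
#' @return A `segmentation_result` with `tissue_mask` and `qc_flags`.
#' @export
segment_tissue <- function(image, clf, min_area = 500) {
  dims <- dim(image)
  raw <- if (is.null(clf)) {
    image > (min(image) + max(image)) / 2
  } else {
    class_map(predict_pixel_probs(clf, image), dims) == 2L
  }
  if (!any(raw)) return(seg_result(NULL, NULL, "tissue_absent", dims))
  lab <- label_components(raw)
  areas <- component_areas(lab)
  main <- which.max(areas)
  mask <- lab == main
  flags <- character()
  if (areas[main] < min_area) flags <- c(flags, "tissue_absent")
  if (any(mask[1, ]) || any(mask[dims[1], ]) ||
      any(mask[, 1]) || any(mask[, dims[2]]))
    flags <- c(flags, "tissue_touches_border")
  seg_result(NULL, mask, flags, dims)
}
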