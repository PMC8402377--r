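#' LIME explanation over a superpixel segmentation
#'
#' The six-step local surrogate procedure: segment the image into
#' superpixels; draw binary on/off perturbation vectors (the all-on vector is
#' always included); build perturbed images by replacing "off" segments with
#' the perturbation baseline; collect the black-box class probabilities; fit
#' a distance-kernel-weighted ridge regression of probability on the binary
#' vectors; and assign each pixel its segment's coefficient.
#'
#' The perturbation baseline defaults to the image mean color, which avoids
#' planting a fake black artifact on dark CT backgrounds. Sample weights use
#' an exponential kernel on the cosine distance of each binary vector to the
#' all-on vector. `ridge = 0` is the documented penalty-to-zero mode (pure
#' weighted least squares) used for oracle validation.
#'
#' @param classifier A `bias_classifier` (black-box contract suffices).
#' @param image HxWx3 array or `scan_image`.
#' @param segmentation A `slic_segmentation`; `NULL` runs [slic_segment()]
#'   with `nslic`.
#' @param class_index Explained class column (2 = class 1 "COVID").
#' @param n_samples Number of random perturbation vectors (must be >=
#'   `n_segments`); ignored when `exhaustive = TRUE`.
#' @param seed RNG seed for the perturbation draw.
#' @param ridge Ridge penalty on segment coefficients (intercept
#'   unpenalised); default 1.
#' @param kernel_width Cosine-distance kernel width (default 0.25).
#' @param baseline `"mean"` (image mean color), `"black"`, or an HxWx3 array.
#' @param exhaustive Enumerate all `2^n_segments` perturbations (requires
#'   `n_segments <= 16`).
#' @param nslic Passed to [slic_segment()] when `segmentation` is `NULL`.
#' @param batch_size Classifier call batch size (result is invariant to it).
#' @return An `xai_heatmap` with convention `symmetric_signed`; segment
#'   coefficients are in `$params$coefficients`.
#' @export
lime_explain <- function(classifier, image, segmentation = NULL,
                         class_index = 2L, n_samples = 1000L, seed = 1L,
                         ridge = 1, kernel_width = 0.25,
                         baseline = "mean", exhaustive = FALSE,
                         nslic = 15L, batch_size = 64L) {
  if (inherits(image, "scan_image")) image <- image$pixels
  if (is.null(segmentation)) segmentation <- slic_segment(image, nslic = nslic)
  labels <- segmentation$labels
  n_seg <- segmentation$n_segments
  if (!exhaustive && n_samples < n_seg)
    stop("n_samples must be >= n_segments (", n_seg, ")")
  if (exhaustive && n_seg > 16)
    stop("exhaustive mode limited to <= 16 segments")

  Z <- if (exhaustive) {
    zz <- as.matrix(expand.grid(rep(list(0:1), n_seg)))
    colnames(zz) <- NULL
    zz
  } else with_seed(seed, {
    rbind(matrix(rbinom(n_samples * n_seg, 1, 0.5), n_samples, n_seg),
          rep(1L, n_seg))
  })

  base_img <- lime_baseline(image, baseline)
  seg_cells <- split(seq_along(labels), as.vector(labels))

  probs <- numeric(nrow(Z))
  for (start in seq(1, nrow(Z), by = batch_size)) {
    idx <- start:min(nrow(Z), start + batch_size - 1)
    batch <- lapply(idx, function(s) {
      img <- image
      off <- which(Z[s, ] == 0)
      if (length(off)) {
        cells <- unlist(seg_cells[off], use.names = FALSE)
        for (ch in 1:3) {
          plane <- img[, , ch]; bp <- base_img[, , ch]
          plane[cells] <- bp[cells]
          img[, , ch] <- plane
        }
      }
      img
    })
    p <- tryCatch(predict_proba(classifier, batch),
                  error = function(e)
                    stop("classifier failed on perturbation batch starting at sample ",
                         start, ": ", conditionMessage(e), call. = FALSE))
    probs[idx] <- p[, class_index]
  }

  coefs <- lime_fit(Z, probs, ridge, kernel_width)
  values <- matrix(coefs[as.vector(labels)], nrow(labels), ncol(labels))
  new_heatmap(values, "LIME", "symmetric_signed",
              params = list(n_segments = n_seg, n_samples = nrow(Z),
                            seed = seed, ridge = ridge,
                            kernel_width = kernel_width,
                            target = "softmax probability",
                            class_index = class_index,
                            classifier = classifier$id,
                            coefficients = coefs))
}

lime_baseline <- function(image, baseline) {
  if (is.array(baseline)) {
    stopifnot(all(dim(baseline) == dim(image)))
    return(baseline)
  }
  switch(baseline,
         mean = {
           mc <- apply(image, 3, mean)
           array(rep(mc, each = dim(image)[1] * dim(image)[2]), dim(image))
         },
         black = array(0, dim(image)),
         stop("unknown baseline '", baseline, "'"))
}

## Kernel-weighted ridge fit; returns segment coefficients (no intercept).
lime_fit <- function(Z, y, ridge, kernel_width) {
  n_seg <- ncol(Z)
  ones_norm <- sqrt(n_seg)
  zn <- sqrt(rowSums(Z))
  cosd <- ifelse(zn > 0, 1 - rowSums(Z) / (zn * ones_norm), 1)
  wts <- exp(-cosd^2 / kernel_width^2)
  X <- cbind(1, Z)
  if (ridge > 0) {
    A <- crossprod(X, wts * X) + diag(c(0, rep(ridge, n_seg)))
    beta <- solve(A, crossprod(X, wts * y))
  } else {
    sw <- sqrt(wts)
    beta <- qr.coef(qr(sw * X), sw * y)
    beta[is.na(beta)] <- 0
  }
  as.numeric(beta)[-1]
}

#' Squaregrid explanation (multi-resolution grid LIME, contributions summed)
#'
#' Avoids superpixel parameter tuning by running LIME over square-cell
#' segmentations whose grids are powers of two (`2^level` cells per side).
#' Cells have equal size `floor(H / 2^level)` and the grid is centred, so any
#' residual offset falls at the image edges (edge cells absorb the
#' remainder); the per-level heatmaps are summed pixelwise with no per-level
#' normalization.
#'
#' @inheritParams lime_explain
#' @param levels Integer vector of grid levels (default `1:5`, i.e. 2x2 up
#'   to 32x32 cells). Levels whose cells would be smaller than 1 px are
#'   skipped with a warning.
#' @param n_samples_per_level LIME samples per level.
#' @return An `xai_heatmap` (`symmetric_signed`).
#' @export
squaregrid_explain <- function(classifier, image, class_index = 2L,
                               levels = 1:5, n_samples_per_level = 1000L,
                               seed = 1L, ridge = 1, kernel_width = 0.25,
                               baseline = "mean", batch_size = 64L) {
  if (inherits(image, "scan_image")) image <- image$pixels
  stopifnot(length(levels) >= 1, all(levels >= 1))
  h <- dim(image)[1]; w <- dim(image)[2]
  acc <- matrix(0, h, w)
  used <- integer(0)
  for (lv in levels) {
    g <- 2^lv
    if (floor(h / g) < 1 || floor(w / g) < 1) {
      warning("level ", lv, " skipped: cells smaller than 1 px")
      next
    }
    seg <- grid_segmentation(h, w, lv)
    hm <- lime_explain(classifier, image, segmentation = seg,
                       class_index = class_index,
                       n_samples = max(n_samples_per_level, seg$n_segments),
                       seed = seed + lv, ridge = ridge,
                       kernel_width = kernel_width, baseline = baseline,
                       batch_size = batch_size)
    acc <- acc + hm$values
    used <- c(used, lv)
  }
  new_heatmap(acc, "Squaregrid", "symmetric_signed",
              params = list(levels = used, seed = seed, ridge = ridge,
                            n_samples_per_level = n_samples_per_level,
                            target = "softmax probability",
                            class_index = class_index,
                            classifier = classifier$id))
}

#' Centred power-of-two grid segmentation
#'
#' @param h,w Image size.
#' @param level Grid level; the grid has `2^level x 2^level` equal cells of
#'   size `floor(h/2^level) x floor(w/2^level)`, centred so residual offsets
#'   fall at the edges (edge cells absorb the remainder).
#' @return A `slic_segmentation`-compatible object with `4^level` segments.
#' @export
grid_segmentation <- function(h, w, level) {
  g <- 2^level
  cell_h <- floor(h / g); cell_w <- floor(w / g)
  stopifnot(cell_h >= 1, cell_w >= 1)
  top <- floor((h - g * cell_h) / 2); left <- floor((w - g * cell_w) / 2)
  rcell <- pmin(pmax(floor((seq_len(h) - 1 - top) / cell_h), 0), g - 1)
  ccell <- pmin(pmax(floor((seq_len(w) - 1 - left) / cell_w), 0), g - 1)
  labels <- outer(rcell, ccell, function(r, cc) r + g * cc + 1L)
  new_segmentation(matrix(as.integer(labels), h, w))
}
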