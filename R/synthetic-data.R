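#' Artifact kinds planted by the synthetic benchmark
#'
#' The generator emulates the artifact taxonomy observed in public COVID
#' CT-scan collections assembled from heterogeneous publications: annotation
#' letters, saturated colored markings, off-gray hue tints, a round frame
#' around the body, a visible scanner support structure, plus the disease
#' surrogate itself (a bright lesion blob, class 1 only).
#'
#' @format Character vector of the six recognised kinds.
#' @export
artifact_kinds <- c("letter", "colored_marking", "hue_tint",
                    "round_frame", "support_structure", "lesion")

.default_split_sizes <- list(train = c(234L, 191L),
                             val   = c(58L, 60L),
                             test  = c(105L, 98L))

.default_artifact_rates <- list(
  letter            = c(0.05, 0.60),
  colored_marking   = c(0.00, 0.25),
  hue_tint          = c(0.02, 0.10),
  round_frame       = c(0.50, 0.50),
  support_structure = c(0.30, 0.70)
)

#' Specification of a synthetic CT-like dataset
#'
#' Describes a two-class (0 = NonCOVID-like, 1 = COVID-like) image benchmark
#' whose spurious artifacts correlate with the class label. The default
#' composition reproduces the 746-image layout of the public COVID-CT
#' collection: train/val/test of 425/118/203 images with per-split class-0 /
#' class-1 counts (234,191), (58,60) and (105,98).
#'
#' Artifact rates are class-conditional plant probabilities. The real
#' collection publishes no quantitative artifact frequencies; the defaults are
#' stand-ins chosen so artifacts correlate with class 1, and are configuration,
#' not claims about the original data.
#'
#' @param split_sizes Named list `split -> c(n_class0, n_class1)`.
#' @param image_size `c(height, width)` in pixels, each >= 32.
#' @param artifact_rates Named list `kind -> c(rate_class0, rate_class1)`;
#'   kinds must be drawn from [artifact_kinds] (lesion is not a plantable
#'   artifact: it is always present in class 1 and never in class 0, so an
#'   unbiased classifier has a learnable signal).
#' @param contrast_jitter Half-width of the multiplicative global intensity
#'   factor `U(1 - j, 1 + j)` applied per image (emulates varying
#'   contrast/lighting).
#' @param aspect_jitter Optional half-width of per-image aspect-ratio jitter
#'   (image rendered at a stretched width then resized back); `0` disables it.
#' @param seed Integer seed; one global stream per dataset, with per-image
#'   substreams derived from the image index so generation is
#'   order-independent.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(split_sizes = .default_split_sizes,
                         image_size = c(224L, 224L),
                         artifact_rates = .default_artifact_rates,
                         contrast_jitter = 0.15,
                         aspect_jitter = 0,
                         seed = 1L) {
  stopifnot(is.list(split_sizes), length(split_sizes) >= 1)
  for (s in names(split_sizes)) {
    n <- split_sizes[[s]]
    if (length(n) != 2 || any(n < 0) || any(n != floor(n)))
      stop("split_sizes[['", s, "']] must be two non-negative counts")
  }
  if (length(image_size) != 2 || any(image_size < 32))
    stop("image_size must be c(height, width) with both >= 32")
  bad <- setdiff(names(artifact_rates), setdiff(artifact_kinds, "lesion"))
  if (length(bad)) stop("unknown artifact kind: ", paste(bad, collapse = ", "))
  for (k in names(artifact_rates)) {
    r <- artifact_rates[[k]]
    if (length(r) != 2 || any(r < 0) || any(r > 1))
      stop("artifact_rates[['", k, "']] must be two probabilities in [0,1]")
  }
  stopifnot_scalar_prob(contrast_jitter, "contrast_jitter")
  structure(list(split_sizes = lapply(split_sizes, as.integer),
                 image_size = as.integer(image_size),
                 artifact_rates = artifact_rates,
                 contrast_jitter = contrast_jitter,
                 aspect_jitter = aspect_jitter,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' @export
print.dataset_spec <- function(x, ...) {
  tot <- vapply(x$split_sizes, sum, numeric(1))
  cat("Synthetic CT-like dataset spec:",
      sum(tot), "images,", paste(names(tot), tot, collapse = " / ", sep = "="),
      "\n  image size:", paste(x$image_size, collapse = "x"),
      " seed:", x$seed, "\n")
  invisible(x)
}

## ---- geometry helpers ------------------------------------------------------

## normalized coordinate grids, cached per size
.grid_env <- new.env(parent = emptyenv())
coord_grid <- function(h, w) {
  key <- paste0(h, "x", w)
  g <- .grid_env[[key]]
  if (is.null(g)) {
    g <- list(yy = matrix((seq_len(h) - 0.5) / h, h, w),
              xx = matrix((seq_len(w) - 0.5) / w, h, w, byrow = TRUE))
    .grid_env[[key]] <- g
  }
  g
}

ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  g <- coord_grid(h, w)
  ((g$yy - cy) / ry)^2 + ((g$xx - cx) / rx)^2 <= 1
}

disc_mask <- function(h, w, cy, cx, r) ellipse_mask(h, w, cy, cx, r, r)

## a glyph is 1-2 axis-aligned bright strokes, loosely letter-like
draw_glyph <- function(h, w, top, left, size, stroke) {
  m <- matrix(FALSE, h, w)
  rows <- top:min(h, top + size - 1)
  cols <- left:min(w, left + stroke - 1)
  m[rows, cols] <- TRUE                                   # vertical stroke
  shape <- sample(c("L", "T", "I"), 1)
  if (shape == "L") {
    r2 <- max(1, min(h, top + size - 1) - stroke + 1):min(h, top + size - 1)
    m[r2, left:min(w, left + size - 1)] <- TRUE
  } else if (shape == "T") {
    m[top:min(h, top + stroke - 1), left:min(w, left + size - 1)] <- TRUE
  }
  m
}

## ---- rendering -------------------------------------------------------------

#' Render one synthetic CT-like scan
#'
#' Paints a dark background, a light elliptical body with two darker lung
#' ellipses, a bright lesion blob inside one lung for class 1, and any
#' requested spurious artifacts, recording a binary ground-truth mask for
#' every element planted. A global multiplicative contrast factor drawn from
#' `1 +/- contrast_jitter` is applied last and the image clipped to `[0,1]`.
#'
#' @param label Class index, 0 (NonCOVID-like) or 1 (COVID-like).
#' @param artifacts Character vector of artifact kinds to plant (subset of
#'   the plantable kinds in [artifact_kinds]); the lesion is controlled by
#'   `label`, not listed here.
#' @param spec A [dataset_spec()] (supplies image size and jitter).
#' @param seed Integer seed for this image's substream.
#' @return A `scan_image`: list with `pixels` (HxWx3 array in \[0,1\]),
#'   `label`, `split`, `masks` (named list of logical HxW matrices, one per
#'   planted element) and `image_id`.
#' @export
render_scan <- function(label, artifacts = character(), spec = dataset_spec(),
                        seed = spec$seed) {
  stopifnot(label %in% c(0, 1))
  artifacts <- unique(as.character(artifacts))
  bad <- setdiff(artifacts, setdiff(artifact_kinds, "lesion"))
  if (length(bad))
    stop("unknown artifact kind: ", paste(bad, collapse = ", "))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  rw <- w
  with_seed(seed, {
    if (spec$aspect_jitter > 0)
      rw <- max(32L, as.integer(round(w * runif(1, 1 - spec$aspect_jitter,
                                                1 + spec$aspect_jitter))))
    img <- .render_scan_core(label, artifacts, h, rw, spec)
  })
  if (rw != w) {
    img$pixels <- vapply(1:3, function(ch) resize_bilinear(img$pixels[, , ch], h, w),
                         matrix(0, h, w))
    img$pixels <- clamp01(array(img$pixels, c(h, w, 3)))
    img$masks <- lapply(img$masks, function(m) resize_bilinear(m * 1, h, w) >= 0.5)
  }
  img$label <- as.integer(label)
  img$split <- NA_character_
  img$image_id <- NA_character_
  class(img) <- "scan_image"
  img
}

.render_scan_core <- function(label, artifacts, h, w, spec) {
  mn <- min(h, w)
  base <- matrix(0.04, h, w) + matrix(rnorm(h * w, 0, 0.015), h, w)

  cy <- 0.5 + runif(1, -0.02, 0.02); cx <- 0.5 + runif(1, -0.02, 0.02)
  by <- runif(1, 0.30, 0.34); bx <- runif(1, 0.38, 0.42)
  body <- ellipse_mask(h, w, cy, cx, by, bx)
  base[body] <- 0.55 + rnorm(sum(body), 0, 0.02)

  lungs <- list(
    ellipse_mask(h, w, cy + 0.01, cx - 0.17, by * 0.62, bx * 0.30),
    ellipse_mask(h, w, cy + 0.01, cx + 0.17, by * 0.62, bx * 0.30))
  for (lg in lungs) base[lg] <- 0.16 + rnorm(sum(lg), 0, 0.02)

  masks <- list()

  if (label == 1) {
    side <- sample(1:2, 1)
    lcy <- cy + 0.01 + runif(1, -0.08, 0.08)
    lcx <- cx + c(-0.17, 0.17)[side] + runif(1, -0.04, 0.04)
    lr <- runif(1, 0.035, 0.055)
    lesion <- disc_mask(h, w, lcy, lcx, lr) & lungs[[side]]
    if (!any(lesion)) lesion <- disc_mask(h, w, cy + 0.01, cx + c(-0.17, 0.17)[side], lr)
    base[lesion] <- 0.80 + rnorm(sum(lesion), 0, 0.02)
    masks$lesion <- lesion
  }

  if ("round_frame" %in% artifacts) {
    g <- coord_grid(h, w)
    d <- sqrt((g$yy - 0.5)^2 + (g$xx - 0.5)^2)
    r0 <- runif(1, 0.44, 0.47)
    frame <- abs(d - r0) <= max(0.006, 1.5 / mn)
    base[frame] <- 0.70
    masks$round_frame <- frame
  }

  if ("support_structure" %in% artifacts) {
    r0 <- round(h * runif(1, 0.90, 0.93))
    rows <- r0:min(h, r0 + max(2L, round(0.02 * h)))
    cols <- round(w * 0.18):round(w * 0.82)
    sup <- matrix(FALSE, h, w); sup[rows, cols] <- TRUE
    base[sup] <- 0.50
    masks$support_structure <- sup
  }

  pix <- array(rep(base, 3), c(h, w, 3))

  if ("letter" %in% artifacts) {
    n_glyph <- sample(1:3, 1)
    corner <- sample(1:4, 1)           # 1 TL, 2 TR, 3 BL, 4 BR
    size <- max(5L, round(0.11 * mn)); stroke <- max(2L, round(0.03 * mn))
    margin <- max(2L, round(0.03 * mn))
    top <- if (corner %in% c(1, 2)) margin else h - margin - size
    lm <- matrix(FALSE, h, w)
    for (i in seq_len(n_glyph)) {
      left <- if (corner %in% c(1, 3)) margin + (i - 1) * (size + stroke)
              else w - margin - i * (size + stroke)
      left <- max(1L, min(w - size, left))
      lm <- lm | draw_glyph(h, w, max(1L, top), left, size, stroke)
    }
    for (ch in 1:3) { p <- pix[, , ch]; p[lm] <- 0.95; pix[, , ch] <- p }
    masks$letter <- lm
  }

  if ("colored_marking" %in% artifacts) {
    # mid-height placement keeps it disjoint from corner letters
    mcy <- runif(1, 0.40, 0.60)
    mcx <- sample(c(runif(1, 0.08, 0.14), runif(1, 0.86, 0.92)), 1)
    mm <- disc_mask(h, w, mcy, mcx, max(0.018, 2.5 / mn))
    col <- rbind(c(0.90, 0.08, 0.08), c(0.95, 0.55, 0.05), c(0.10, 0.80, 0.15))
    col <- col[sample(3, 1), ]
    for (ch in 1:3) { p <- pix[, , ch]; p[mm] <- col[ch]; pix[, , ch] <- p }
    masks$colored_marking <- mm
  }

  if ("hue_tint" %in% artifacts) {
    d <- runif(1, 0.06, 0.12) * sample(c(-1, 1), 1)
    pix[, , 1] <- pix[, , 1] * (1 + d)
    pix[, , 3] <- pix[, , 3] * (1 - d)
    masks$hue_tint <- matrix(TRUE, h, w)
  }

  pix <- clamp01(pix * runif(1, 1 - spec$contrast_jitter, 1 + spec$contrast_jitter))
  list(pixels = pix, masks = masks)
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("scan_image %s: %dx%d, label=%d, split=%s, artifacts: %s\n",
              x$image_id, dim(x$pixels)[1], dim(x$pixels)[2], x$label,
              x$split, paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Generate a full synthetic dataset
#'
#' Draws every image of the composition in `spec`, planting each plantable
#' artifact independently with its class-conditional rate. Counts are exact
#' (not sampled); artifact plants are Bernoulli. Deterministic given
#' `spec$seed`, and independent of generation order because each image uses a
#' substream derived from its global index.
#'
#' @param spec A [dataset_spec()].
#' @return List of `scan_image` objects with `split` and `image_id` filled in.
#' @export
generate_dataset <- function(spec = dataset_spec()) {
  stopifnot(inherits(spec, "dataset_spec"))
  out <- vector("list", sum(vapply(spec$split_sizes, sum, numeric(1))))
  idx <- 0L
  plantable <- names(spec$artifact_rates)
  for (split in names(spec$split_sizes)) {
    counts <- spec$split_sizes[[split]]
    for (cls in 0:1) {
      for (i in seq_len(counts[cls + 1])) {
        idx <- idx + 1L
        sseed <- substream_seed(spec$seed, idx)
        draw <- with_seed(sseed, {
          rates <- vapply(spec$artifact_rates, function(r) r[cls + 1], numeric(1))
          plantable[runif(length(plantable)) < rates]
        })
        img <- render_scan(cls, draw, spec, seed = substream_seed(spec$seed, idx) + 1)
        img$split <- split
        img$image_id <- sprintf("%s_%04d", split, idx)
        out[[idx]] <- img
      }
    }
  }
  out
}

## ---- persistence -----------------------------------------------------------

#' Write a dataset to disk (PNG images, PNG masks, CSV manifest)
#'
#' Images are written as 8-bit RGB PNGs under per-split subdirectories, masks
#' as 8-bit gray \{0,255\} PNGs under `masks/`, and a manifest CSV with one
#' row per image and one flag column per artifact kind.
#'
#' @param images List of `scan_image` objects.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the manifest `data.frame` (also written to
#'   `manifest.csv`).
#' @export
write_dataset <- function(images, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(directory, "masks"), showWarnings = FALSE)
  kinds <- artifact_kinds
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    sub <- file.path(directory, im$split)
    dir.create(sub, showWarnings = FALSE)
    rel <- file.path(im$split, paste0(im$image_id, ".png"))
    ok <- tryCatch(png::writePNG(im$pixels, file.path(directory, rel)),
                   error = function(e)
                     stop("failed writing ", file.path(directory, rel), ": ",
                          conditionMessage(e), call. = FALSE))
    for (k in names(im$masks))
      png::writePNG(im$masks[[k]] * 1,
                    file.path(directory, "masks", paste0(im$image_id, "_", k, ".png")))
    flags <- as.integer(kinds %in% names(im$masks))
    names(flags) <- kinds
    rows[[i]] <- data.frame(image_id = im$image_id, path = rel,
                            label = im$label, split = im$split,
                            as.list(flags), check.names = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = 4 + length(kinds))),
                    c("image_id", "path", "label", "split", kinds))
  utils::write.csv(manifest, file.path(directory, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Persist a dataset spec as a flat JSON config (and read it back)
#'
#' @param spec A [dataset_spec()].
#' @param path JSON file path.
#' @export
write_dataset_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dataset_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset_spec
#' @export
read_dataset_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dataset_spec(split_sizes = as.list(x$split_sizes),
               image_size = x$image_size,
               artifact_rates = as.list(x$artifact_rates),
               contrast_jitter = x$contrast_jitter,
               aspect_jitter = x$aspect_jitter,
               seed = x$seed)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory Directory containing `manifest.csv`.
#' @param with_masks Load artifact masks too (default `TRUE`).
#' @return List of `scan_image` objects.
#' @export
read_dataset <- function(directory, with_masks = TRUE) {
  manifest <- utils::read.csv(file.path(directory, "manifest.csv"),
                              check.names = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    pix <- png::readPNG(file.path(directory, row$path))
    if (length(dim(pix)) == 2) pix <- array(rep(pix, 3), c(dim(pix), 3))
    masks <- list()
    if (with_masks)
      for (k in intersect(artifact_kinds, names(row)))
        if (isTRUE(row[[k]] == 1)) {
          mp <- file.path(directory, "masks", paste0(row$image_id, "_", k, ".png"))
          if (file.exists(mp)) masks[[k]] <- png::readPNG(mp) >= 0.5
        }
    structure(list(pixels = pix[, , 1:3, drop = FALSE], label = as.integer(row$label),
                   split = as.character(row$split), masks = masks,
                   image_id = as.character(row$image_id)),
              class = "scan_image")
  })
}
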