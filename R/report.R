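#' Artifact-localization score for a heatmap
#'
#' Quantifies how much of a heatmap's relevance falls inside a named region.
#' Relevance is derived from the raw map per its scale convention: the
#' positive part for signed and unit maps, the absolute value for magnitude
#' maps, and the minimum-shifted values for `min_max` maps (whose absolute
#' scale has no defined meaning). Then
#' `mass_fraction = sum(relevance in mask) / sum(relevance)` (0 when total
#' relevance is 0), `area_fraction = |mask| / (H*W)`, and
#' `enrichment = mass_fraction / area_fraction` — enrichment > 1 means the
#' method concentrates attention on the region beyond its share of the
#' image. Enrichment, not raw mass, is the headline score because mass
#' conflates region size with attention.
#'
#' @param heatmap An `xai_heatmap`.
#' @param mask Logical HxW matrix (nonempty, same shape as the heatmap).
#' @return List with `mass_fraction`, `area_fraction`, `enrichment`.
#' @export
localization_score <- function(heatmap, mask) {
  stopifnot(inherits(heatmap, "xai_heatmap"), is.matrix(mask))
  mask <- mask != 0
  if (!all(dim(mask) == dim(heatmap$values)))
    stop("mask shape does not match heatmap")
  if (!any(mask)) stop("mask must be nonempty")
  r <- relevance_values(heatmap)
  total <- sum(r)
  mass <- if (total <= 0) 0 else sum(r[mask]) / total
  area <- mean(mask)
  list(mass_fraction = mass, area_fraction = area, enrichment = mass / area)
}

relevance_values <- function(heatmap) {
  v <- heatmap$values
  switch(heatmap$scale_convention,
         symmetric_signed = pmax(v, 0),
         unit = pmax(v, 0),
         magnitude = abs(v),
         min_max = v - min(v))
}

#' Mask of the top fraction of heatmap relevance
#'
#' Pixels whose relevance is at or above the `1 - fraction` quantile
#' (threshold taken as the `ceil(fraction * H * W)`-th largest value, so the
#' region has exactly that many pixels up to ties).
#'
#' @param heatmap An `xai_heatmap`.
#' @param fraction Fraction of pixels to keep (default top decile).
#' @return Logical HxW matrix.
#' @export
top_fraction_mask <- function(heatmap, fraction = 0.1) {
  r <- relevance_values(heatmap)
  k <- ceiling(fraction * length(r))
  thr <- sort(as.vector(r), decreasing = TRUE)[k]
  r >= thr
}

## colormap helpers: all return n x 3 RGB in [0,1]
.ramp_signed <- grDevices::colorRamp(c("#b2182b", "#f7f7f7", "#2166ac"))  # red -> blue
.ramp_unit <- grDevices::colorRamp(c("#ffffff", "#08306b"))               # white -> blue

#' Render a heatmap under its scale convention
#'
#' Produces two rasters: (i) the colormapped heatmap — diverging red/blue
#' centred at zero for `symmetric_signed` (blue = positive), red(min) to
#' blue(max) for `min_max`, single-hue blue for `unit`, grayscale for
#' `magnitude`; and (ii) the underlay image with the top-decile relevance
#' region outlined. Pure function of its inputs.
#'
#' @param heatmap An `xai_heatmap` (finite values; NaN rejected).
#' @param underlay Optional `scan_image` or HxWx3 array drawn under the
#'   outline rendering (defaults to a gray canvas).
#' @param outline_fraction Fraction of pixels outlined (default top decile).
#' @return List with `heat` and `overlay`, both HxWx3 arrays in `[0,1]`.
#' @export
render_heatmap <- function(heatmap, underlay = NULL, outline_fraction = 0.1) {
  stopifnot(inherits(heatmap, "xai_heatmap"))
  v <- heatmap$values
  if (any(is.nan(v))) stop("heatmap contains NaN")
  h <- nrow(v); w <- ncol(v)
  heat_rgb <- switch(
    heatmap$scale_convention,
    symmetric_signed = {
      m <- max(abs(v))
      u <- if (m > 0) (v / m + 1) / 2 else matrix(0.5, h, w)
      ramp_to_array(.ramp_signed, u, h, w)
    },
    min_max = {
      rng <- range(v)
      u <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else matrix(0.5, h, w)
      ramp_to_array(.ramp_signed, u, h, w)
    },
    unit = ramp_to_array(.ramp_unit, clamp01(v), h, w),
    magnitude = {
      m <- max(v)
      u <- if (m > 0) v / m else v * 0
      array(rep(u, 3), c(h, w, 3))
    })
  if (is.null(underlay)) underlay <- array(0.5, c(h, w, 3))
  if (inherits(underlay, "scan_image")) underlay <- underlay$pixels
  stopifnot(all(dim(underlay)[1:2] == c(h, w)))
  region <- top_fraction_mask(heatmap, outline_fraction)
  border <- region & !shrink_mask(region)
  overlay <- underlay
  for (ch in 1:3) {
    p <- overlay[, , ch]
    p[border] <- c(1, 0.1, 0.1)[ch]
    overlay[, , ch] <- p
  }
  list(heat = heat_rgb, overlay = overlay)
}

ramp_to_array <- function(ramp, u, h, w) {
  cols <- ramp(as.vector(u)) / 255
  array(cols, c(h, w, 3))
}

## 4-neighbour erosion (border = mask minus eroded mask)
shrink_mask <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(m[1, , drop = FALSE], m[-h, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[h, , drop = FALSE])
  lf <- cbind(m[, 1, drop = FALSE], m[, -w, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], m[, w, drop = FALSE])
  m & up & dn & lf & rt
}

.all_techniques <- c("gradcam", "vanilla", "smooth", "integrated",
                     "lime", "squaregrid", "rise")

.gradient_techniques <- c("gradcam", "vanilla", "smooth", "integrated")

apply_technique <- function(technique, classifier, image, class_index = 2L,
                            seed = 1L, opts = list()) {
  a <- function(name, default) if (!is.null(opts[[name]])) opts[[name]] else default
  switch(technique,
         gradcam = gradcam(classifier, image, class_index),
         vanilla = vanilla_gradient(classifier, image, class_index),
         smooth = smooth_gradient(classifier, image, class_index,
                                  n_noisy = a("n_noisy", 25L),
                                  sigma = a("sigma", 0.15), seed = seed),
         integrated = integrated_gradient(classifier, image, class_index,
                                          steps = a("steps", 50L)),
         lime = lime_explain(classifier, image, class_index = class_index,
                             n_samples = a("n_samples", 1000L), seed = seed,
                             nslic = a("nslic", 15L)),
         squaregrid = squaregrid_explain(classifier, image,
                                         class_index = class_index,
                                         levels = a("levels", 1:5),
                                         n_samples_per_level =
                                           a("n_samples_per_level", 1000L),
                                         seed = seed),
         rise = rise_explain(classifier, image, class_index = class_index,
                             config = rise_config(a("n_masks", 4000L),
                                                  a("cell_grid", 7L),
                                                  a("keep_prob", 0.5),
                                                  seed = seed)),
         stop("unknown technique '", technique, "'"))
}

#' Per-model x per-technique comparison grid with localization report
#'
#' Runs every requested technique on every classifier for one image, writes
#' the two renderings of each computed heatmap (plus the underlay) into
#' `out_dir`, and scores every computed heatmap against every artifact mask
#' the image carries. Gradient-based techniques are only applied to
#' classifiers satisfying the differentiable contract; GradCAM on an
#' ensemble is recorded as `"undefined for ensembles"` rather than computed.
#' Any other per-cell failure is recorded and the grid continues.
#'
#' @param classifiers List of `bias_classifier` objects (ids used in paths).
#' @param techniques Character vector from
#'   `c("gradcam","vanilla","smooth","integrated","lime","squaregrid","rise")`.
#' @param image A `scan_image` (its masks define the artifact regions).
#' @param out_dir Output directory for PNG panels and the CSV report.
#' @param class_index Explained class.
#' @param seed Seed shared by the stochastic techniques.
#' @param opts Named list of per-technique parameter overrides (e.g.
#'   `list(n_masks = 1000, levels = 2:3)`).
#' @return List with `report` (data.frame: classifier, technique, artifact,
#'   mass_fraction, area_fraction, enrichment, status), `heatmaps` (nested
#'   list), and `files`.
#' @export
compare_report <- function(classifiers, techniques, image, out_dir = NULL,
                           class_index = 2L, seed = 1L, opts = list()) {
  stopifnot(inherits(image, "scan_image"))
  techniques <- match.arg(techniques, .all_techniques, several.ok = TRUE)
  rows <- list(); files <- character(0); heatmaps <- list()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- names(image$masks)
  for (clf in classifiers) {
    heatmaps[[clf$id]] <- list()
    for (tech in techniques) {
      status <- "ok"; hm <- NULL
      if (tech == "gradcam" && inherits(clf, "ensemble_classifier")) {
        status <- "undefined for ensembles"
      } else if (tech %in% .gradient_techniques &&
                 !inherits(clf, "differentiable_classifier")) {
        status <- "requires differentiable classifier"
      } else {
        hm <- tryCatch(apply_technique(tech, clf, image, class_index, seed, opts),
                       error = function(e) {
                         status <<- conditionMessage(e); NULL
                       })
      }
      if (!is.null(hm)) {
        heatmaps[[clf$id]][[tech]] <- hm
        if (!is.null(out_dir)) {
          rend <- render_heatmap(hm, image)
          f1 <- file.path(out_dir, paste0(clf$id, "_", tech, "_heat.png"))
          f2 <- file.path(out_dir, paste0(clf$id, "_", tech, "_overlay.png"))
          png::writePNG(rend$heat, f1); png::writePNG(rend$overlay, f2)
          files <- c(files, f1, f2)
        }
        for (k in kinds) {
          sc <- localization_score(hm, image$masks[[k]])
          rows[[length(rows) + 1]] <-
            data.frame(classifier = clf$id, technique = tech, artifact = k,
                       mass_fraction = sc$mass_fraction,
                       area_fraction = sc$area_fraction,
                       enrichment = sc$enrichment, status = "ok")
        }
      } else {
        rows[[length(rows) + 1]] <-
          data.frame(classifier = clf$id, technique = tech, artifact = NA,
                     mass_fraction = NA_real_, area_fraction = NA_real_,
                     enrichment = NA_real_, status = status)
      }
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "localization_report.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(out_dir, "localization_report.csv"))
  }
  list(report = report, heatmaps = heatmaps, files = files)
}
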