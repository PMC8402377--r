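#' Saliency heatmap container
#'
#' Common output type of all seven explanation methods: an HxW real map plus
#' the technique tag and its scale convention, which downstream rendering and
#' localization scoring interpret:
#' \describe{
#'   \item{symmetric_signed}{signed map, rendered on a diverging scale
#'     centred at 0 (LIME, Squaregrid, Integrated Gradients)}
#'   \item{min_max}{only relative values are meaningful; shifted by the
#'     minimum before scoring (RISE)}
#'   \item{unit}{nonnegative, normalised to max 1 (GradCAM)}
#'   \item{magnitude}{unsigned gradient magnitudes (Vanilla/Smooth
#'     Gradients)}
#' }
#'
#' @param values HxW numeric matrix (finite).
#' @param technique Technique tag, e.g. `"LIME"`.
#' @param scale_convention One of the conventions above.
#' @param params Named list of parameters recorded for provenance.
#' @return Object of class `xai_heatmap`.
#' @export
new_heatmap <- function(values, technique,
                        scale_convention = c("symmetric_signed", "min_max",
                                             "unit", "magnitude"),
                        params = list()) {
  scale_convention <- match.arg(scale_convention)
  stopifnot(is.matrix(values))
  if (!all(is.finite(values))) stop("heatmap values must be finite")
  structure(list(values = values, technique = technique,
                 scale_convention = scale_convention, params = params),
            class = "xai_heatmap")
}

#' @export
print.xai_heatmap <- function(x, ...) {
  cat(sprintf("%s heatmap %dx%d [%s], range [%.4g, %.4g]\n", x$technique,
              nrow(x$values), ncol(x$values), x$scale_convention,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Persist / load a heatmap (32-bit float TIFF + JSON sidecar)
#'
#' @param heatmap An `xai_heatmap`.
#' @param path_base Path without extension; writes `<base>.tif` and
#'   `<base>.json`.
#' @export
save_heatmap <- function(heatmap, path_base) {
  stopifnot(inherits(heatmap, "xai_heatmap"))
  v <- heatmap$values
  rng <- range(v)
  u <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0 + 0.5
  tiff::writeTIFF(u, paste0(path_base, ".tif"), bits.per.sample = 32)
  side <- c(list(technique = heatmap$technique,
                 scale_convention = heatmap$scale_convention,
                 value_min = rng[1], value_max = rng[2]),
            heatmap$params)
  jsonlite::write_json(side, paste0(path_base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path_base)
}

#' @rdname save_heatmap
#' @export
load_heatmap <- function(path_base) {
  u <- tiff::readTIFF(paste0(path_base, ".tif"))
  side <- jsonlite::read_json(paste0(path_base, ".json"), simplifyVector = TRUE)
  vals <- side$value_min + u * (side$value_max - side$value_min)
  drop_keys <- c("technique", "scale_convention", "value_min", "value_max")
  new_heatmap(vals, side$technique, side$scale_convention,
              side[setdiff(names(side), drop_keys)])
}
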