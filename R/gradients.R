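#' GradCAM class activation map
#'
#' The per-map weights `alpha_k` are the global average pool of the gradient
#' of the target class logit with respect to each feature map of the chosen
#' layer; the heatmap is the rectified alpha-weighted sum of the maps,
#' bilinearly upsampled to image size and divided by its maximum when that
#' maximum is positive (so values lie in `[0,1]`).
#'
#' Not defined for ensembles: averaging softmax outputs has no single
#' internal feature layer to attribute to.
#'
#' @param classifier A `differentiable_classifier`.
#' @param image HxWx3 array or `scan_image`.
#' @param class_index Explained class (2 = class 1).
#' @param layer Layer id exposing spatial feature maps; defaults to the last
#'   exposed (deepest) layer.
#' @return `xai_heatmap` with convention `unit` (all values >= 0).
#' @export
gradcam <- function(classifier, image, class_index = 2L, layer = NULL) {
  if (inherits(classifier, "ensemble_classifier"))
    stop("GradCAM is not defined for ensembles of models")
  stopifnot(inherits(classifier, "differentiable_classifier"))
  if (inherits(image, "scan_image")) image <- image$pixels
  if (is.null(layer)) layer <- default_layer(classifier)
  if (!length(layer) || !layer %in% classifier$layers)
    stop("layer '", layer, "' does not expose spatial feature maps")
  A <- feature_maps(classifier, image, layer)
  G <- feature_map_gradient(classifier, image, class_index, layer)
  stopifnot(all(dim(A) == dim(G)), length(dim(A)) == 3)
  alphas <- apply(G, 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alphas)) cam <- cam + alphas[k] * A[, , k]
  cam <- pmax(cam, 0)
  up <- resize_bilinear(cam, dim(image)[1], dim(image)[2])
  up <- pmax(up, 0)                      # guard fp wiggle from interpolation
  if (max(up) > 0) up <- up / max(up)
  new_heatmap(up, "GradCAM", "unit",
              params = list(layer = layer, alphas = alphas,
                            target = "logit", class_index = class_index,
                            classifier = classifier$id))
}

#' Vanilla gradient saliency
#'
#' Per-pixel maximum over channels of the absolute gradient of the target
#' class logit with respect to the input — relevance without sign.
#'
#' @inheritParams gradcam
#' @return `xai_heatmap` with convention `magnitude`.
#' @export
vanilla_gradient <- function(classifier, image, class_index = 2L) {
  stopifnot(inherits(classifier, "differentiable_classifier"))
  if (inherits(image, "scan_image")) image <- image$pixels
  g <- input_gradient(classifier, image, class_index, on = "logit")
  values <- pmax(abs(g[, , 1]), abs(g[, , 2]), abs(g[, , 3]))
  new_heatmap(values, "VanillaGrad", "magnitude",
              params = list(target = "logit", class_index = class_index,
                            classifier = classifier$id))
}

#' SmoothGrad saliency
#'
#' Mean over `n_noisy` draws of [vanilla_gradient()] evaluated at
#' `image + N(0, sigma)` (noise in intensity units; perturbed images are not
#' re-clipped, so gradients are evaluated exactly where perturbed). With
#' `sigma = 0` this equals the vanilla map exactly.
#'
#' @inheritParams gradcam
#' @param n_noisy Number of noisy replicas (>= 1).
#' @param sigma Noise standard deviation as a fraction of the `[0,1]` range.
#' @param seed RNG seed.
#' @return `xai_heatmap` with convention `magnitude`.
#' @export
smooth_gradient <- function(classifier, image, class_index = 2L,
                            n_noisy = 25L, sigma = 0.15, seed = 1L) {
  stopifnot(inherits(classifier, "differentiable_classifier"),
            n_noisy >= 1, sigma >= 0)
  if (inherits(image, "scan_image")) image <- image$pixels
  if (sigma == 0) {
    # all draws coincide with the input: the mean is the vanilla map exactly
    vals <- vanilla_gradient(classifier, image, class_index)$values
    return(new_heatmap(vals, "SmoothGrad", "magnitude",
                       params = list(n_noisy = n_noisy, sigma = 0, seed = seed,
                                     target = "logit", class_index = class_index,
                                     classifier = classifier$id)))
  }
  acc <- matrix(0, dim(image)[1], dim(image)[2])
  with_seed(seed, {
    for (i in seq_len(n_noisy)) {
      noisy <- image + array(rnorm(length(image), 0, sigma), dim(image))
      g <- input_gradient(classifier, noisy, class_index, on = "logit")
      acc <- acc + pmax(abs(g[, , 1]), abs(g[, , 2]), abs(g[, , 3]))
    }
  })
  new_heatmap(acc / n_noisy, "SmoothGrad", "magnitude",
              params = list(n_noisy = n_noisy, sigma = sigma, seed = seed,
                            target = "logit", class_index = class_index,
                            classifier = classifier$id))
}

#' Integrated gradients
#'
#' Midpoint-rule Riemann approximation over `steps` interpolation points of
#' the path integral of the input gradient from `baseline` to the image,
#' multiplied pixelwise by `(image - baseline)` and summed over channels.
#' Satisfies completeness: attributions sum to
#' `y_c(image) - y_c(baseline)` as `steps` grows (20–300 steps are typically
#' sufficient).
#'
#' @inheritParams gradcam
#' @param steps Number of interpolation steps (>= 1; default 50).
#' @param baseline `"black"` or an HxWx3 array of the same shape.
#' @return `xai_heatmap` with convention `symmetric_signed`; the attribution
#'   sum is recorded in `$params$attribution_sum`.
#' @export
integrated_gradient <- function(classifier, image, class_index = 2L,
                                steps = 50L, baseline = "black") {
  stopifnot(inherits(classifier, "differentiable_classifier"), steps >= 1)
  if (inherits(image, "scan_image")) image <- image$pixels
  base <- if (is.character(baseline) && baseline == "black")
    array(0, dim(image)) else baseline
  stopifnot(all(dim(base) == dim(image)))
  diff <- image - base
  acc <- array(0, dim(image))
  for (k in seq_len(steps)) {
    t_k <- (k - 0.5) / steps
    acc <- acc + input_gradient(classifier, base + t_k * diff, class_index,
                                on = "logit")
  }
  attrib <- (acc / steps) * diff
  values <- attrib[, , 1] + attrib[, , 2] + attrib[, , 3]
  new_heatmap(values, "IntegratedGrad", "symmetric_signed",
              params = list(steps = steps, target = "logit",
                            class_index = class_index,
                            classifier = classifier$id,
                            attribution_sum = sum(values)))
}
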