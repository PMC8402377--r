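#' Classifier contracts
#'
#' All explanation methods in this package consume classifiers through two
#' small contracts. A *black-box* classifier only maps a batch of images to
#' softmax probability rows; a *differentiable* classifier additionally
#' exposes class logits, input gradients, and named internal feature maps
#' with their gradients (needed by GradCAM and the gradient explainers).
#'
#' Gradient-based methods differentiate the pre-softmax logit of the target
#' class (standard GradCAM practice); perturbation methods (LIME, Squaregrid,
#' RISE) use the softmax probability.
#'
#' @param predict_fn Function `list-of-HxWx3-arrays -> n x K probability
#'   matrix`; must be pure and preserve batch order.
#' @param n_classes Number of classes K.
#' @param id Character identifier used in reports.
#' @return Object of class `bias_classifier`.
#' @export
new_classifier <- function(predict_fn, n_classes = 2L, id = "classifier") {
  structure(list(predict = predict_fn, n_classes = as.integer(n_classes), id = id),
            class = "bias_classifier")
}

#' @rdname new_classifier
#' @param logit_fn Function `image -> length-K logit vector`.
#' @param input_gradient_fn Function `(image, class_index, on)` returning an
#'   HxWxC array of d y_c / d pixel, where `on` is `"logit"` or `"prob"`.
#' @param layers Character vector of exposed layer ids (last = default
#'   GradCAM layer).
#' @param feature_maps_fn Function `(image, layer)` returning an h x w x K
#'   array of feature maps.
#' @param feature_map_gradient_fn Function `(image, class_index, layer)`
#'   returning an h x w x K array of d y_c / d A^k.
#' @export
new_differentiable_classifier <- function(predict_fn, logit_fn,
                                          input_gradient_fn,
                                          layers, feature_maps_fn,
                                          feature_map_gradient_fn,
                                          n_classes = 2L, id = "classifier") {
  obj <- new_classifier(predict_fn, n_classes, id)
  obj$logits <- logit_fn
  obj$input_gradient <- input_gradient_fn
  obj$layers <- layers
  obj$feature_maps <- feature_maps_fn
  obj$feature_map_gradient <- feature_map_gradient_fn
  class(obj) <- c("differentiable_classifier", class(obj))
  obj
}

#' Predict class probabilities
#'
#' @param classifier A `bias_classifier`.
#' @param images A single HxWx3 array or a list of them.
#' @return `n x K` matrix of probability rows (each sums to 1).
#' @export
predict_proba <- function(classifier, images) {
  stopifnot(inherits(classifier, "bias_classifier"))
  if (is.array(images) && !is.list(images)) images <- list(images)
  p <- classifier$predict(images)
  stopifnot(is.matrix(p), nrow(p) == length(images))
  p
}

#' @rdname new_classifier
#' @param classifier,image,class_index,on,layer See details.
#' @export
class_logits <- function(classifier, image) {
  stopifnot(inherits(classifier, "differentiable_classifier"))
  classifier$logits(image)
}

#' @rdname new_classifier
#' @export
input_gradient <- function(classifier, image, class_index, on = c("logit", "prob")) {
  stopifnot(inherits(classifier, "differentiable_classifier"))
  classifier$input_gradient(image, class_index, match.arg(on))
}

#' @rdname new_classifier
#' @export
feature_maps <- function(classifier, image, layer = default_layer(classifier)) {
  stopifnot(inherits(classifier, "differentiable_classifier"))
  if (!layer %in% classifier$layers)
    stop("layer '", layer, "' is not exposed by this classifier")
  classifier$feature_maps(image, layer)
}

#' @rdname new_classifier
#' @export
feature_map_gradient <- function(classifier, image, class_index,
                                 layer = default_layer(classifier)) {
  stopifnot(inherits(classifier, "differentiable_classifier"))
  if (!layer %in% classifier$layers)
    stop("layer '", layer, "' is not exposed by this classifier")
  classifier$feature_map_gradient(image, class_index, layer)
}

#' @rdname new_classifier
#' @export
default_layer <- function(classifier) {
  classifier$layers[length(classifier$layers)]
}

#' @export
print.bias_classifier <- function(x, ...) {
  cat("<", paste(class(x)[1]), "> id=", x$id, ", classes=", x$n_classes, "\n", sep = "")
  invisible(x)
}

## ---- analytic oracles ------------------------------------------------------

#' Region-oracle classifier (analytic ground truth for explanation methods)
#'
#' A two-class differentiable classifier whose class-1 logit is
#' `gain * mean over region_mask of the channel-weighted pixel intensity`
#' (class-0 logit is 0), passed through softmax. Every derivative has a
#' closed form: the input gradient is `gain * weight_c / |region|` inside the
#' mask and exactly 0 outside, so perturbing any pixel outside the region
#' provably cannot change the prediction. For GradCAM testing it exposes one
#' synthetic layer, `"pooled14"`: a 14x14 block-average pool of the masked
#' channel-weighted image, in which the class-1 logit is exactly linear.
#'
#' @param region_mask Logical HxW matrix; must be nonempty.
#' @param channel_weights Length-3 weights combining RGB channels.
#' @param gain Logit gain (controls how saturated softmax outputs are).
#' @param id Identifier for reports.
#' @return A `differentiable_classifier`.
#' @export
make_region_oracle <- function(region_mask, channel_weights = c(1, 1, 1) / 3,
                               gain = 10, id = "region_oracle") {
  stopifnot(is.matrix(region_mask))
  region_mask <- region_mask != 0
  if (!any(region_mask)) stop("region_mask must be nonempty")
  stopifnot(length(channel_weights) == 3)
  n_reg <- sum(region_mask)
  h <- nrow(region_mask); w <- ncol(region_mask)
  wts <- as.numeric(channel_weights)

  weighted_mean <- function(image) {
    acc <- 0
    for (ch in 1:3) acc <- acc + wts[ch] * sum(image[, , ch][region_mask])
    acc / n_reg
  }
  logit_fn <- function(image) c(0, gain * weighted_mean(image))
  predict_fn <- function(images)
    t(vapply(images, function(im) softmax(logit_fn(im)), numeric(2)))

  input_gradient_fn <- function(image, class_index, on) {
    g <- array(0, dim(image))
    base <- gain / n_reg
    if (class_index == 2)
      for (ch in 1:3) {
        plane <- matrix(0, h, w); plane[region_mask] <- base * wts[ch]
        g[, , ch] <- plane
      }
    if (on == "prob") {
      p <- softmax(logit_fn(image))
      # d p_c / d logit_2 ; logit_1 is constant
      jac <- if (class_index == 2) p[2] * (1 - p[2]) else -p[1] * p[2]
      if (class_index == 1) {     # d p_1 / d pixel = jac * d logit_2 / d pixel
        for (ch in 1:3) {
          plane <- matrix(0, h, w); plane[region_mask] <- gain / n_reg * wts[ch]
          g[, , ch] <- plane
        }
      }
      g <- g * jac
    }
    g
  }

  pool_info <- block_pool_sizes(h, w, 14, 14)
  feature_maps_fn <- function(image, layer) {
    wimg <- image[, , 1] * wts[1] + image[, , 2] * wts[2] + image[, , 3] * wts[3]
    wimg[!region_mask] <- 0
    array(block_pool_mean(wimg, 14, 14), c(14, 14, 1))
  }
  ## y_2 = gain/|R| * sum_blocks |B_ij| A_ij  (exactly linear in the layer)
  feature_map_gradient_fn <- function(image, class_index, layer) {
    g <- if (class_index == 2) gain * pool_info$counts / n_reg
         else matrix(0, 14, 14)
    array(g, c(14, 14, 1))
  }

  oracle <- new_differentiable_classifier(
    predict_fn, logit_fn, input_gradient_fn,
    layers = "pooled14", feature_maps_fn, feature_map_gradient_fn, id = id)
  oracle$region_mask <- region_mask
  oracle
}

#' Linear-logit toy classifier
#'
#' Two-class classifier with class-1 logit `sum(w * image) + b`; used as an
#' exactly solvable ground truth for the gradient explainers.
#'
#' @param w HxWx3 weight array.
#' @param b Scalar bias.
#' @param id Identifier.
#' @return A `differentiable_classifier` (no spatial layers exposed).
#' @export
make_linear_classifier <- function(w, b = 0, id = "linear") {
  stopifnot(length(dim(w)) == 3)
  logit_fn <- function(image) c(0, sum(w * image) + b)
  new_differentiable_classifier(
    predict_fn = function(images)
      t(vapply(images, function(im) softmax(logit_fn(im)), numeric(2))),
    logit_fn = logit_fn,
    input_gradient_fn = function(image, class_index, on) {
      if (on == "logit")
        return(if (class_index == 2) w else array(0, dim(w)))
      p <- softmax(logit_fn(image))
      jac <- if (class_index == 2) p[2] * (1 - p[2]) else -p[1] * p[2]
      w * jac
    },
    layers = character(), feature_maps_fn = function(image, layer) stop("no layers"),
    feature_map_gradient_fn = function(image, class_index, layer) stop("no layers"),
    id = id)
}

#' Constant-output classifier
#'
#' Always returns the same probability row; handy for degenerate-case tests
#' (a constant classifier must produce a zero/flat heatmap under every
#' method).
#'
#' @param p Probability of class 1.
#' @param id Identifier.
#' @export
make_constant_classifier <- function(p = 0.5, id = "constant") {
  stopifnot_scalar_prob(p, "p")
  new_classifier(function(images)
    matrix(rep(c(1 - p, p), each = length(images)), ncol = 2), id = id)
}

## ---- metrics ---------------------------------------------------------------

## internal: metrics from class-1 probabilities + 0/1 labels
metrics_from_probs <- function(p1, labels) {
  pred <- p1 > 0.5
  y <- labels == 1
  acc <- mean(pred == y)
  tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  auc <- if (length(unique(labels)) < 2) NA_real_ else {
    r <- rank(p1)                          # ties get average rank => ties count 1/2
    n1 <- sum(y); n0 <- sum(!y)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(accuracy = acc, f1 = f1, auc = auc)
}

#' Evaluate a classifier on a labelled image split
#'
#' Accuracy at argmax, positive-class (class 1) binary F1, and AUC computed as
#' the probability that a random class-1 image outranks a random class-0 image
#' by class-1 probability (ties counting one half). AUC is `NA` on a
#' single-class split; the other metrics are still computed.
#'
#' @param classifier A `bias_classifier`.
#' @param images List of labelled `scan_image` objects (or any list with
#'   `$pixels` and `$label`).
#' @param batch_size Prediction batch size (results are batch-size invariant).
#' @return `split_metrics` list with `accuracy`, `f1`, `auc`.
#' @export
evaluate <- function(classifier, images, batch_size = 64L) {
  stopifnot(length(images) >= 1)
  labels <- vapply(images, function(im) im$label, numeric(1))
  pix <- lapply(images, function(im) im$pixels)
  p1 <- numeric(length(pix))
  for (start in seq(1, length(pix), by = batch_size)) {
    idx <- start:min(length(pix), start + batch_size - 1)
    p1[idx] <- predict_proba(classifier, pix[idx])[, 2]
  }
  structure(metrics_from_probs(p1, labels), class = "split_metrics")
}

#' @export
print.split_metrics <- function(x, ...) {
  cat(sprintf("accuracy=%.4f  F1=%.4f  AUC=%s\n", x$accuracy, x$f1,
              ifelse(is.na(x$auc), "undefined", sprintf("%.4f", x$auc))))
  invisible(x)
}
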