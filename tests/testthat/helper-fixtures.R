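# Shared fixtures: tiny dataset specs, analytic toy classifiers, and
# independent oracles (finite differences, brute-force least squares,
# naive selection) used to cross-check the package's own computations.

tiny_spec <- function(image_size = c(48, 48), seed = 1,
                      splits = list(train = c(4L, 4L), val = c(2L, 2L),
                                    test = c(1L, 1L))) {
  dataset_spec(split_sizes = splits, image_size = image_size, seed = seed)
}

# central finite difference of y_c (logit or prob) at chosen pixels
fd_gradient_at <- function(clf, image, class_index, pts, on = "logit",
                           h = 1e-4) {
  vapply(seq_len(nrow(pts)), function(t) {
    i <- pts[t, 1]; j <- pts[t, 2]; ch <- pts[t, 3]
    up <- image; up[i, j, ch] <- up[i, j, ch] + h
    dn <- image; dn[i, j, ch] <- dn[i, j, ch] - h
    if (on == "logit")
      (class_logits(clf, up)[class_index] -
         class_logits(clf, dn)[class_index]) / (2 * h)
    else
      (predict_proba(clf, up)[, class_index] -
         predict_proba(clf, dn)[, class_index]) / (2 * h)
  }, numeric(1))
}

# classifier over 8 vertical bands: p(class 1) = 0.1 + 0.2 * z_3,
# where z_3 = 1 iff band 3 still holds its original intensity
band_blackbox <- function(h = 16, w = 16, on_value = 0.8) {
  labels <- matrix(rep(1:8, each = w / 8), h, w, byrow = TRUE)
  seg <- new_segmentation(labels)
  band3 <- seg$labels == 3
  clf <- new_classifier(function(images) {
    p1 <- vapply(images, function(im) 0.1 + 0.2 * (mean(im[, , 1][band3]) >
                                                     on_value / 2),
                 numeric(1))
    cbind(1 - p1, p1)
  }, id = "band_blackbox")
  list(clf = clf, seg = seg, image = array(on_value, c(h, w, 3)))
}

# toy differentiable classifier whose logit is an explicit nonlinear head
# over 3 feature maps (7x7 block means of the channels); the head formula is
# exposed so tests can finite-difference y with respect to the maps.
toy_featuremap_classifier <- function(head_w = c(0.7, -0.4, 0.3)) {
  maps_of <- function(image)
    vapply(1:3, function(ch) block_pool_toy(image[, , ch]),
           matrix(0, 7, 7))
  head_of <- function(A) {
    y <- 0
    for (k in 1:3) y <- y + head_w[k] * sum(tanh(A[, , k]))
    y
  }
  clf <- new_differentiable_classifier(
    predict_fn = function(images)
      t(vapply(images, function(im)
        biaslens:::softmax(c(0, head_of(maps_of(im)))), numeric(2))),
    logit_fn = function(image) c(0, head_of(maps_of(image))),
    input_gradient_fn = function(image, class_index, on)
      stop("not needed for this toy"),
    layers = "pool7",
    feature_maps_fn = function(image, layer) maps_of(image),
    feature_map_gradient_fn = function(image, class_index, layer) {
      A <- maps_of(image)
      g <- array(0, dim(A))
      if (class_index == 2)
        for (k in 1:3) g[, , k] <- head_w[k] * (1 - tanh(A[, , k])^2)
      g
    },
    id = "toy_maps")
  list(clf = clf, maps_of = maps_of, head_of = head_of)
}

block_pool_toy <- function(m) biaslens:::block_pool_mean(m, 7, 7)

# constant differentiable classifier (all gradients identically zero)
constant_differentiable <- function(p = 0.5, size = c(16, 16)) {
  logit <- log(p / (1 - p))
  new_differentiable_classifier(
    predict_fn = function(images)
      matrix(rep(c(1 - p, p), each = length(images)), ncol = 2),
    logit_fn = function(image) c(0, logit),
    input_gradient_fn = function(image, class_index, on) array(0, dim(image)),
    layers = "flat",
    feature_maps_fn = function(image, layer)
      array(1, c(4, 4, 2)),
    feature_map_gradient_fn = function(image, class_index, layer)
      array(0, c(4, 4, 2)),
    id = "constant_diff")
}

# independent naive implementation of the selection rule, used to brute-force
# check select_best: max accuracy, then min size, then smallest id vector
naive_select <- function(records) {
  best <- NULL
  for (i in seq_len(nrow(records))) {
    r <- records[i, , drop = FALSE]
    if (is.null(best)) { best <- r; next }
    if (r$val_accuracy > best$val_accuracy) { best <- r; next }
    if (r$val_accuracy < best$val_accuracy) next
    if (r$size < best$size) { best <- r; next }
    if (r$size > best$size) next
    va <- strsplit(r$member_ids, "+", fixed = TRUE)[[1]]
    vb <- strsplit(best$member_ids, "+", fixed = TRUE)[[1]]
    for (k in seq_len(min(length(va), length(vb)))) {
      if (va[k] < vb[k]) { best <- r; break }
      if (va[k] > vb[k]) break
    }
  }
  best
}
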