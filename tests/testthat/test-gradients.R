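test_that("vanilla gradient is exact for linear logits and local for oracles", {
  set.seed(1)
  w <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  lin <- make_linear_classifier(w, b = 0.3)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  hm <- vanilla_gradient(lin, img, 2)
  expect_equal(hm$values, pmax(abs(w[, , 1]), abs(w[, , 2]), abs(w[, , 3])))
  expect_equal(hm$scale_convention, "magnitude")

  mask <- matrix(FALSE, 12, 12); mask[3:6, 4:8] <- TRUE
  orc <- make_region_oracle(mask, gain = 5)
  ho <- vanilla_gradient(orc, img, 2)
  expect_true(all(ho$values[!mask] == 0))
  expect_true(all(ho$values[mask] > 0))
})

test_that("vanilla gradient matches finite differences on a small CNN", {
  clf <- make_untrained_cnn(c(16, 16), filters = c(4, 6, 8),
                            activation = "tanh", pool = "avg", seed = 9)
  set.seed(10)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  g <- input_gradient(clf, img, 2, on = "logit")
  pts <- cbind(sample(16, 10, replace = TRUE), sample(16, 10, replace = TRUE),
               sample(3, 10, replace = TRUE))
  fd <- fd_gradient_at(clf, img, 2, pts)
  expect_lt(max(abs(g[pts] - fd) / pmax(abs(fd), 1e-6)), 1e-3)
})

test_that("smooth gradients collapse to vanilla at zero noise and stay exact for linear logits", {
  set.seed(2)
  w <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  lin <- make_linear_classifier(w)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  v <- vanilla_gradient(lin, img, 2)
  s0 <- smooth_gradient(lin, img, 2, n_noisy = 7, sigma = 0)
  expect_identical(s0$values, v$values)

  # |d y / d x| = |w| at every point, so the mean over noisy draws is exact
  s <- smooth_gradient(lin, img, 2, n_noisy = 10, sigma = 0.2, seed = 4)
  expect_equal(s$values, v$values, tolerance = 1e-12)

  # n_noisy = 1 equals vanilla at the single noisy point
  s1 <- smooth_gradient(lin, img, 2, n_noisy = 1, sigma = 0.1, seed = 6)
  noisy <- biaslens:::with_seed(6, img + array(rnorm(length(img), 0, 0.1),
                                               dim(img)))
  expect_identical(s1$values, vanilla_gradient(lin, noisy, 2)$values)
})

test_that("integrated gradients are exact for linear logits and vanish at the baseline", {
  set.seed(3)
  w <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  lin <- make_linear_classifier(w)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  for (steps in c(1, 7)) {
    hm <- integrated_gradient(lin, img, 2, steps = steps)
    expect_equal(hm$values,
                 w[, , 1] * img[, , 1] + w[, , 2] * img[, , 2] +
                   w[, , 3] * img[, , 3],
                 tolerance = 1e-12)
  }
  z <- integrated_gradient(lin, img, 2, steps = 5, baseline = img)
  expect_true(all(z$values == 0))
})

test_that("integrated gradients satisfy completeness on a smooth CNN", {
  clf <- make_untrained_cnn(c(16, 16), filters = c(4, 6, 8),
                            activation = "tanh", pool = "avg", seed = 12)
  set.seed(13)
  img <- array(runif(16 * 16 * 3, 0.2, 0.9), c(16, 16, 3))
  target <- class_logits(clf, img)[2] -
    class_logits(clf, array(0, dim(img)))[2]
  gaps <- vapply(c(20, 300), function(steps) {
    hm <- integrated_gradient(clf, img, 2, steps = steps)
    abs(hm$params$attribution_sum - target)
  }, numeric(1))
  expect_lt(gaps[2] / abs(target), 0.01)
  expect_lte(gaps[2], gaps[1] + 1e-12)
})

test_that("all gradient methods return zero maps for a constant classifier", {
  clf <- constant_differentiable(0.6)
  img <- array(0.5, c(16, 16, 3))
  expect_true(all(vanilla_gradient(clf, img, 2)$values == 0))
  expect_true(all(smooth_gradient(clf, img, 2, n_noisy = 3, sigma = 0.1,
                                  seed = 1)$values == 0))
  expect_true(all(integrated_gradient(clf, img, 2, steps = 5)$values == 0))
  expect_true(all(gradcam(clf, img, 2, layer = "flat")$values == 0))
})
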