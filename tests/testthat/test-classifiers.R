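test_that("region oracle matches its closed form and is local to its region", {
  mask <- matrix(FALSE, 20, 20); mask[4:9, 5:11] <- TRUE
  wts <- c(0.5, 0.3, 0.2); gain <- 6
  orc <- make_region_oracle(mask, wts, gain)

  u <- array(0.5, c(20, 20, 3))
  expect_equal(predict_proba(orc, u)[1, ],
               biaslens:::softmax(c(0, gain * 0.5 * sum(wts))))

  set.seed(1)
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  p0 <- predict_proba(orc, img)
  out <- which(!mask, arr.ind = TRUE)[7, ]
  img2 <- img; img2[out[1], out[2], ] <- 1 - img2[out[1], out[2], ]
  expect_identical(predict_proba(orc, img2), p0)

  expect_error(make_region_oracle(matrix(FALSE, 4, 4)), "nonempty")
})

test_that("oracle input gradients match central finite differences", {
  mask <- matrix(FALSE, 20, 20); mask[4:9, 5:11] <- TRUE
  orc <- make_region_oracle(mask, c(0.5, 0.3, 0.2), gain = 6)
  set.seed(2)
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  inside <- which(mask, arr.ind = TRUE)
  pts <- cbind(rbind(inside[sample(nrow(inside), 5), ],
                     which(!mask, arr.ind = TRUE)[c(3, 50, 150, 250, 350), ]),
               sample(3, 10, replace = TRUE))
  for (on in c("logit", "prob")) {
    g <- input_gradient(orc, img, 2, on = on)
    fd <- fd_gradient_at(orc, img, 2, pts, on = on)
    got <- g[pts]
    expect_lt(max(abs(got - fd)), 1e-4)
  }
})

test_that("split metrics reproduce hand-computed values", {
  # perfect separator
  imgs <- lapply(1:6, function(i)
    structure(list(pixels = array(ifelse(i <= 3, 0.1, 0.9), c(8, 8, 3)),
                   label = as.integer(i > 3)), class = "scan_image"))
  sep <- new_classifier(function(images)
    t(vapply(images, function(im) if (mean(im) > 0.5) c(0, 1) else c(1, 0),
             numeric(2))), id = "sep")
  m <- evaluate(sep, imgs)
  expect_equal(unclass(m), list(accuracy = 1, f1 = 1, auc = 1))

  # constant classifier on a 58/60 split: AUC is all ties = 0.5
  imgs2 <- lapply(1:118, function(i)
    structure(list(pixels = array(0.5, c(8, 8, 3)),
                   label = as.integer(i > 58)), class = "scan_image"))
  m2 <- evaluate(make_constant_classifier(0.7), imgs2)
  expect_equal(m2$auc, 0.5)

  # confusion table TP=3 FP=1 FN=1 TN=5 -> F1 = 2*3/(2*3+1+1) = 0.75:
  # 4 positives (3 scored high, 1 low), 6 negatives (1 high, 5 low)
  p1 <- c(0.9, 0.8, 0.7, 0.2, 0.9, 0.1, 0.1, 0.1, 0.2, 0.3)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  mm <- biaslens:::metrics_from_probs(p1, y)
  expect_equal(mm$f1, 0.75)
  expect_equal(mm$accuracy, 0.8)

  # single-class split: AUC undefined, others computed
  m3 <- biaslens:::metrics_from_probs(c(0.9, 0.8), c(1, 1))
  expect_true(is.na(m3$auc))
  expect_equal(m3$accuracy, 1)
})

test_that("tie-aware AUC agrees with an independent implementation", {
  set.seed(9)
  for (r in 1:3) {
    p1 <- round(runif(60), 1)            # coarse grid forces ties
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    ours <- biaslens:::metrics_from_probs(p1, y)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(y, p1, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("prediction is permutation-equivariant and label flips mirror accuracy", {
  mask <- matrix(TRUE, 12, 12)
  orc <- make_region_oracle(mask, gain = 4)
  set.seed(3)
  imgs <- lapply(1:7, function(i) array(runif(12 * 12 * 3), c(12, 12, 3)))
  p <- predict_proba(orc, imgs)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  expect_identical(predict_proba(orc, imgs[perm]), p[perm, ])

  labelled <- lapply(seq_along(imgs)[1:6], function(i)
    structure(list(pixels = imgs[[i]], label = as.integer(i %% 2)),
              class = "scan_image"))
  acc <- evaluate(orc, labelled)$accuracy
  flipped <- lapply(labelled, function(im) { im$label <- 1L - im$label; im })
  expect_equal(evaluate(orc, flipped)$accuracy, 1 - acc)
})
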