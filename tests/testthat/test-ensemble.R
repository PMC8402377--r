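test_that("ensemble prediction is the simple average of member softmax rows", {
  a <- new_classifier(function(images)
    matrix(rep(c(1, 0), each = length(images)), ncol = 2), id = "a")
  b <- new_classifier(function(images)
    matrix(rep(c(0, 1), each = length(images)), ncol = 2), id = "b")
  ens <- ensemble_classifier(list(a, b))
  imgs <- list(array(0, c(4, 4, 3)), array(1, c(4, 4, 3)))
  expect_equal(ensemble_predict(ens, imgs),
               matrix(0.5, 2, 2))
  # single member: identical to that member
  solo <- ensemble_classifier(list(a))
  expect_equal(ensemble_predict(solo, imgs), predict_proba(a, imgs))
  # probability rows stay normalised for arbitrary members
  set.seed(4)
  rnd <- lapply(1:3, function(i) {
    p <- runif(1)
    new_classifier(function(images)
      t(vapply(images, function(im) {
        q <- plogis(mean(im) * (i - 2) * 3)
        c(1 - q, q)
      }, numeric(2))), id = paste0("r", i))
  })
  pr <- ensemble_predict(ensemble_classifier(rnd), imgs)
  expect_equal(rowSums(pr), c(1, 1), tolerance = 1e-9)

  cls3 <- new_classifier(function(images) matrix(1 / 3, length(images), 3),
                         n_classes = 3)
  expect_error(ensemble_classifier(list(a, cls3)), "n_classes")
})

test_that("enumeration yields exactly 2^n - 1 distinct records", {
  set.seed(7)
  labels <- rbinom(30, 1, 0.5)
  for (n in c(1, 2, 4, 6)) {
    ids <- LETTERS[seq_len(n)]
    probs <- matrix(runif(30 * n), 30, n)
    rec <- enumerate_ensembles(ids, probs, labels)
    expect_equal(nrow(rec), 2^n - 1)
    expect_equal(anyDuplicated(rec$member_ids), 0)
    expect_equal(sum(rec$size == 1), n)
    # singleton metrics equal direct metrics of the cached columns
    for (j in seq_len(n)) {
      direct <- biaslens:::metrics_from_probs(probs[, j], labels)
      row <- rec[rec$member_ids == ids[j], ]
      expect_equal(row$val_accuracy, direct$accuracy)
      expect_equal(row$val_auc, direct$auc)
    }
  }
  expect_error(enumerate_ensembles(c("a", "b"), matrix(0.5, 10, 2),
                                   rep(0:1, 4)), "length")
})

test_that("selection maximises accuracy, then prefers fewer members, then lexicographic", {
  rec <- function(ids, acc) data.frame(member_ids = paste(ids, collapse = "+"),
                                       size = length(ids), val_accuracy = acc,
                                       val_f1 = acc, val_auc = acc)
  # the published tie-break: equal accuracy, sizes 3 vs 2 -> the pair wins
  r <- rbind(rec(c("A", "B", "C"), 0.9), rec(c("D", "E"), 0.9))
  expect_equal(select_best(r)$member_ids, "D+E")
  # single record returns itself
  expect_equal(select_best(r[1, ])$member_ids, "A+B+C")
  # remaining ties resolved lexicographically on the member id vectors
  r2 <- rbind(rec(c("A", "B", "C", "D"), 0.96), rec(c("A", "B", "C", "E"), 0.96),
              rec(c("A", "B"), 0.95))
  expect_equal(select_best(r2)$member_ids, "A+B+C+D")
})

test_that("selection agrees with brute force and ignores input order", {
  set.seed(12)
  ids <- c("m1", "m2", "m3", "m4")
  for (trial in 1:25) {
    probs <- matrix(runif(16 * 4), 16, 4)
    labels <- rbinom(16, 1, 0.5)
    rec <- enumerate_ensembles(ids, probs, labels)
    # quantise accuracies to force frequent ties
    rec$val_accuracy <- round(rec$val_accuracy, 1)
    got <- select_best(rec)
    ref <- naive_select(rec)
    expect_equal(got$member_ids, ref$member_ids)
    shuffled <- rec[sample(nrow(rec)), ]
    expect_equal(select_best(shuffled)$member_ids, got$member_ids)
    # the best validation accuracy is never below the best singleton
    expect_gte(got$val_accuracy, max(rec$val_accuracy[rec$size == 1]))
  }
})

test_that("records round-trip through the CSV/JSON writers", {
  set.seed(3)
  rec <- enumerate_ensembles(c("a", "b", "c"), matrix(runif(24), 8, 3),
                             rbinom(8, 1, 0.5))
  dir <- withr::local_tempdir()
  write_ensemble_records(rec, dir)
  back <- utils::read.csv(file.path(dir, "ensemble_records.csv"))
  expect_equal(nrow(back), 7)
  best <- jsonlite::read_json(file.path(dir, "best_ensemble.json"),
                              simplifyVector = TRUE)
  expect_equal(best$member_ids, select_best(rec)$member_ids)
})
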