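#' Simple-average ensemble classifier
#'
#' The ensembled prediction is the unweighted arithmetic mean of the member
#' softmax rows; every member contributes with equal weight. The result is a
#' valid probability row by convexity. The ensemble satisfies the black-box
#' contract (so LIME, Squaregrid and RISE apply) but not the differentiable
#' one; GradCAM rejects it.
#'
#' @param members List of `bias_classifier` objects (>= 1), all with the
#'   same number of classes.
#' @param id Identifier.
#' @return Object of class `c("ensemble_classifier", "bias_classifier")`.
#' @export
ensemble_classifier <- function(members, id = "ensemble") {
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, logical(1), "bias_classifier")))
  ncl <- vapply(members, function(m) m$n_classes, integer(1))
  if (length(unique(ncl)) != 1)
    stop("ensemble members disagree on n_classes")
  obj <- new_classifier(function(images) {
    p <- predict_proba(members[[1]], images)
    for (m in members[-1]) p <- p + predict_proba(m, images)
    p / length(members)
  }, n_classes = ncl[1], id = id)
  obj$members <- members
  class(obj) <- c("ensemble_classifier", class(obj))
  obj
}

#' @rdname ensemble_classifier
#' @param ensemble An `ensemble_classifier`.
#' @param images Single image or list of images.
#' @export
ensemble_predict <- function(ensemble, images) {
  stopifnot(inherits(ensemble, "ensemble_classifier"))
  predict_proba(ensemble, images)
}

## subset member indicator matrix: (2^n - 1) x n_models
subset_indicators <- function(n) {
  stopifnot(n >= 1, n <= 20)
  ids <- seq_len(2^n - 1)
  matrix(vapply(seq_len(n), function(j) bitwAnd(ids, bitwShiftL(1L, j - 1L)) > 0,
                logical(length(ids))),
         nrow = length(ids), ncol = n)
}

#' Exhaustively enumerate all model ensembles
#'
#' Builds one record per nonempty subset of the model pool (`2^n - 1`
#' records), computing each subset's validation metrics from the simple
#' average of cached per-model class-1 probabilities — bit-identical to
#' re-running inference by the purity contract, but fast enough that all
#' 16,383 ensembles of a 14-model pool are scored in seconds.
#'
#' @param model_ids Character vector of model identifiers.
#' @param val_probs Numeric matrix `n_images x n_models` of cached class-1
#'   validation probabilities (columns in `model_ids` order).
#' @param labels 0/1 validation labels (length `n_images`).
#' @param test_probs,test_labels Optional test-set analogues; reported only,
#'   never used for selection.
#' @return `data.frame` of class `ensemble_records`, one row per subset:
#'   `member_ids` ("+"-joined), `size`, `val_accuracy`, `val_f1`, `val_auc`
#'   and, if supplied, `test_*` columns.
#' @export
enumerate_ensembles <- function(model_ids, val_probs, labels,
                                test_probs = NULL, test_labels = NULL) {
  n <- length(model_ids)
  stopifnot(n >= 1)
  val_probs <- as.matrix(val_probs)
  if (nrow(val_probs) != length(labels))
    stop("val_probs rows and labels length differ")
  if (ncol(val_probs) != n) stop("val_probs must have one column per model")
  ind <- subset_indicators(n)
  sizes <- rowSums(ind)
  members <- apply(ind, 1, function(r) paste(model_ids[r], collapse = "+"))
  metrics <- subset_metrics(val_probs, labels, ind, sizes)
  rec <- data.frame(member_ids = members, size = sizes,
                    val_accuracy = metrics$accuracy, val_f1 = metrics$f1,
                    val_auc = metrics$auc, stringsAsFactors = FALSE)
  if (!is.null(test_probs)) {
    test_probs <- as.matrix(test_probs)
    if (nrow(test_probs) != length(test_labels))
      stop("test_probs rows and test_labels length differ")
    tm <- subset_metrics(test_probs, test_labels, ind, sizes)
    rec$test_accuracy <- tm$accuracy; rec$test_f1 <- tm$f1; rec$test_auc <- tm$auc
  }
  class(rec) <- c("ensemble_records", "data.frame")
  rec
}

subset_metrics <- function(probs, labels, ind, sizes) {
  avg <- probs %*% t(ind)                 # n_images x n_subsets
  avg <- sweep(avg, 2, sizes, "/")
  y <- labels == 1
  pred <- avg > 0.5
  acc <- colMeans(pred == y)
  tp <- colSums(pred & y); fp <- colSums(pred & !y); fn <- colSums(!pred & y)
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, 0, 2 * tp / denom)
  auc <- if (length(unique(labels)) < 2) rep(NA_real_, ncol(avg)) else {
    n1 <- sum(y); n0 <- sum(!y)
    apply(avg, 2, function(p) (sum(rank(p)[y]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  list(accuracy = acc, f1 = f1, auc = auc)
}

## lexicographic comparison of two "+"-joined member id strings
members_less <- function(a, b) {
  va <- strsplit(a, "+", fixed = TRUE)[[1]]
  vb <- strsplit(b, "+", fixed = TRUE)[[1]]
  for (i in seq_len(min(length(va), length(vb)))) {
    if (va[i] < vb[i]) return(TRUE)
    if (va[i] > vb[i]) return(FALSE)
  }
  length(va) < length(vb)
}

#' Select the best ensemble record
#'
#' Maximal validation accuracy first; among ties, the fewest members; among
#' remaining ties, the lexicographically smallest member id set (a
#' deterministic stand-in for picking a tied ensemble at random — at
#' thousands of subsets exact ties do occur). Selection never consults test
#' metrics.
#'
#' @param records An `ensemble_records` data frame (or compatible).
#' @return The selected record as a one-row data frame.
#' @export
select_best <- function(records) {
  stopifnot(nrow(records) >= 1)
  best <- records[records$val_accuracy == max(records$val_accuracy), , drop = FALSE]
  best <- best[best$size == min(best$size), , drop = FALSE]
  if (nrow(best) > 1) {
    sel <- 1L
    for (i in seq_len(nrow(best))[-1])
      if (members_less(best$member_ids[i], best$member_ids[sel])) sel <- i
    best <- best[sel, , drop = FALSE]
  }
  rownames(best) <- NULL
  best
}

#' Write ensemble-search outputs
#'
#' CSV of all records plus a JSON of the selected record (and the scatter
#' data for an accuracy-vs-size plot).
#'
#' @param records An `ensemble_records` data frame.
#' @param out_dir Output directory.
#' @export
write_ensemble_records <- function(records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, file.path(out_dir, "ensemble_records.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(select_best(records)),
                       file.path(out_dir, "best_ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
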