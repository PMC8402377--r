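#' RISE configuration
#'
#' Randomized Input Sampling for Explanation probes a black box with random
#' soft occlusion masks: each mask starts as an `s x s` Bernoulli(`keep_prob`)
#' binary grid, is bilinearly upsampled to a canvas one cell larger than the
#' image, and cropped at a uniform random offset within one cell. Defaults
#' (`n_masks = 4000`, `cell_grid = 7`, `keep_prob = 0.5`) follow original
#' RISE practice.
#'
#' @param n_masks Number of masks N (>= 1).
#' @param cell_grid Small-mask resolution s (>= 2).
#' @param keep_prob Probability p1 that a grid cell is preserved, in (0,1).
#' @param seed RNG seed.
#' @export
rise_config <- function(n_masks = 4000L, cell_grid = 7L, keep_prob = 0.5,
                        seed = 1L) {
  stopifnot(n_masks >= 1, cell_grid >= 2, keep_prob > 0, keep_prob <= 1)
  structure(list(n_masks = as.integer(n_masks), cell_grid = as.integer(cell_grid),
                 keep_prob = keep_prob, seed = as.integer(seed)),
            class = "rise_config")
}

## Draw all mask randomness up front: the s x s Bernoulli grids and the crop
## offsets. Mask construction itself is deterministic, so explanation results
## cannot depend on the classifier-call batch size.
draw_rise_randomness <- function(n, s, p1, h, w) {
  ch <- ceiling(h / s); cw <- ceiling(w / s)
  list(G = matrix(rbinom(n * s * s, 1, p1), n, s * s),
       oy = sample.int(ch, n, replace = TRUE) - 1L,
       ox = sample.int(cw, n, replace = TRUE) - 1L)
}

## Build masks rows `rows` as a length(rows) x (H*W) matrix in [0,1].
build_rise_masks <- function(rnd, rows, s, h, w) {
  ch <- ceiling(h / s); cw <- ceiling(w / s)
  CH <- h + ch; CW <- w + cw
  # map canvas pixel centers to grid coordinates (grid cell size = ch/cw)
  gy <- (seq_len(CH) - 0.5) / ch - 0.5
  gx <- (seq_len(CW) - 0.5) / cw - 0.5
  clamp_axis <- function(g, s) {
    i0 <- floor(g)
    f <- g - i0
    f[i0 < 0] <- 0; i0[i0 < 0] <- 0
    f[i0 > s - 2] <- 1; i0[i0 > s - 2] <- s - 2
    list(i0 = as.integer(i0) + 1L, f = f)     # 1-based lower index
  }
  ay <- clamp_axis(gy, s); ax <- clamp_axis(gx, s)
  # canvas-pixel -> 4 grid indices (into s*s vector, column-major) + weights
  iy0 <- rep(ay$i0, CW); fy <- rep(ay$f, CW)
  ix0 <- rep(ax$i0, each = CH); fx <- rep(ax$f, each = CH)
  i00 <- iy0 + (ix0 - 1L) * s
  i10 <- i00 + 1L
  i01 <- i00 + s
  i11 <- i01 + 1L
  nb <- length(rows)
  G <- rnd$G[rows, , drop = FALSE]
  # two-stage lerp (exact for constant grids, e.g. p1 = 1 -> mask == 1)
  fyr <- rep(fy, each = nb); fxr <- rep(fx, each = nb)
  colA <- G[, i00, drop = FALSE]
  colA <- colA + fyr * (G[, i10, drop = FALSE] - colA)
  colB <- G[, i01, drop = FALSE]
  colB <- colB + fyr * (G[, i11, drop = FALSE] - colB)
  canvas <- colA + fxr * (colB - colA)
  base <- rep((seq_len(w) - 1L) * CH, each = h) + rep(seq_len(h), w)  # crop at (0,0)
  out <- matrix(0, nb, h * w)
  for (i in seq_len(nb))
    out[i, ] <- canvas[i, base + rnd$oy[rows[i]] + rnd$ox[rows[i]] * CH]
  out
}

#' Generate RISE occlusion masks
#'
#' @param config A [rise_config()].
#' @param out_size `c(h, w)` of the image to be probed.
#' @param n Number of masks to return (default `config$n_masks`).
#' @return List of HxW numeric masks with values in `[0,1]`; deterministic
#'   given `config$seed`.
#' @export
rise_masks <- function(config, out_size, n = config$n_masks) {
  h <- out_size[1]; w <- out_size[2]
  rnd <- with_seed(config$seed,
                   draw_rise_randomness(n, config$cell_grid, config$keep_prob, h, w))
  M <- build_rise_masks(rnd, seq_len(n), config$cell_grid, h, w)
  lapply(seq_len(n), function(i) matrix(M[i, ], h, w))
}

#' RISE explanation
#'
#' Heatmap `H = 1/(N p1) * sum_i f(I (.) M_i) M_i`, where `(.)` is pixelwise
#' multiplication broadcast over channels and `f` the softmax probability of
#' the explained class. For a constant classifier `f = c` the expected value
#' of every pixel is exactly `c` (since `E[M] = p1`).
#'
#' @inheritParams lime_explain
#' @param config A [rise_config()].
#' @param return_se Attach the per-pixel Monte-Carlo standard error as
#'   attribute `"se"`.
#' @return An `xai_heatmap` with convention `min_max`.
#' @export
rise_explain <- function(classifier, image, class_index = 2L,
                         config = rise_config(), batch_size = 200L,
                         return_se = FALSE) {
  if (inherits(image, "scan_image")) image <- image$pixels
  h <- dim(image)[1]; w <- dim(image)[2]
  n <- config$n_masks; p1 <- config$keep_prob
  acc <- numeric(h * w); acc2 <- numeric(h * w)
  rnd <- with_seed(config$seed,
                   draw_rise_randomness(n, config$cell_grid, p1, h, w))
  done <- 0L
  while (done < n) {
    rows <- (done + 1):min(n, done + batch_size)
    M <- build_rise_masks(rnd, rows, config$cell_grid, h, w)
    batch <- lapply(seq_len(nrow(M)), function(i) {
      m <- matrix(M[i, ], h, w)
      image * array(rep(m, 3), c(h, w, 3))
    })
    f <- tryCatch(predict_proba(classifier, batch)[, class_index],
                  error = function(e)
                    stop("classifier failed on mask ", done + 1, ": ",
                         conditionMessage(e), call. = FALSE))
    contrib <- (f / p1) * M              # row-scale each mask by its weight
    acc <- acc + colSums(contrib)
    acc2 <- acc2 + colSums(contrib^2)
    done <- done + length(rows)
  }
  values <- matrix(acc / n, h, w)
  hm <- new_heatmap(values, "RISE", "min_max",
                    params = list(n_masks = n, cell_grid = config$cell_grid,
                                  keep_prob = p1, seed = config$seed,
                                  target = "softmax probability",
                                  class_index = class_index,
                                  classifier = classifier$id))
  if (return_se) {
    v <- pmax(acc2 / n - (acc / n)^2, 0)
    attr(hm, "se") <- matrix(sqrt(v / n), h, w)
  }
  hm
}
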