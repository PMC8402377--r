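#' @keywords internal
"_PACKAGE"

## Shared numeric helpers. Nothing here is exported.

clamp01 <- function(x) {      # preserves dim attributes, unlike pmax(0, x)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

relu <- function(x) pmax(x, 0)

#' Run code with a temporarily seeded RNG, restoring the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(code)
}

## Order-independent per-item substream seed (kept < 2^31).
substream_seed <- function(seed, index) {
  (as.double(seed) %% 2147483647 + as.double(index) * 48271) %% 2147483647
}

#' Bilinear resize of a matrix (half-pixel centers, edges clamped).
#' @noRd
resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  map_axis <- function(n_out, n_in) {
    # centers of output pixels mapped into input pixel-center coordinates
    x <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5 - 0.5  # 1-based center coords
    x <- pmin(pmax(x, 1), n_in)
    i0 <- pmin(floor(x), n_in - 1L)
    if (n_in == 1L) i0 <- rep(1, n_out)
    frac <- x - i0
    list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1, n_in)), f = frac)
  }
  ry <- map_axis(out_h, in_h)
  rx <- map_axis(out_w, in_w)
  a <- m[ry$i0, rx$i0, drop = FALSE]
  b <- m[ry$i1, rx$i0, drop = FALSE]
  cc <- m[ry$i0, rx$i1, drop = FALSE]
  d <- m[ry$i1, rx$i1, drop = FALSE]
  fy <- matrix(ry$f, out_h, out_w)
  fx <- matrix(rx$f, out_h, out_w, byrow = TRUE)
  (a * (1 - fy) + b * fy) * (1 - fx) + (cc * (1 - fy) + d * fy) * fx
}

## Block average pooling to an out_h x out_w grid (blocks as equal as possible).
block_pool_mean <- function(m, out_h, out_w) {
  rb <- findInterval(seq_len(nrow(m)) - 1, seq(0, nrow(m), length.out = out_h + 1),
                     rightmost.closed = TRUE)
  cb <- findInterval(seq_len(ncol(m)) - 1, seq(0, ncol(m), length.out = out_w + 1),
                     rightmost.closed = TRUE)
  rb <- pmin(rb, out_h); cb <- pmin(cb, out_w)
  rm_ <- rowsum(m, rb)                       # out_h x W sums over row blocks
  cm_ <- t(rowsum(t(rm_), cb))               # out_h x out_w sums
  cnt <- tabulate(rb, out_h) %o% tabulate(cb, out_w)
  cm_ / cnt
}

## Sizes of the blocks used by block_pool_mean (for analytic gradients).
block_pool_sizes <- function(in_h, in_w, out_h, out_w) {
  rb <- findInterval(seq_len(in_h) - 1, seq(0, in_h, length.out = out_h + 1),
                     rightmost.closed = TRUE)
  cb <- findInterval(seq_len(in_w) - 1, seq(0, in_w, length.out = out_w + 1),
                     rightmost.closed = TRUE)
  list(row_block = pmin(rb, out_h), col_block = pmin(cb, out_w),
       counts = tabulate(pmin(rb, out_h), out_h) %o% tabulate(pmin(cb, out_w), out_w))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0,1]", name), call. = FALSE)
}
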