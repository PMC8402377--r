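#' SLIC superpixel segmentation
#'
#' Localized k-means clustering in the 5-D space combining CIELAB color with
#' the pixel coordinates, seeded on a regular grid of spacing
#' `S = sqrt(HW / nslic)`. Each center only competes for pixels within a
#' `2S x 2S` window, and the distance is
#' `sqrt(d_lab^2 + (compactness / S)^2 * d_xy^2)`. After convergence,
#' connected components are relabelled and fragments smaller than a quarter
#' of the mean segment size are merged into their dominant neighbour, so the
#' result is a partition of the image into contiguous, nonempty segments.
#'
#' The requested count `nslic` is a target; the actual `n_segments` may
#' differ. The default `nslic = 15` is the heuristic that separates
#' background from lung fields on CT-like images. Labels are `1..n_segments`
#' (R convention).
#'
#' @param image HxWx3 array in `[0,1]` (or a `scan_image`).
#' @param nslic Requested number of superpixels (>= 2).
#' @param compactness Spatial regularity weight (SLIC "m"), default 10.
#' @param max_iter k-means iterations.
#' @return Object of class `slic_segmentation`: list with `labels`
#'   (HxW integer matrix) and `n_segments`. A constant image yields a single
#'   segment and a `degenerate` attribute with a warning.
#' @export
slic_segment <- function(image, nslic = 15L, compactness = 10, max_iter = 10L) {
  if (inherits(image, "scan_image")) image <- image$pixels
  stopifnot(length(dim(image)) == 3, nslic >= 2)
  h <- dim(image)[1]; w <- dim(image)[2]; n <- h * w
  rgb <- matrix(image, n, 3)
  if (max(rgb) - min(rgb) < 1e-9) {
    warning("constant image: returning a single segment")
    return(structure(list(labels = matrix(1L, h, w), n_segments = 1L),
                     degenerate = TRUE, class = "slic_segmentation"))
  }
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1], h, w); A <- matrix(lab[, 2], h, w); B <- matrix(lab[, 3], h, w)
  S <- sqrt(n / nslic)
  kx <- max(1L, ceiling(sqrt(nslic * w / h)))
  ky <- max(1L, ceiling(nslic / kx))
  gy <- pmin(pmax(round((seq_len(ky) - 0.5) * h / ky), 1), h)
  gx <- pmin(pmax(round((seq_len(kx) - 0.5) * w / kx), 1), w)
  centers <- expand.grid(y = unique(gy), x = unique(gx))
  k <- nrow(centers)
  cen <- data.frame(y = centers$y, x = centers$x,
                    L = L[cbind(centers$y, centers$x)],
                    A = A[cbind(centers$y, centers$x)],
                    B = B[cbind(centers$y, centers$x)])
  m2 <- (compactness / S)^2
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  assign_lab <- matrix(0L, h, w)
  for (it in seq_len(max_iter)) {
    D <- matrix(Inf, h, w)
    for (ci in seq_len(k)) {
      rr <- max(1, round(cen$y[ci] - 2 * S)):min(h, round(cen$y[ci] + 2 * S))
      cc <- max(1, round(cen$x[ci] - 2 * S)):min(w, round(cen$x[ci] + 2 * S))
      dl <- (L[rr, cc, drop = FALSE] - cen$L[ci])^2 +
            (A[rr, cc, drop = FALSE] - cen$A[ci])^2 +
            (B[rr, cc, drop = FALSE] - cen$B[ci])^2
      dxy <- (yy[rr, cc, drop = FALSE] - cen$y[ci])^2 +
             (xx[rr, cc, drop = FALSE] - cen$x[ci])^2
      d <- dl + m2 * dxy
      sel <- d < D[rr, cc]
      Dw <- D[rr, cc, drop = FALSE]; Lw <- assign_lab[rr, cc, drop = FALSE]
      Dw[sel] <- d[sel]; Lw[sel] <- ci
      D[rr, cc] <- Dw; assign_lab[rr, cc] <- Lw
    }
    # any pixel missed by all windows: nearest center by xy
    miss <- which(assign_lab == 0L)
    if (length(miss)) {
      my <- ((miss - 1) %% h) + 1; mx <- ((miss - 1) %/% h) + 1
      for (ii in seq_along(miss)) {
        d <- (cen$y - my[ii])^2 + (cen$x - mx[ii])^2
        assign_lab[miss[ii]] <- which.min(d)
      }
    }
    av <- as.vector(assign_lab)
    sums <- rowsum(cbind(as.vector(yy), as.vector(xx), lab), av)
    cnt <- tabulate(av, k)
    live_ids <- sort(unique(av))          # rowsum rows follow sorted group ids
    cen[live_ids, c("y", "x", "L", "A", "B")] <- sums / cnt[live_ids]
  }
  lab_final <- enforce_connectivity(assign_lab, min_size = max(4, floor(n / k / 4)))
  structure(list(labels = lab_final, n_segments = max(lab_final)),
            class = "slic_segmentation")
}

## Relabel into connected components (4-neighbour) by iterative minimum-label
## propagation, then merge small fragments into their dominant neighbour.
enforce_connectivity <- function(assign_lab, min_size = 4) {
  h <- nrow(assign_lab); w <- ncol(assign_lab)
  comp <- matrix(seq_len(h * w), h, w)
  repeat {
    up <- rbind(comp[1, , drop = FALSE], comp[-h, , drop = FALSE])
    dn <- rbind(comp[-1, , drop = FALSE], comp[h, , drop = FALSE])
    lf <- cbind(comp[, 1, drop = FALSE], comp[, -w, drop = FALSE])
    rt <- cbind(comp[, -1, drop = FALSE], comp[, w, drop = FALSE])
    nb <- pmin(ifelse(rbind(assign_lab[1, , drop = FALSE],
                            assign_lab[-h, , drop = FALSE]) == assign_lab, up, Inf),
               ifelse(rbind(assign_lab[-1, , drop = FALSE],
                            assign_lab[h, , drop = FALSE]) == assign_lab, dn, Inf),
               ifelse(cbind(assign_lab[, 1, drop = FALSE],
                            assign_lab[, -w, drop = FALSE]) == assign_lab, lf, Inf),
               ifelse(cbind(assign_lab[, -1, drop = FALSE],
                            assign_lab[, w, drop = FALSE]) == assign_lab, rt, Inf))
    new <- pmin(comp, nb)
    if (all(new == comp)) break
    comp <- new
  }
  comp <- matrix(match(comp, sort(unique(as.vector(comp)))), h, w)
  # merge fragments below min_size into the most frequent neighbouring comp
  repeat {
    sizes <- tabulate(comp, max(comp))
    small <- which(sizes > 0 & sizes < min_size)
    if (!length(small)) break
    changed <- FALSE
    for (sc in small) {
      cells <- which(comp == sc)
      ys <- ((cells - 1) %% h) + 1; xs <- ((cells - 1) %/% h) + 1
      nbr <- integer(0)
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ny <- ys + dd[1]; nx <- xs + dd[2]
        ok <- ny >= 1 & ny <= h & nx >= 1 & nx <= w
        nbr <- c(nbr, comp[cbind(ny[ok], nx[ok])])
      }
      nbr <- nbr[nbr != sc]
      if (!length(nbr)) next
      comp[cells] <- as.integer(names(which.max(table(nbr))))
      changed <- TRUE
    }
    if (!changed) break
    comp <- matrix(match(comp, sort(unique(as.vector(comp)))), h, w)
  }
  matrix(as.integer(comp), h, w)
}

#' Construct a segmentation from an explicit label matrix
#'
#' @param labels HxW integer matrix with labels `1..n` covering all pixels.
#' @return A `slic_segmentation`-compatible object.
#' @export
new_segmentation <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  u <- sort(unique(as.vector(labels)))
  if (!identical(u, seq_along(u))) {
    labels <- matrix(match(labels, u), nrow(labels), ncol(labels))
    u <- seq_along(u)
  }
  structure(list(labels = labels, n_segments = length(u)),
            class = "slic_segmentation")
}

#' @export
print.slic_segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %dx%d pixels, %d segments\n",
              nrow(x$labels), ncol(x$labels), x$n_segments))
  invisible(x)
}
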