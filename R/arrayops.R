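# Low-level vectorized 3D array primitives shared by the segmentation and
# pipeline modules. Everything here operates on plain (z, y, x) arrays.

# shift `a` along `axis` by `off` voxels; vacated positions are filled
# according to `pad`: "zero", "edge" (replicate border) or "reflect" (mirror
# including the border voxel).
shift3d <- function(a, axis, off, pad = c("zero", "edge", "reflect")) {
  pad <- match.arg(pad)
  if (off == 0) return(a)
  n <- dim(a)[axis]
  idx <- seq_len(n) + off
  if (pad == "edge") {
    idx <- pmin(pmax(idx, 1L), n)
  } else if (pad == "reflect") {
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
  } else {
    idx[idx < 1L | idx > n] <- NA_integer_
  }
  out <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
  if (pad == "zero" && anyNA(idx)) out[is.na(out)] <- 0
  out
}

# separable correlation of `a` with a 1D kernel along one axis
conv_axis <- function(a, kernel, axis, pad) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = dim(a))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * shift3d(a, axis, j - r - 1L, pad)
  out
}

# truncated sampled Gaussian kernel, normalized to sum 1
gaussian_kernel1d <- function(sigma, truncate = 3) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# binary erosion with a 3x3x3 cross (6-neighborhood) or box (26-neighborhood)
# structuring element; outside the grid counts as background.
erode3d_once <- function(m, se = c("cross", "box")) {
  se <- match.arg(se)
  storage.mode(m) <- "logical"
  if (se == "cross") {
    out <- m
    for (ax in 1:3)
      out <- out & shift3d(m, ax, -1L, "zero") & shift3d(m, ax, 1L, "zero")
    out
  } else {
    out <- m
    for (ax in 1:3)
      out <- out & shift3d(out, ax, -1L, "zero") & shift3d(out, ax, 1L, "zero")
    out
  }
}

dilate3d_once <- function(m, se = c("cross", "box")) {
  se <- match.arg(se)
  storage.mode(m) <- "logical"
  if (se == "cross") {
    out <- m
    for (ax in 1:3)
      out <- out | shift3d(m, ax, -1L, "zero") | shift3d(m, ax, 1L, "zero")
    out
  } else {
    out <- m
    for (ax in 1:3)
      out <- out | shift3d(out, ax, -1L, "zero") | shift3d(out, ax, 1L, "zero")
    out
  }
}

# morphological reconstruction by dilation of `marker` inside `mask`
# (26-connectivity); returns the union of mask components touched by marker.
reconstruct3d <- function(marker, mask) {
  cur <- marker & mask
  repeat {
    nxt <- dilate3d_once(cur, "box") & mask
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# keep the largest 26-connected component of a binary mask
largest_component3d <- function(mask) {
  storage.mode(mask) <- "logical"
  remaining <- mask
  best <- NULL
  best_n <- -1L
  while (any(remaining)) {
    seed <- array(FALSE, dim = dim(mask))
    seed[which(remaining)[1L]] <- TRUE
    comp <- reconstruct3d(seed, remaining)
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  if (is.null(best)) mask else best
}

#' Otsu threshold of a set of intensities
#'
#' Maximal between-class-variance split of a sample of intensities in
#' `[0, 1]`, computed on a fixed 256-bin histogram. Used by the pipeline's
#' automatic enamel threshold and for the global dentine/pulp split.
#'
#' @param x numeric vector of intensities in `[0, 1]`.
#' @param levels number of histogram bins.
#' @return The threshold (bin upper edge) maximizing between-class variance;
#'   classification convention is `x >= threshold` for the bright class.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite intensities to threshold")
  bin <- pmin(pmax(as.integer(floor(x * levels)) + 1L, 1L), levels)
  h <- tabulate(bin, nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu <- mu1[levels]
  w2 <- 1 - w1
  bcv <- (mu * w1 - mu1)^2 / (w1 * w2)
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  k / levels  # upper edge of bin k: bright class is x >= threshold
}
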