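# Internal numeric helpers shared across modules.

# Dense 1-D Gaussian smoothing operator with truncated, renormalized kernel
# (normalized convolution at the borders). Symmetric, so it commutes with
# mirroring exactly.
gaussSmoothMatrix <- function(n, sigma) {
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  m <- exp(-d^2 / (2 * sigma^2))
  m / rowSums(m)
}

# Separable 2-D Gaussian smoothing of a matrix.
gaussSmooth <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  R <- gaussSmoothMatrix(nrow(img), sigma)
  C <- gaussSmoothMatrix(ncol(img), sigma)
  R %*% img %*% t(C)
}

# Per-channel 1st-99th percentile rescale to [0, 1] (no clipping).
normalizeChannels <- function(px) {
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  for (c in seq_len(dim(px)[3])) {
    q <- stats::quantile(px[, , c], c(0.01, 0.99), names = FALSE)
    if (q[2] > q[1]) px[, , c] <- (px[, , c] - q[1]) / (q[2] - q[1])
    else px[, , c] <- px[, , c] - q[1]
  }
  px
}

# Pad an H x W (xC) array on the bottom/right with edge replication so both
# spatial dims are multiples of `mult`. Returns list(x, H, W) with original dims.
padToMultiple <- function(x, mult) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  Hp <- ceiling(H / mult) * mult
  Wp <- ceiling(W / mult) * mult
  if (Hp == H && Wp == W) return(list(x = x, H = H, W = W))
  ri <- c(seq_len(H), rep(H, Hp - H))
  ci <- c(seq_len(W), rep(W, Wp - W))
  x <- if (length(d) == 2) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
  list(x = x, H = H, W = W)
}

# Bilinear sampling of matrix `m` at fractional coordinates (y, x), 1-based.
# Coordinates are clamped to the canvas.
bilinearSample <- function(m, y, x) {
  H <- nrow(m); W <- ncol(m)
  y <- pmin(pmax(y, 1), H)
  x <- pmin(pmax(x, 1), W)
  y0 <- pmin(floor(y), H - 1L); x0 <- pmin(floor(x), W - 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- (x0 - 1) * H + y0
  v00 <- m[i00];         v10 <- m[i00 + 1]
  v01 <- m[i00 + H];     v11 <- m[i00 + H + 1]
  (1 - fy) * (1 - fx) * v00 + fy * (1 - fx) * v10 +
    (1 - fy) * fx * v01 + fy * fx * v11
}

# Relabel a label matrix to consecutive ids 1..k preserving id order.
relabelConsecutive <- function(labels) {
  ids <- roiIds(labels)
  if (!length(ids)) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- match(labels[labels > 0], ids)
  storage.mode(out) <- "integer"
  out
}

# Centroids (row, col means) of every ROI; rows named by id.
roiCentroids <- function(labels) {
  ids <- roiIds(labels)
  if (!length(ids)) return(matrix(numeric(), 0, 2))
  idx <- which(labels > 0)
  rr <- (idx - 1) %% nrow(labels) + 1
  cc <- (idx - 1) %/% nrow(labels) + 1
  f <- factor(labels[idx], levels = ids)
  cbind(tapply(rr, f, mean), tapply(cc, f, mean))
}

# Pixel areas per ROI, named by id.
roiAreas <- function(labels) {
  ids <- roiIds(labels)
  tab <- tabulate(labels[labels > 0], nbins = max(ids, 0L))
  stats::setNames(tab[ids], ids)
}

# Derive an independent 32-bit sub-seed from a base seed and a stream index.
subSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12347) %%
               2147483629)
}
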