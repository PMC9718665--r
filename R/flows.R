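#' Quality-control configuration for mask reconstruction
#'
#' @param flowErrorThreshold dimensionless flow-error rejection threshold
#'   (default 0.4): reconstructed ROI whose predicted flows disagree with the
#'   flows recomputed from the ROI itself by more than this mean squared
#'   difference are discarded.
#' @param minRoiSize minimum ROI area in pixels (default 15).
#' @return list of class `QcConfig`.
#' @export
qcConfig <- function(flowErrorThreshold = 0.4, minRoiSize = 15) {
  stopifnot(flowErrorThreshold > 0, minRoiSize >= 0)
  structure(list(flowErrorThreshold = flowErrorThreshold,
                 minRoiSize = minRoiSize), class = "QcConfig")
}

# Median-coordinate ROI centre snapped to the nearest in-ROI pixel
# (robust for crescents). Returns c(row, col).
roiCenter <- function(rr, cc) {
  my <- stats::median(rr); mx <- stats::median(cc)
  i <- which.min((rr - my)^2 + (cc - mx)^2)
  c(rr[i], cc[i])
}

#' Convert an instance label map to flow-field training targets
#'
#' For every ROI a scalar heat-diffusion field is computed from the ROI's
#' centre pixel (per-axis median coordinate snapped to the nearest in-ROI
#' pixel); the flows are the unit-normalized spatial gradient of that field,
#' so they point toward the centre from everywhere inside the ROI. Background
#' flows are zero and `insideProb` is the 0/1 in-ROI indicator.
#'
#' @param labels integer label matrix or [LabeledImage-class].
#' @return a [FlowTarget-class].
#' @seealso [followFlows()] for the inverse operation.
#' @export
masksToFlows <- function(labels) {
  if (is(labels, "LabeledImage")) labels <- labelMap(labels)
  H <- nrow(labels); W <- ncol(labels)
  fy <- matrix(0, H, W); fx <- matrix(0, H, W)
  ids <- roiIds(labels)
  for (id in ids) {
    idx <- which(labels == id)
    rr <- (idx - 1L) %% H + 1L
    cc <- (idx - 1L) %/% H + 1L
    r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
    bh <- r1 - r0 + 3L; bw <- c1 - c0 + 3L   # 1-px zero pad around the bbox
    mask <- matrix(FALSE, bh, bw)
    mask[cbind(rr - r0 + 2L, cc - c0 + 2L)] <- TRUE
    ctr <- roiCenter(rr, cc)
    niter <- 2L * max(bh, bw)
    Tf <- .diffuseMask(mask, ctr[1] - r0 + 1L, ctr[2] - c0 + 1L, niter)
    inb <- cbind(rr - r0 + 2L, cc - c0 + 2L)
    gy <- (Tf[inb + cbind(rep(1L, nrow(inb)), 0L)] -
           Tf[inb - cbind(rep(1L, nrow(inb)), 0L)]) / 2
    gx <- (Tf[inb + cbind(rep(0L, nrow(inb)), 1L)] -
           Tf[inb - cbind(rep(0L, nrow(inb)), 1L)]) / 2
    mag <- sqrt(gy^2 + gx^2)
    # relative floor: numerically-zero gradients (e.g. the symmetric centre
    # pixel) must not be blown up to unit vectors
    nz <- mag > 1e-9 * max(mag)
    gy[nz] <- gy[nz] / mag[nz]; gx[nz] <- gx[nz] / mag[nz]
    gy[!nz] <- 0; gx[!nz] <- 0
    fy[idx] <- gy; fx[idx] <- gx
  }
  new("FlowTarget", flowY = fy, flowX = fx,
      insideProb = matrix(as.numeric(labels > 0), H, W))
}

#' Reconstruct instance masks by following a flow field
#'
#' Every pixel whose inside-cell probability exceeds `probThreshold` is
#' advected along the flow field with fixed-step Euler integration (bilinear
#' flow interpolation, positions clamped to the canvas). Trajectories that
#' converge to the same sink (within `mergeRadius` pixels) form one ROI; ROI
#' smaller than `qc$minRoiSize` are discarded.
#'
#' @param flows a [FlowTarget-class] or a list with `flowY`, `flowX`,
#'   `insideProb` matrices (predicted maps need not be unit-norm).
#' @param probThreshold inside-probability threshold (default 0.5).
#' @param nSteps number of Euler steps (default 200).
#' @param stepSize Euler step in pixels (default 1).
#' @param mergeRadius sink-merge radius in pixels (default 2.5).
#' @param qc a [qcConfig()]; only `minRoiSize` is used here (the flow-error
#'   filter is applied by [segmentImage()]).
#' @return integer instance label map with consecutive ids.
#' @export
followFlows <- function(flows, probThreshold = 0.5, nSteps = 200,
                        stepSize = 1, mergeRadius = 2.5, qc = qcConfig()) {
  fy <- if (is(flows, "FlowTarget")) flows@flowY else flows$flowY
  fx <- if (is(flows, "FlowTarget")) flows@flowX else flows$flowX
  pr <- if (is(flows, "FlowTarget")) flows@insideProb else flows$insideProb
  stopifnot(all(dim(fy) == dim(fx)), all(dim(fy) == dim(pr)))
  if (!all(is.finite(fy)) || !all(is.finite(fx)))
    stop("non-finite flow values")
  H <- nrow(fy); W <- ncol(fy)
  out <- matrix(0L, H, W)
  idx <- which(pr > probThreshold)
  if (!length(idx)) return(out)
  y <- as.numeric((idx - 1L) %% H + 1L)
  x <- as.numeric((idx - 1L) %/% H + 1L)
  for (s in seq_len(nSteps)) {
    vy <- bilinearSample(fy, y, x)
    vx <- bilinearSample(fx, y, x)
    y <- pmin(pmax(y + stepSize * vy, 1), H)
    x <- pmin(pmax(x + stepSize * vx, 1), W)
  }
  ry <- pmin(pmax(round(y), 1), H)
  rx <- pmin(pmax(round(x), 1), W)
  occ <- matrix(0, H, W)
  occ[cbind(ry, rx)] <- 1
  brush <- EBImage::makeBrush(2L * floor(mergeRadius) + 1L, shape = "disc")
  comp <- EBImage::bwlabel(EBImage::dilate(occ, brush))
  out[idx] <- as.integer(comp[cbind(ry, rx)])
  sizes <- roiAreas(out)
  small <- as.integer(names(sizes)[sizes < qc$minRoiSize])
  if (length(small)) out[out %in% small] <- 0L
  relabelConsecutive(out)
}

#' Per-ROI flow error (quality-control score)
#'
#' For each ROI of a reconstructed map, the mean squared difference (over
#' pixels and the two vector components) between the predicted flows inside
#' the ROI and the flows recomputed from the reconstructed ROI itself via
#' [masksToFlows()]. Self-consistent flows score near 0; unrelated flows
#' score near 1, so the default rejection threshold 0.4 separates them.
#'
#' @param flows predicted flows ([FlowTarget-class] or list with `flowY`,
#'   `flowX`).
#' @param reconstructed integer label map produced from those flows.
#' @return named numeric vector of errors, one per ROI id.
#' @export
flowError <- function(flows, reconstructed) {
  fy <- if (is(flows, "FlowTarget")) flows@flowY else flows$flowY
  fx <- if (is(flows, "FlowTarget")) flows@flowX else flows$flowX
  stopifnot(all(dim(fy) == dim(reconstructed)))
  ids <- roiIds(reconstructed)
  if (!length(ids)) return(stats::setNames(numeric(0), character(0)))
  ref <- masksToFlows(reconstructed)
  errs <- vapply(ids, function(id) {
    ix <- which(reconstructed == id)
    mean(((fy[ix] - ref@flowY[ix])^2 + (fx[ix] - ref@flowX[ix])^2) / 2)
  }, 0)
  stats::setNames(errs, ids)
}

#' Mean equivalent ROI diameter
#'
#' The equivalent diameter of a ROI is `2 * sqrt(area / pi)`. For a single
#' label map the mean over its ROI is returned; for a list of images the
#' dataset-level diameter is the mean of the per-image means.
#'
#' @param x integer label matrix, [LabeledImage-class], or list of either.
#' @return diameter in pixels.
#' @export
estimateDiameter <- function(x) {
  if (is.list(x) && !is(x, "LabeledImage"))
    return(mean(vapply(x, estimateDiameter, 0)))
  if (is(x, "LabeledImage")) x <- labelMap(x)
  areas <- roiAreas(x)
  if (!length(areas)) stop("cannot estimate a diameter from an empty map")
  mean(2 * sqrt(areas / pi))
}

#' Rescale an image so its objects match the model's native diameter
#'
#' Scales pixels (bilinear) and labels (nearest-neighbour) by
#' `modelDiameter / targetDiameter`. Segmenting at the model's native object
#' size and mapping masks back restores the original shape.
#'
#' @param img a [LabeledImage-class].
#' @param targetDiameter estimated object diameter of `img` in pixels.
#' @param modelDiameter native object diameter of the model in pixels.
#' @return rescaled `LabeledImage`.
#' @export
resizeForDiameter <- function(img, targetDiameter, modelDiameter) {
  stopifnot(targetDiameter > 0, modelDiameter > 0)
  f <- modelDiameter / targetDiameter
  if (f < 1 / 16 || f > 16)
    stop("rescaling factor ", signif(f, 3), " outside [1/16, 16]")
  px <- pixels(img); lb <- labelMap(img)
  H2 <- max(2L, round(dim(px)[1] * f))
  W2 <- max(2L, round(dim(px)[2] * f))
  px2 <- array(0, c(H2, W2, dim(px)[3]))
  for (c in seq_len(dim(px)[3]))
    px2[, , c] <- EBImage::resize(px[, , c], w = H2, h = W2,
                                  filter = "bilinear")
  lb2 <- EBImage::resize(lb, w = H2, h = W2, filter = "none")
  storage.mode(lb2) <- "integer"
  LabeledImage(px2, lb2, channelRoles(img), img@pixelSize, img@sourceId)
}

# Nearest-neighbour resize of a label matrix to explicit dims (used to map
# masks back to the original frame after diameter rescaling).
resizeLabelsTo <- function(labels, H, W) {
  out <- EBImage::resize(labels, w = H, h = W, filter = "none")
  storage.mode(out) <- "integer"
  out
}
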