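#' Scene configuration for the synthetic cell generator
#'
#' Describes one synthetic microscopy scene: canvas size, cell count and
#' geometry, texture, optional nucleus channel with orphan nuclei (nuclei
#' whose cell has no cytoplasmic signal), crowding limit and noise level.
#' The same seed always yields a bit-identical scene.
#'
#' @param canvas `c(H, W)` in pixels.
#' @param nCells number of cytoplasmic cells to place.
#' @param diameterMean,diameterSd cell equivalent-diameter distribution (px);
#'   diameters are truncated above 3 px.
#' @param shape `"disk"`, `"ellipse"` or `"blobby"` (low-frequency polygonal
#'   perturbation of a disk).
#' @param texture `"flat"`, `"granular"` (multiplicative speckle) or
#'   `"membrane"` (bright rim).
#' @param nucleusChannel add a second channel with nuclear signal.
#' @param orphanFrac fraction (of `nCells`) of extra nucleus-only cells
#'   rendered in the nucleus channel with no cytoplasmic signal.
#' @param crowding maximum packing fraction; placement stops at this density
#'   and values above 0.9 are rejected as impossible packing.
#' @param noiseSd additive Gaussian pixel noise s.d. (intensity units).
#' @param seed integer RNG seed.
#' @return list of class `SceneConfig`.
#' @export
sceneConfig <- function(canvas = c(64, 64), nCells = 12, diameterMean = 10,
                        diameterSd = 1.5, shape = c("disk", "ellipse", "blobby"),
                        texture = c("flat", "granular", "membrane"),
                        nucleusChannel = FALSE, orphanFrac = 0,
                        crowding = 0.5, noiseSd = 0.05, seed = 0L) {
  shape <- match.arg(shape); texture <- match.arg(texture)
  stopifnot(nCells >= 0, diameterMean > 2, orphanFrac >= 0, orphanFrac <= 1,
            noiseSd >= 0, crowding > 0)
  structure(list(canvas = as.integer(canvas), nCells = as.integer(nCells),
                 diameterMean = diameterMean, diameterSd = diameterSd,
                 shape = shape, texture = texture,
                 nucleusChannel = nucleusChannel, orphanFrac = orphanFrac,
                 crowding = crowding, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "SceneConfig")
}

# Rasterize one cell footprint; returns linear pixel indices on the canvas.
rasterizeCell <- function(H, W, cy, cx, r, shape) {
  r0 <- max(1L, floor(cy - r - 2)); r1 <- min(H, ceiling(cy + r + 2))
  c0 <- max(1L, floor(cx - r - 2)); c1 <- min(W, ceiling(cx + r + 2))
  yy <- r0:r1; xx <- c0:c1
  dy <- outer(yy - cy, rep(1, length(xx)))
  dx <- outer(rep(1, length(yy)), xx - cx)
  inside <- switch(shape,
    disk = dy^2 + dx^2 <= r^2,
    ellipse = {
      th <- stats::runif(1, 0, pi); ecc <- stats::runif(1, 0.55, 0.85)
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      (u / r)^2 + (v / (r * ecc))^2 <= 1
    },
    blobby = {
      ph <- stats::runif(2, 0, 2 * pi)
      ang <- atan2(dx, dy)
      rad <- r * (1 + 0.22 * sin(3 * ang + ph[1]) + 0.12 * sin(5 * ang + ph[2]))
      dy^2 + dx^2 <= rad^2
    })
  w <- which(inside, arr.ind = TRUE)
  if (!nrow(w)) return(integer(0))
  (xx[w[, 2]] - 1L) * H + yy[w[, 1]]
}

#' Generate a synthetic scene with its biological-truth label map
#'
#' Cells are placed by rejection sampling with a hard no-overlap constraint,
#' then rendered with the configured texture into a cytoplasm channel (and
#' optionally a nucleus channel including orphan nuclei). The returned
#' `roiData` records, per ROI, whether it is an orphan nucleus, its centroid
#' and its mean cytoplasmic intensity; [applyStyle()] consumes these.
#'
#' @param cfg a [sceneConfig()].
#' @return a [LabeledImage-class] whose labels are the biological truth.
#' @export
generateScene <- function(cfg) {
  stopifnot(inherits(cfg, "SceneConfig"))
  if (cfg$crowding > 0.9)
    stop("impossible packing: crowding target ", cfg$crowding, " > 0.9")
  set.seed(cfg$seed)
  H <- cfg$canvas[1]; W <- cfg$canvas[2]
  labels <- matrix(0L, H, W)
  nucleus <- matrix(0, H, W)
  cyto <- matrix(0, H, W)
  nOrphan <- round(cfg$orphanFrac * cfg$nCells)
  info <- list()
  id <- 0L
  placeOne <- function(r, orphan) {
    for (try in 1:200) {
      cy <- stats::runif(1, r + 1, H - r)
      cx <- stats::runif(1, r + 1, W - r)
      px <- rasterizeCell(H, W, cy, cx, r, if (orphan) "disk" else cfg$shape)
      if (length(px) && all(labels[px] == 0L)) {
        return(list(px = px, cy = cy, cx = cx))
      }
    }
    NULL
  }
  total <- cfg$nCells + nOrphan
  kinds <- c(rep(FALSE, cfg$nCells), rep(TRUE, nOrphan))
  for (k in seq_len(total)) {
    if (sum(labels > 0) / (H * W) >= cfg$crowding) break
    orphan <- kinds[k]
    d <- max(3.2, stats::rnorm(1, cfg$diameterMean, cfg$diameterSd))
    r <- if (orphan) 0.38 * d else d / 2
    hit <- placeOne(r, orphan)
    if (is.null(hit)) next
    id <- id + 1L
    labels[hit$px] <- id
    base <- stats::runif(1, 0.5, 0.75)
    if (orphan) {
      nucleus[hit$px] <- stats::runif(1, 0.7, 0.9)
    } else {
      cyto[hit$px] <- base
      if (cfg$nucleusChannel) {
        npx <- rasterizeCell(H, W, hit$cy, hit$cx, 0.38 * d, "disk")
        npx <- npx[labels[npx] == id]
        nucleus[npx] <- stats::runif(1, 0.7, 0.9)
      }
    }
    info[[length(info) + 1]] <- data.frame(
      id = id, orphan = orphan, cy = hit$cy, cx = hit$cx,
      intensity = if (orphan) 0 else base)
  }
  # texture on the cytoplasm channel
  if (cfg$texture == "granular") {
    # image-wide multiplicative speckle (cells and background), the way
    # granular contrast pervades a phase-contrast field of view
    speck <- matrix(stats::runif(H * W, 0.55, 1.45), H, W)
    cyto <- (cyto + 0.1) * speck - 0.1
  } else if (cfg$texture == "membrane") {
    inner <- EBImage::erode(matrix(as.numeric(labels > 0), H, W),
                            EBImage::makeBrush(3, "diamond"))
    rim <- (labels > 0) & (inner == 0)
    cyto[rim] <- cyto[rim] * 1.6
    cyto[labels > 0 & !rim] <- cyto[labels > 0 & !rim] * 0.7
  }
  cyto <- cyto + 0.1 + matrix(stats::rnorm(H * W, 0, cfg$noiseSd), H, W)
  px <- if (cfg$nucleusChannel) {
    nucleus <- nucleus + 0.05 + matrix(stats::rnorm(H * W, 0, cfg$noiseSd), H, W)
    array(c(cyto, nucleus), c(H, W, 2))
  } else array(cyto, c(H, W, 1))
  roles <- if (cfg$nucleusChannel) c("cytoplasm", "nucleus") else "cytoplasm"
  rd <- if (length(info)) do.call(rbind, info) else
    data.frame(id = integer(), orphan = logical(), cy = numeric(),
               cx = numeric(), intensity = numeric())
  LabeledImage(px, labels, roles, sourceId = sprintf("scene%d", cfg$seed),
               roiData = rd)
}

#' Annotation style for synthetic ground truth
#'
#' Emulates systematic differences between annotators: whether orphan nuclei
#' are labeled, a bias of drawn outlines outward/inward of the true boundary,
#' and skipping of ROI in dense neighbourhoods or of dim ROI.
#'
#' @param labelOrphanNuclei label nuclei that have no cytoplasm (default TRUE).
#' @param boundaryBias signed outline bias in pixels, in `[-3, 3]`; positive
#'   dilates (stopping at collisions), negative erodes.
#' @param skipDense drop ROI with more than `denseThreshold` neighbouring
#'   centroids within 2.5 mean diameters.
#' @param denseThreshold neighbour count threshold (default 3).
#' @param skipDim drop ROI whose mean intensity falls below the
#'   `dimPercentile` quantile of per-ROI intensities.
#' @param dimPercentile intensity percentile in `[0, 1]` (default 0.1).
#' @return list of class `AnnotationStyle`.
#' @export
annotationStyle <- function(labelOrphanNuclei = TRUE, boundaryBias = 0,
                            skipDense = FALSE, denseThreshold = 3,
                            skipDim = FALSE, dimPercentile = 0.1) {
  stopifnot(boundaryBias >= -3, boundaryBias <= 3)
  structure(list(labelOrphanNuclei = labelOrphanNuclei,
                 boundaryBias = as.integer(round(boundaryBias)),
                 skipDense = skipDense, denseThreshold = denseThreshold,
                 skipDim = skipDim, dimPercentile = dimPercentile),
            class = "AnnotationStyle")
}

# One simultaneous 1-px dilation of all ROI into background; growth stops at
# collisions (a background pixel adjacent to two different labels stays 0).
dilateLabelsOnce <- function(L) {
  H <- nrow(L); W <- ncol(L)
  lo <- matrix(Inf, H, W); hi <- matrix(-Inf, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- (1 + max(0, dy)):(H + min(0, dy))
    xs <- (1 + max(0, dx)):(W + min(0, dx))
    sh <- matrix(0L, H, W)
    sh[ys - dy, xs - dx] <- L[ys, xs]
    pos <- sh > 0
    lo[pos] <- pmin(lo[pos], sh[pos])
    hi[pos] <- pmax(hi[pos], sh[pos])
  }
  grow <- L == 0 & is.finite(lo) & lo == hi
  L[grow] <- as.integer(lo[grow])
  L
}

# One 1-px erosion of every ROI; ROI that would vanish are left unchanged.
erodeLabelsOnce <- function(L) {
  H <- nrow(L); W <- ncol(L)
  boundary <- matrix(FALSE, H, W)
  for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    dy <- dd[1]; dx <- dd[2]
    ys <- (1 + max(0, dy)):(H + min(0, dy))
    xs <- (1 + max(0, dx)):(W + min(0, dx))
    sh <- matrix(-1L, H, W)
    sh[ys - dy, xs - dx] <- L[ys, xs]
    boundary <- boundary | (L > 0 & sh != L)
  }
  cand <- L > 0 & boundary
  keepIds <- setdiff(roiIds(L), roiIds(L * (!cand)))  # ROI that would vanish
  cand[L %in% keepIds] <- FALSE
  L[cand] <- 0L
  L
}

#' Apply an annotation style to a biological-truth label map
#'
#' Transforms the truth labels the way a particular annotator would: orphan
#' nuclei are dropped unless the style labels them, outlines are dilated or
#' eroded by `boundaryBias` pixels (dilation stops at collisions so distinct
#' ROI never merge), and dense-neighbourhood or dim ROI are skipped when the
#' corresponding flags are set. No ROI absent from the truth is ever
#' invented.
#'
#' @param truth a [LabeledImage-class] from [generateScene()].
#' @param style an [annotationStyle()].
#' @return a `LabeledImage` with the same pixels and style-transformed labels.
#' @export
applyStyle <- function(truth, style) {
  stopifnot(inherits(style, "AnnotationStyle"))
  L <- labelMap(truth)
  rd <- roiData(truth)
  drop <- integer(0)
  if (!style$labelOrphanNuclei && nrow(rd))
    drop <- c(drop, rd$id[rd$orphan])
  if (style$skipDense && nrow(rd) > 1) {
    radius <- 2.5 * estimateDiameter(L)
    d2 <- as.matrix(stats::dist(rd[, c("cy", "cx")]))
    nNear <- rowSums(d2 < radius) - 1
    drop <- c(drop, rd$id[nNear > style$denseThreshold])
  }
  if (style$skipDim && nrow(rd)) {
    cyto <- pixels(truth)[, , 1]
    ids <- rd$id
    mi <- vapply(ids, function(i) mean(cyto[L == i]), 0)
    thr <- stats::quantile(mi, style$dimPercentile, names = FALSE)
    drop <- c(drop, ids[mi < thr])
  }
  drop <- unique(drop)
  if (length(drop)) L[L %in% drop] <- 0L
  b <- style$boundaryBias
  if (b > 0) for (i in seq_len(b)) L <- dilateLabelsOnce(L)
  if (b < 0) for (i in seq_len(-b)) L <- erodeLabelsOnce(L)
  rd2 <- rd[!(rd$id %in% drop), , drop = FALSE]
  LabeledImage(pixels(truth), L, channelRoles(truth), truth@pixelSize,
               paste0(truth@sourceId, "_styled"), rd2)
}

#' Two-class benchmark with conflicting annotation styles
#'
#' Builds two image classes with a learnable appearance cue (flat vs granular
#' cytoplasmic texture) and conflicting styles: class A annotators label
#' orphan nuclei, class B annotators do not. This is the desk-scale analog of
#' the style-conflict experiments motivating specialist model ensembles.
#'
#' @param seed integer seed; the benchmark is fully reproducible.
#' @param nTrainPerClass,nTestPerClass images per class and split.
#' @param canvas canvas size, default 64 x 64.
#' @param nCells cells per scene (default 10).
#' @param nStylePerClass additional scenes per class returned in
#'   `styleOnly` — cheap extra material for style clustering, mirroring
#'   protocols that cluster a much larger corpus than they train on.
#' @return list with `train`, `test` (lists of [LabeledImage-class] whose
#'   labels follow the class's style), `trainClass`, `testClass` (integer
#'   class ids 1/2), `styleOnly`/`styleOnlyClass`, and the two `styles`.
#' @export
makeTwoStyleBenchmark <- function(seed, nTrainPerClass = 6, nTestPerClass = 4,
                                  canvas = c(64, 64), nCells = 10,
                                  nStylePerClass = 0) {
  styles <- list(annotationStyle(labelOrphanNuclei = TRUE),
                 annotationStyle(labelOrphanNuclei = FALSE))
  textures <- c("flat", "granular")
  mk <- function(class, k, split) {
    cfg <- sceneConfig(canvas = canvas, nCells = nCells, diameterMean = 10,
                       diameterSd = 1.2, shape = "disk",
                       texture = textures[class], nucleusChannel = TRUE,
                       orphanFrac = 0.3, noiseSd = 0.04,
                       seed = subSeed(seed, class * 1000L + k +
                                        (split == "test") * 500L))
    truth <- generateScene(cfg)
    img <- applyStyle(truth, styles[[class]])
    img@sourceId <- sprintf("class%s_%s%d", LETTERS[class], split, k)
    img
  }
  train <- list(); trainClass <- integer(0)
  test <- list(); testClass <- integer(0)
  for (cl in 1:2) {
    for (k in seq_len(nTrainPerClass)) {
      train[[length(train) + 1]] <- mk(cl, k, "train")
      trainClass <- c(trainClass, cl)
    }
    for (k in seq_len(nTestPerClass)) {
      test[[length(test) + 1]] <- mk(cl, k, "test")
      testClass <- c(testClass, cl)
    }
  }
  styleOnly <- list(); styleOnlyClass <- integer(0)
  for (cl in 1:2) {
    for (k in seq_len(nStylePerClass)) {
      styleOnly[[length(styleOnly) + 1]] <- mk(cl, 700L + k, "style")
      styleOnlyClass <- c(styleOnlyClass, cl)
    }
  }
  list(train = train, trainClass = trainClass, test = test,
       testClass = testClass, styleOnly = styleOnly,
       styleOnlyClass = styleOnlyClass, styles = styles, seed = seed)
}
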