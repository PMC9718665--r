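#' IoU matrix between two instance maps
#'
#' Entry (i, j) is `|P_i intersect T_j| / |P_i union T_j|` for predicted ROI
#' `i` and truth ROI `j`; only overlapping pairs are nonzero.
#'
#' @param predicted,truth integer label matrices on the same canvas (or
#'   [LabeledImage-class]).
#' @return numeric matrix with predicted ids as rownames, truth ids as
#'   colnames.
#' @export
iouMatrix <- function(predicted, truth) {
  if (is(predicted, "LabeledImage")) predicted <- labelMap(predicted)
  if (is(truth, "LabeledImage")) truth <- labelMap(truth)
  stopifnot(all(dim(predicted) == dim(truth)))
  pid <- roiIds(predicted); tid <- roiIds(truth)
  m <- matrix(0, length(pid), length(tid),
              dimnames = list(pid, tid))
  if (!length(pid) || !length(tid)) return(m)
  joint <- which(predicted > 0 & truth > 0)
  if (length(joint)) {
    inter <- table(factor(predicted[joint], levels = pid),
                   factor(truth[joint], levels = tid))
    pa <- roiAreas(predicted); ta <- roiAreas(truth)
    un <- outer(pa[as.character(pid)], ta[as.character(tid)], "+") - inter
    m[] <- as.numeric(inter) / as.numeric(un)
  }
  m
}

#' One-to-one mask matching at an IoU threshold
#'
#' Finds the one-to-one matching that maximizes total matched IoU over pairs
#' with IoU at or above the threshold (optimal assignment; a greedy
#' highest-IoU-first mode is available). Matched pairs are the true
#' positives; unmatched predictions are false positives and unmatched truth
#' ROI false negatives.
#'
#' @param ious IoU matrix from [iouMatrix()].
#' @param threshold IoU threshold in (0, 1).
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return list of class `MatchResult` with `pairs` (data.frame `pred`,
#'   `truth`, `iou`), `tp`, `fp`, `fn`, `threshold`.
#' @export
matchMasks <- function(ious, threshold, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(threshold > 0, threshold < 1)
  np <- nrow(ious); nt <- ncol(ious)
  profit <- ious
  profit[profit < threshold] <- 0
  pairs <- data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  if (np > 0 && nt > 0 && any(profit > 0)) {
    if (method == "optimal") {
      n <- max(np, nt)
      cost <- matrix(max(profit), n, n)
      cost[seq_len(np), seq_len(nt)] <- max(profit) - profit
      asg <- .hungarian(cost)
      for (i in seq_len(np)) {
        j <- asg[i]
        if (j <= nt && profit[i, j] > 0)
          pairs <- rbind(pairs, data.frame(
            pred = as.integer(rownames(ious)[i]),
            truth = as.integer(colnames(ious)[j]),
            iou = ious[i, j]))
      }
    } else {
      cand <- which(profit > 0, arr.ind = TRUE)
      ord <- order(profit[cand], -cand[, 1], -cand[, 2], decreasing = TRUE)
      usedP <- logical(np); usedT <- logical(nt)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (usedP[i] || usedT[j]) next
        usedP[i] <- TRUE; usedT[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          pred = as.integer(rownames(ious)[i]),
          truth = as.integer(colnames(ious)[j]),
          iou = ious[i, j]))
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(pairs = pairs, tp = tp, fp = np - tp, fn = nt - tp,
                 threshold = threshold), class = "MatchResult")
}

# AP for one image pair at several thresholds.
apSingle <- function(predicted, truth, thresholds) {
  if (is(predicted, "LabeledImage")) predicted <- labelMap(predicted)
  if (is(truth, "LabeledImage")) truth <- labelMap(truth)
  np <- roiCount(predicted); nt <- roiCount(truth)
  if (np == 0 && nt == 0) return(rep(1, length(thresholds)))
  if (np == 0 || nt == 0) return(rep(0, length(thresholds)))
  ious <- iouMatrix(predicted, truth)
  vapply(thresholds, function(th) {
    m <- matchMasks(ious, th)
    m$tp / (m$tp + m$fp + m$fn)
  }, 0)
}

#' Average precision between predicted and ground-truth masks
#'
#' The dataset-matching form of average precision:
#' `AP = TP / (TP + FP + FN)` after one-to-one IoU matching at each
#' threshold, averaged (unweighted) over images. An image with empty truth
#' and empty prediction scores 1; empty truth with predictions scores 0.
#'
#' @param predicted,truth single label matrices/[LabeledImage-class], or
#'   parallel lists of them.
#' @param thresholds ascending IoU thresholds (default `seq(0.5, 0.9, 0.05)`).
#' @return list of class `ApReport`: `thresholds`, `perImage` (image x
#'   threshold matrix) and `meanAp` (named vector).
#' @export
averagePrecision <- function(predicted, truth,
                             thresholds = seq(0.5, 0.9, by = 0.05)) {
  stopifnot(!is.unsorted(thresholds))
  if (!is.list(predicted) || is(predicted, "LabeledImage")) {
    predicted <- list(predicted); truth <- list(truth)
  }
  stopifnot(length(predicted) == length(truth))
  per <- vapply(seq_along(predicted), function(i)
    apSingle(predicted[[i]], truth[[i]], thresholds),
    numeric(length(thresholds)))
  per <- matrix(per, nrow = length(thresholds))  # thresholds x images
  per <- t(per)
  meanAp <- colMeans(per)
  names(meanAp) <- paste0("AP@", format(thresholds))
  structure(list(thresholds = thresholds, perImage = per, meanAp = meanAp),
            class = "ApReport")
}

#' Performance as a function of training-set size
#'
#' For each requested subset size, draws `nReplicates` random subsets of the
#' training pool (fractional sizes 0.25/0.5 use quarter tiles of one image),
#' trains a model on each via `trainFn`, evaluates AP on the test set, and
#' reports the mean and s.e.m. over replicates together with the number of
#' training ROI actually used.
#'
#' @param trainPool list of [LabeledImage-class] training images.
#' @param testSet list of test images with truth labels.
#' @param sizes numeric sizes; values < 1 denote fractions of one image in
#'   quarters (0.25, 0.5), integers denote image counts.
#' @param trainFn function(images, seed) returning a checkpoint.
#' @param nReplicates replicates per size (default 5).
#' @param threshold IoU threshold for the reported AP (default 0.5).
#' @param seed base seed.
#' @return data.frame with columns `size`, `nTrainRoi`, `meanAp`, `sem`.
#' @export
apVsTrainingSize <- function(trainPool, testSet, sizes, trainFn,
                             nReplicates = 5, threshold = 0.5, seed = 0L) {
  rows <- list()
  for (s in sizes) {
    aps <- numeric(nReplicates); rois <- numeric(nReplicates)
    for (r in seq_len(nReplicates)) {
      set.seed(subSeed(seed, 1000L * which(sizes == s)[1] + r))
      if (s < 1) {
        nTiles <- round(4 * s)
        if (nTiles < 1) stop("size ", s, " smaller than a quarter image")
        src <- trainPool[[sample.int(length(trainPool), 1)]]
        tiles <- splitQuarters(src)
        subset <- tiles[sample.int(4, nTiles)]
      } else {
        if (s > length(trainPool)) stop("size ", s, " exceeds the pool")
        subset <- trainPool[sample.int(length(trainPool), s)]
      }
      ck <- trainFn(subset, subSeed(seed, 77L * r))
      pred <- lapply(testSet, function(im) segmentImage(ck, im)$labels)
      aps[r] <- averagePrecision(pred, lapply(testSet, labelMap),
                                 threshold)$meanAp[1]
      rois[r] <- sum(vapply(subset, roiCount, 0L))
    }
    rows[[length(rows) + 1]] <- data.frame(
      size = s, nTrainRoi = mean(rois), meanAp = mean(aps),
      sem = stats::sd(aps) / sqrt(nReplicates))
  }
  do.call(rbind, rows)
}

#' Within-annotator agreement bound
#'
#' The AP between two annotation passes of the same images, where the second
#' pass was performed on mirrored copies (to reduce memory effects) and must
#' be mirrored back before comparison. This is an upper bound on achievable
#' model performance.
#'
#' @param truthA list of [LabeledImage-class] (or label matrices): first pass.
#' @param truthB second pass, annotated on mirrored images.
#' @param thresholds IoU thresholds (default 0.5).
#' @param mirrored is `truthB` still in the mirrored frame? (default TRUE)
#' @return `ApReport` between the two annotation sets.
#' @export
withinAnnotatorBound <- function(truthA, truthB, thresholds = 0.5,
                                 mirrored = TRUE) {
  if (!is.list(truthA) || is(truthA, "LabeledImage")) {
    truthA <- list(truthA); truthB <- list(truthB)
  }
  la <- lapply(truthA, function(x)
    if (is(x, "LabeledImage")) labelMap(x) else x)
  lb <- lapply(truthB, function(x)
    if (is(x, "LabeledImage")) labelMap(x) else x)
  if (mirrored)
    lb <- lapply(lb, function(m) m[nrow(m):1, ncol(m):1, drop = FALSE])
  for (i in seq_along(la))
    if (!all(dim(la[[i]]) == dim(lb[[i]])))
      stop("canvas mismatch after un-mirroring (image ", i, ")")
  averagePrecision(lb, la, thresholds)
}
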