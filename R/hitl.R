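#' Human-in-the-loop configuration
#'
#' @param acceptIou IoU threshold above which a predicted ROI is accepted by
#'   the simulated annotator (default 0.5, aligned with the headline AP
#'   threshold).
#' @param rounds number of annotation rounds (defaults to the number of
#'   training images).
#' @param init `"scratch"` or a pretrained checkpoint used to (re-)initialize
#'   every retraining round.
#' @param trainCfg retraining schedule; defaults to the online schedule
#'   (100 epochs, no annealing).
#' @param netCfg network configuration for scratch initialization.
#' @param warmStart if TRUE, retrain from the previous round's weights
#'   instead of re-initializing from `init` each round (default FALSE).
#' @param seed RNG seed.
#' @return list of class `HitlConfig`.
#' @export
hitlConfig <- function(acceptIou = 0.5, rounds = NULL, init = "scratch",
                       trainCfg = trainConfig("online"),
                       netCfg = netConfig(), warmStart = FALSE, seed = 0L) {
  stopifnot(acceptIou > 0, acceptIou < 1)
  structure(list(acceptIou = acceptIou, rounds = rounds, init = init,
                 trainCfg = trainCfg, netCfg = netCfg,
                 warmStart = isTRUE(warmStart), seed = as.integer(seed)),
            class = "HitlConfig")
}

#' Simulate an annotator correcting a model prediction
#'
#' Predictions are matched one-to-one to truth ROI by IoU; predictions whose
#' match reaches `acceptIou` are kept verbatim (accepted). Every truth ROI
#' that is unmatched or matched below threshold is copied from the truth
#' into the corrected map (manual), with the copied truth pixels taking
#' precedence at conflicts (the human's stroke wins). Spurious unmatched
#' predictions are dropped.
#'
#' @param predicted integer instance map from the model.
#' @param truth integer truth map on the same canvas.
#' @param acceptIou acceptance IoU threshold (default 0.5).
#' @return list with `corrected` (integer instance map) and `round`
#'   (one-row data.frame: `nPredicted`, `nAccepted`, `nManual`).
#' @export
simulateCorrection <- function(predicted, truth, acceptIou = 0.5) {
  if (is(predicted, "LabeledImage")) predicted <- labelMap(predicted)
  if (is(truth, "LabeledImage")) truth <- labelMap(truth)
  stopifnot(all(dim(predicted) == dim(truth)))
  ious <- iouMatrix(predicted, truth)
  mr <- matchMasks(ious, acceptIou)
  acceptedIds <- mr$pairs$pred
  manualIds <- setdiff(roiIds(truth), mr$pairs$truth)
  out <- matrix(0L, nrow(truth), ncol(truth))
  nid <- 0L
  for (id in acceptedIds) {
    nid <- nid + 1L
    out[predicted == id] <- nid
  }
  for (id in manualIds) {
    nid <- nid + 1L
    out[truth == id] <- nid       # human stroke wins at conflicts
  }
  # an accepted prediction fully covered by manual strokes is gone
  surviving <- roiIds(out)
  nAccepted <- sum(seq_along(acceptedIds) %in% surviving)
  out <- relabelConsecutive(out)
  list(corrected = out,
       round = data.frame(nPredicted = roiCount(predicted),
                          nAccepted = nAccepted,
                          nManual = length(manualIds)))
}

#' Run the human-in-the-loop annotation/retraining driver
#'
#' For each round r: segment image r with the current model, simulate the
#' annotator's correction against the ground truth, then retrain on all
#' corrected images so far using the online schedule, re-initialized each
#' round from the configured starting checkpoint (set `warmStart = TRUE` in
#' the config to chain rounds instead). Logs per-round ROI accounting and
#' the test-set AP after each retraining.
#'
#' @param images ordered list of [LabeledImage-class] with truth labels.
#' @param test held-out list of `LabeledImage` with truth labels.
#' @param cfg a [hitlConfig()].
#' @param threshold IoU threshold for the reported test AP (default 0.5).
#' @return list with `rounds` (data.frame: round, imageId, nPredicted,
#'   nAccepted, nManual, testAp), `checkpoint` (final model) and
#'   `totalManualRoi`.
#' @export
runHitl <- function(images, test, cfg = hitlConfig(), threshold = 0.5) {
  stopifnot(length(images) >= 1)
  rounds <- if (is.null(cfg$rounds)) length(images) else
    min(cfg$rounds, length(images))
  current <- if (identical(cfg$init, "scratch")) buildNetwork(cfg$netCfg)
             else cfg$init
  corrected <- list()
  log <- list()
  ckpt <- current
  for (r in seq_len(rounds)) {
    img <- images[[r]]
    pred <- segmentImage(current, img)$labels
    corr <- simulateCorrection(pred, labelMap(img), cfg$acceptIou)
    corrected[[r]] <- LabeledImage(pixels(img), corr$corrected,
                                   channelRoles(img),
                                   sourceId = paste0(img@sourceId, "_corr"))
    tc <- cfg$trainCfg
    tc$seed <- subSeed(cfg$seed, r)
    initR <- if (cfg$warmStart && r > 1) ckpt else cfg$init
    ckpt <- trainModel(initR, corrected, tc, cfg$netCfg)
    current <- ckpt
    predsT <- lapply(test, function(tm) segmentImage(ckpt, tm)$labels)
    ap <- averagePrecision(predsT, lapply(test, labelMap),
                           threshold)$meanAp[1]
    log[[r]] <- cbind(data.frame(round = r, imageId = img@sourceId),
                      corr$round, data.frame(testAp = ap))
  }
  log <- do.call(rbind, log)
  list(rounds = log, checkpoint = ckpt,
       totalManualRoi = sum(log$nManual))
}

#' Offline annotation baseline
#'
#' Every image is annotated fully by hand (total manual ROI = sum of all
#' truth ROI) and a single model is trained once with the offline schedule.
#'
#' @param images list of fully annotated [LabeledImage-class].
#' @param init `"scratch"` or a pretrained checkpoint.
#' @param trainCfg an offline [trainConfig()].
#' @param netCfg network configuration.
#' @return list with `checkpoint` and `totalManualRoi`.
#' @export
offlineBaseline <- function(images, init = "scratch",
                            trainCfg = trainConfig("offline"),
                            netCfg = netConfig()) {
  ckpt <- trainModel(init, images, trainCfg, netCfg)
  list(checkpoint = ckpt,
       totalManualRoi = sum(vapply(images, roiCount, 0L)))
}
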