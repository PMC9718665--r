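# Desk-scale benchmark experiments: scaled-down synthetic analogs of the
# fine-tuning, human-in-the-loop and ensemble-vs-generalist comparisons.
# Problem sizes (48 px scenes, 2-level/8-channel nets, shortened epoch
# budgets) are chosen so each experiment runs in minutes on one CPU; the
# methods vignette discusses these choices.

deskNetConfig <- function(inChannels = 1, seed = 0L,  broadcastStyle = TRUE) {
  netConfig(nLevels = 2, baseChannels = 8, inChannels = inChannels,
            broadcastStyle = broadcastStyle, seed = seed)
}

# Source domain: clean flat disks. Target domain: noisy crowded granular
# blobs with variable sizes — hard enough that a handful of images
# underdetermines it.
sourceScene <- function(seed) {
  generateScene(sceneConfig(canvas = c(48, 48), nCells = 8, diameterMean = 9,
                            shape = "disk", texture = "flat", noiseSd = 0.05,
                            seed = seed))
}
targetScene <- function(seed) {
  generateScene(sceneConfig(canvas = c(48, 48), nCells = 12, diameterMean = 9,
                            diameterSd = 2.5, shape = "blobby",
                            texture = "membrane", noiseSd = 0.25,
                            crowding = 0.5, seed = seed))
}

#' Pretrain a small base model on the source domain
#'
#' Trains the desk-scale network on clean synthetic scenes; the result plays
#' the role of the generic pretrained model that fine-tuning and
#' human-in-the-loop experiments start from.
#'
#' @param seed base seed.
#' @param nImages source-domain training scenes (default 6).
#' @param epochs training epochs (default 80, online-style schedule).
#' @return a checkpoint.
#' @export
pretrainBaseModel <- function(seed = 1L, nImages = 6, epochs = 80) {
  imgs <- lapply(seq_len(nImages), function(k) sourceScene(subSeed(seed, k)))
  trainModel("scratch", imgs,
             trainConfig("online", epochs = epochs, tileSize = 48,
                         seed = subSeed(seed, 11L)),
             deskNetConfig(seed = subSeed(seed, 12L)))
}

#' Fine-tuning versus training from scratch
#'
#' The scaled-down transfer experiment: a model pretrained on the source
#' domain is fine-tuned on a few target-domain images and compared with a
#' model trained from scratch on exactly the same images and epoch budget.
#' Test AP\@0.5 is measured on held-out target scenes, averaged over
#' replicate seeds.
#'
#' @param seed base seed.
#' @param nSeeds replicates (default 5).
#' @param nTrainImages target-domain training images per replicate (1-4).
#' @param epochs shared training budget per model (default 20).
#' @param pretrained optional checkpoint from [pretrainBaseModel()]
#'   (computed if missing).
#' @return list with `perSeed` (data.frame seed/apFinetune/apScratch/
#'   nTrainRoi), `meanFinetune`, `meanScratch`, `meanGain`.
#' @export
fineTuneExperiment <- function(seed = 1L, nSeeds = 5, nTrainImages = 1,
                               epochs = 20, pretrained = NULL) {
  if (is.null(pretrained)) pretrained <- pretrainBaseModel(seed)
  test <- lapply(101:104, function(k) targetScene(subSeed(seed, k)))
  testL <- lapply(test, labelMap)
  ncfg <- deskNetConfig()
  rows <- lapply(seq_len(nSeeds), function(r) {
    tr <- lapply(seq_len(nTrainImages),
                 function(k) targetScene(subSeed(seed, 200L + 10L * r + k)))
    tc <- trainConfig("online", epochs = epochs, warmupEpochs = 10,
                      tileSize = 48, seed = subSeed(seed, 300L + r))
    ncfgR <- ncfg; ncfgR$seed <- subSeed(seed, 400L + r)
    ft <- trainModel(pretrained, tr, tc, ncfgR)
    sc <- trainModel("scratch", tr, tc, ncfgR)
    apF <- averagePrecision(lapply(test, function(im)
      segmentImage(ft, im)$labels), testL, 0.5)$meanAp[[1]]
    apS <- averagePrecision(lapply(test, function(im)
      segmentImage(sc, im)$labels), testL, 0.5)$meanAp[[1]]
    data.frame(seed = r, apFinetune = apF, apScratch = apS,
               nTrainRoi = sum(vapply(tr, roiCount, 0L)))
  })
  perSeed <- do.call(rbind, rows)
  list(perSeed = perSeed,
       meanFinetune = mean(perSeed$apFinetune),
       meanScratch = mean(perSeed$apScratch),
       meanGain = mean(perSeed$apFinetune - perSeed$apScratch))
}

#' Human-in-the-loop versus offline annotation
#'
#' Runs the online/pretrained human-in-the-loop loop (segment, simulated
#' correction, online retraining from the pretrained checkpoint) over a
#' sequence of target-domain images and compares it with the
#' offline/pretrained baseline in which every image is annotated fully by
#' hand. Reports, per replicate, the total manually annotated ROI of both
#' strategies, the final test AP of both models, and the per-round manual
#' counts.
#'
#' @param seed base seed.
#' @param nSeeds replicates (default 5).
#' @param rounds annotation rounds / training images (default 5,
#'   the number of sequentially annotated training images in the published
#'   workflow).
#' @param nTest held-out test images (default 3).
#' @param onlineEpochs retraining epochs per round (default 45).
#' @param offlineEpochs offline-baseline epochs (default 45, annealed).
#' @param acceptIou acceptance threshold of the simulated annotator
#'   (default 0.75: only predictions that match the truth closely count as
#'   correctly segmented; sloppier ones are redrawn and counted as manual).
#' @param peakLr peak learning rate shared by both annotation strategies
#'   (default 0.05: half the published rate, matched to networks with about
#'   1/100th of the full-scale parameter count, where gradient noise at the
#'   published rate dominates the final constant-rate snapshot).
#' @param pretrained optional checkpoint from [pretrainBaseModel()].
#' @return list with `perSeed` data.frame (manualOnline, manualOffline,
#'   apOnline, apOffline), `perRoundManual` (seed x round matrix),
#'   `meanApGap`, `meanManualRatio`.
#' @export
hitlExperiment <- function(seed = 1L, nSeeds = 5, rounds = 5, nTest = 3,
                           onlineEpochs = 45, offlineEpochs = 45,
                           acceptIou = 0.75, peakLr = 0.05,
                           pretrained = NULL) {
  if (is.null(pretrained)) pretrained <- pretrainBaseModel(seed)
  rows <- list(); prm <- matrix(NA_real_, nSeeds, rounds)
  for (r in seq_len(nSeeds)) {
    imgs <- lapply(seq_len(rounds),
                   function(k) targetScene(subSeed(seed, 500L + 10L * r + k)))
    test <- lapply(seq_len(nTest),
                   function(k) targetScene(subSeed(seed, 800L + 10L * r + k)))
    cfg <- hitlConfig(
      acceptIou = acceptIou, init = pretrained,
      trainCfg = trainConfig("online", epochs = onlineEpochs,
                             peakLr = peakLr, tileSize = 48),
      netCfg = deskNetConfig(), seed = subSeed(seed, 900L + r))
    hl <- runHitl(imgs, test, cfg)
    off <- offlineBaseline(imgs, init = pretrained,
                           trainCfg = trainConfig("offline",
                                                  epochs = offlineEpochs,
                                                  annealStart = 35,
                                                  peakLr = peakLr,
                                                  tileSize = 48,
                                                  seed = subSeed(seed, 950L + r)),
                           netCfg = deskNetConfig())
    apOff <- averagePrecision(
      lapply(test, function(im) segmentImage(off$checkpoint, im)$labels),
      lapply(test, labelMap), 0.5)$meanAp[[1]]
    prm[r, ] <- hl$rounds$nManual
    rows[[r]] <- data.frame(
      seed = r, manualOnline = hl$totalManualRoi,
      manualOffline = off$totalManualRoi,
      apOnline = hl$rounds$testAp[rounds], apOffline = apOff)
  }
  perSeed <- do.call(rbind, rows)
  list(perSeed = perSeed, perRoundManual = prm,
       meanApGap = mean(perSeed$apOffline - perSeed$apOnline),
       meanManualRatio = mean(perSeed$manualOnline / perSeed$manualOffline))
}

#' Ensemble of style specialists versus a single generalist
#'
#' On the two-style conflicting benchmark (class A labels orphan nuclei,
#' class B does not), trains one generalist on all images and one specialist
#' per style cluster (clusters found by Leiden on the generalist's style
#' vectors of a larger corpus), then compares test AP\@0.5 of the routed
#' ensemble against the generalist. Specialists are initialized from the
#' generalist and fine-tuned on their cluster's images — the desk-scale
#' analog of giving each specialist a full training run. Setting
#' `broadcastStyle = FALSE` runs the style-broadcast ablation.
#'
#' @param seed base seed.
#' @param nSeeds replicates (default 5).
#' @param epochs generalist training budget (default 30).
#' @param specialistEpochs per-cluster fine-tuning budget (default 20).
#' @param broadcastStyle network style-broadcast switch.
#' @return list with `perSeed` (apEnsemble, apGeneralist, nClusters),
#'   `meanEnsemble`, `meanGeneralist`, `meanGap`.
#' @export
ensembleExperiment <- function(seed = 1L, nSeeds = 5, epochs = 30,
                               specialistEpochs = 20,
                               broadcastStyle = TRUE) {
  rows <- lapply(seq_len(nSeeds), function(r) {
    bench <- makeTwoStyleBenchmark(subSeed(seed, 60L + r),
                                   nTrainPerClass = 5, nTestPerClass = 3,
                                   canvas = c(48, 48), nCells = 8,
                                   nStylePerClass = 10)
    ncfg <- deskNetConfig(inChannels = 2, seed = subSeed(seed, 70L + r),
                          broadcastStyle = broadcastStyle)
    tc <- trainConfig("online", epochs = epochs, tileSize = 48,
                      seed = subSeed(seed, 80L + r))
    generalist <- trainModel("scratch", bench$train, tc, ncfg)
    # cluster a larger style corpus than is trained on: the labeled train
    # images plus the unlabeled style-only scenes
    members <- c(bench$train, bench$styleOnly)
    styles <- do.call(rbind, lapply(members,
                                    function(im) extractStyle(generalist, im)))
    cl <- clusterStyles(styles, nNeighbors = 100, resolution = 0.45,
                        seed = subSeed(seed, 90L + r))
    nclust <- length(unique(cl@clusterIds))
    trainCl <- cl@clusterIds[seq_along(bench$train)]
    # one specialist per cluster; clusters with no usable training images
    # fall back to the generalist checkpoint
    ckpts <- vector("list", nclust)
    for (ci in seq_len(nclust) - 1L) {
      imgs <- filterMinRois(bench$train[trainCl == ci])
      ckpts[[ci + 1L]] <- if (length(imgs)) {
        tcC <- trainConfig("online", epochs = specialistEpochs,
                           tileSize = 48,
                           seed = subSeed(tc$seed, ci + 1L))
        trainModel(generalist, imgs, tcC, ncfg)
      } else generalist
    }
    zoo <- new("ModelZoo", clustering = cl, checkpoints = ckpts, k = 5L)
    testL <- lapply(bench$test, labelMap)
    ens <- segmentWithEnsemble(zoo, bench$test, generalist)
    apE <- averagePrecision(ens$labels, testL, 0.5)$meanAp[[1]]
    apG <- averagePrecision(lapply(bench$test, function(im)
      segmentImage(generalist, im)$labels), testL, 0.5)$meanAp[[1]]
    data.frame(seed = r, apEnsemble = apE, apGeneralist = apG,
               nClusters = nclust)
  })
  perSeed <- do.call(rbind, rows)
  list(perSeed = perSeed,
       meanEnsemble = mean(perSeed$apEnsemble),
       meanGeneralist = mean(perSeed$apGeneralist),
       meanGap = mean(perSeed$apEnsemble - perSeed$apGeneralist))
}

#' Style-routing benchmark on planted classes
#'
#' Generates two synthetic classes with distinct textures, extracts style
#' vectors with a (randomly initialized) network, clusters the training
#' styles, and measures how often held-out images are routed to their own
#' class's cluster. No model training is involved: routing quality is a
#' property of the style embedding and the K-NN classifier.
#'
#' @param seed base seed.
#' @param nTrainPerClass,nTestPerClass images per class (defaults 15 / 25).
#' @return list with `accuracy` (held-out routing accuracy), `nClusters`,
#'   `betweenWithinRatio` (mean between-class over within-class style
#'   distance) and the clustering.
#' @export
styleRoutingBenchmark <- function(seed = 1L, nTrainPerClass = 15,
                                  nTestPerClass = 25) {
  mk <- function(class, k) {
    generateScene(sceneConfig(canvas = c(48, 48), nCells = 8,
                              diameterMean = 9,
                              texture = c("flat", "granular")[class],
                              noiseSd = 0.05,
                              seed = subSeed(seed, 100L * class + k)))
  }
  # style extractor: a small segmentation net trained briefly on a mixed
  # sample of both domains (styles come from a trained model)
  styleTrain <- lapply(1:4, function(k) mk(1L + k %% 2L, 5000L + k))
  net <- trainModel("scratch", styleTrain,
                    trainConfig("online", epochs = 40, tileSize = 48,
                                seed = subSeed(seed, 6L)),
                    deskNetConfig(seed = subSeed(seed, 5L)))
  trCls <- rep(1:2, each = nTrainPerClass)
  teCls <- rep(1:2, each = nTestPerClass)
  tr <- mapply(mk, trCls, seq_along(trCls), SIMPLIFY = FALSE)
  te <- mapply(mk, teCls, 1000L + seq_along(teCls), SIMPLIFY = FALSE)
  styles <- do.call(rbind, lapply(tr, function(im) extractStyle(net, im)))
  d <- as.matrix(stats::dist(styles))
  same <- outer(trCls, trCls, "==") & upper.tri(d)
  diff <- outer(trCls, trCls, "!=") & upper.tri(d)
  cl <- clusterStyles(styles, nNeighbors = 100, resolution = 0.45,
                      seed = subSeed(seed, 7L))
  # majority map cluster -> class on the training members
  map <- tapply(trCls, cl@clusterIds, function(v)
    as.integer(names(which.max(table(v)))))
  pred <- vapply(te, function(im) {
    cid <- assignCluster(cl, extractStyle(net, im))
    map[[as.character(cid)]]
  }, 0L)
  list(accuracy = mean(pred == teCls),
       nClusters = length(unique(cl@clusterIds)),
       betweenWithinRatio = mean(d[diff]) / mean(d[same]),
       clustering = cl)
}
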