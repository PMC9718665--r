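#' Training configuration (offline / online / generalist schedules)
#'
#' Encodes the three SGD schedules: offline training runs 300 epochs with
#' weight decay 1e-4 and peak learning rate 0.1, warming up linearly over the
#' first ten epochs and halving every five epochs after epoch 250; online
#' (human-in-the-loop retraining) runs 100 epochs with the same parameters
#' but never anneals; generalist training runs 500 epochs with weight decay
#' 1e-5 and peak learning rate 0.2, halving every ten epochs after epoch
#' 400. Batches hold eight images sampled with replacement, with a minimum
#' of eight images per epoch.
#'
#' @param mode `"offline"`, `"online"` or `"generalist"`.
#' @param epochs number of epochs; defaults to the mode's schedule.
#' @param batchSize images per batch (default 8).
#' @param weightDecay,peakLr,warmupEpochs,annealStart,annealHalvingPeriod
#'   schedule parameters; defaults follow the mode.
#' @param minImagesPerEpoch minimum images per epoch (default 8); smaller
#'   training sets are resampled with replacement up to this count.
#' @param momentum SGD momentum (default 0.9).
#' @param flowAmplitude scale applied to unit flow targets in the regression
#'   loss (default 5), so the flow term dominates appropriately.
#' @param flowWeight,bceWeight loss weights for the flow MSE and inside-map
#'   binary cross-entropy terms (default 1 each).
#' @param tileSize training crop size in pixels (default 64).
#' @param seed RNG seed for sampling and augmentation.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(mode = c("offline", "online", "generalist"),
                        epochs = NULL, batchSize = 8, weightDecay = NULL,
                        peakLr = NULL, warmupEpochs = 10, annealStart = NULL,
                        annealHalvingPeriod = NULL, minImagesPerEpoch = 8,
                        momentum = 0.9, flowAmplitude = 5, flowWeight = 1,
                        bceWeight = 1, tileSize = 64, seed = 0L) {
  mode <- match.arg(mode)
  def <- switch(mode,
    offline = list(epochs = 300L, wd = 1e-4, lr = 0.1, anneal = 250L, half = 5L),
    online = list(epochs = 100L, wd = 1e-4, lr = 0.1, anneal = NA, half = NA),
    generalist = list(epochs = 500L, wd = 1e-5, lr = 0.2, anneal = 400L, half = 10L))
  if (is.null(epochs)) epochs <- def$epochs
  if (is.null(weightDecay)) weightDecay <- def$wd
  if (is.null(peakLr)) peakLr <- def$lr
  if (is.null(annealStart)) annealStart <- def$anneal
  if (is.null(annealHalvingPeriod)) annealHalvingPeriod <- def$half
  stopifnot(epochs >= warmupEpochs, batchSize >= 1)
  structure(list(mode = mode, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 weightDecay = weightDecay, peakLr = peakLr,
                 warmupEpochs = as.integer(warmupEpochs),
                 annealStart = annealStart,
                 annealHalvingPeriod = annealHalvingPeriod,
                 minImagesPerEpoch = as.integer(minImagesPerEpoch),
                 momentum = momentum, flowAmplitude = flowAmplitude,
                 flowWeight = flowWeight, bceWeight = bceWeight,
                 tileSize = as.integer(tileSize), seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch
#'
#' Linear warmup from `peakLr / warmupEpochs` to `peakLr` over the first
#' `warmupEpochs` epochs, a plateau at `peakLr`, and halving every
#' `annealHalvingPeriod` epochs after `annealStart`. Online mode never
#' anneals.
#'
#' @param cfg a [trainConfig()].
#' @param epoch 0-based epoch index in `[0, cfg$epochs)`.
#' @return learning rate.
#' @examples
#' lrSchedule(trainConfig("offline"), 100)  # 0.1
#' lrSchedule(trainConfig("offline"), 252)  # 0.05
#' @export
lrSchedule <- function(cfg, epoch) {
  stopifnot(inherits(cfg, "TrainConfig"))
  if (any(epoch < 0) || any(epoch >= cfg$epochs))
    stop("epoch index out of range [0, ", cfg$epochs, ")")
  lr <- ifelse(epoch < cfg$warmupEpochs,
               cfg$peakLr * (epoch + 1) / cfg$warmupEpochs,
               cfg$peakLr)
  if (!is.na(cfg$annealStart)) {
    past <- epoch > cfg$annealStart
    halvings <- ceiling((epoch - cfg$annealStart) / cfg$annealHalvingPeriod)
    lr <- ifelse(past, cfg$peakLr / 2^halvings, lr)
  }
  lr
}

#' Sample one epoch of batches
#'
#' The image list is sampled with replacement; if fewer than
#' `minImagesPerEpoch` images are available the list is resampled up to that
#' minimum. One batch per `ceiling(n / batchSize)` group.
#'
#' @param nImages number of available images (must be >= 1).
#' @param cfg a [trainConfig()]. Uses the current RNG state; seed upstream
#'   for determinism.
#' @return list of integer index vectors, one per batch.
#' @export
makeEpoch <- function(nImages, cfg) {
  if (nImages < 1) stop("empty training set")
  m <- max(nImages, cfg$minImagesPerEpoch)
  idx <- sample.int(nImages, m, replace = TRUE)
  split(idx, ceiling(seq_along(idx) / cfg$batchSize))
}

#' Augmentation configuration
#'
#' Random rotation (uniform over the circle), scale jitter, horizontal and
#' vertical flips, intensity jitter and a random crop to the training tile.
#'
#' @param rotate draw a uniform rotation angle?
#' @param scaleRange multiplicative scale-jitter range, a sub-interval of
#'   `[0.5, 2]` (default `c(0.75, 1.25)`).
#' @param flips allow horizontal/vertical flips?
#' @param intensityJitter relative intensity jitter amplitude (default 0.1).
#' @return list of class `AugmentConfig`.
#' @export
augmentConfig <- function(rotate = TRUE, scaleRange = c(0.75, 1.25),
                          flips = TRUE, intensityJitter = 0.1) {
  stopifnot(scaleRange[1] >= 0.5, scaleRange[2] <= 2,
            scaleRange[1] <= scaleRange[2])
  structure(list(rotate = rotate, scaleRange = scaleRange, flips = flips,
                 intensityJitter = intensityJitter),
            class = "AugmentConfig")
}

# Geometric transform draw; identity when the config disables everything.
drawTransform <- function(cfg) {
  list(theta = if (cfg$rotate) stats::runif(1, 0, 2 * pi) else 0,
       scale = stats::runif(1, cfg$scaleRange[1], cfg$scaleRange[2]),
       fy = if (cfg$flips && stats::runif(1) < 0.5) -1 else 1,
       fx = if (cfg$flips && stats::runif(1) < 0.5) -1 else 1,
       gain = 1 + stats::runif(1, -cfg$intensityJitter, cfg$intensityJitter))
}

#' Augment one training sample
#'
#' Applies an identical geometric transform to the image, the inside map and
#' the flow maps, rotating/reflecting the flow *vectors* with the frame so
#' that they still point at the transformed cell centres, and crops to
#' `tileSize`. Deterministic given the RNG state.
#'
#' @param x normalized intensity array `H x W x C`.
#' @param flows a [FlowTarget-class] matching `x`.
#' @param cfg an [augmentConfig()].
#' @param tileSize output tile side in pixels.
#' @param transform optional pre-drawn transform (list with `theta`, `scale`,
#'   `fy`, `fx`, `gain`); drawn from `cfg` when `NULL`.
#' @return list with augmented `x` (tile array), `flowY`, `flowX`,
#'   `inside` matrices.
#' @export
augmentSample <- function(x, flows, cfg = augmentConfig(), tileSize = 64,
                          transform = NULL) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  tr <- if (is.null(transform)) drawTransform(cfg) else transform
  Tt <- tileSize
  ct <- (Tt + 1) / 2
  # inverse map: output offsets -> source coordinates
  s <- tr$scale
  R <- matrix(c(cos(tr$theta), sin(tr$theta),
                -sin(tr$theta), cos(tr$theta)), 2, 2)
  Fm <- diag(c(tr$fy, tr$fx))
  Ainv <- t(R) %*% Fm / s           # inverse of s * F * R (F, R orthogonal)
  # source centre: random but keeping the tile inside when possible
  halft <- Tt / (2 * s) * sqrt(2)
  cy <- if (H - 2 * halft > 1) stats::runif(1, 1 + halft, H - halft) else (H + 1) / 2
  cx <- if (W - 2 * halft > 1) stats::runif(1, 1 + halft, W - halft) else (W + 1) / 2
  oy <- rep(seq_len(Tt) - ct, times = Tt)
  ox <- rep(seq_len(Tt) - ct, each = Tt)
  sy <- Ainv[1, 1] * oy + Ainv[1, 2] * ox + cy
  sx <- Ainv[2, 1] * oy + Ainv[2, 2] * ox + cx
  inCanvas <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  ry <- pmin(pmax(round(sy), 1), H)
  rx <- pmin(pmax(round(sx), 1), W)
  lin <- (rx - 1L) * H + ry
  xt <- array(0, c(Tt, Tt, C))
  for (c in seq_len(C)) {
    v <- bilinearSample(x[, , c], sy, sx) * tr$gain
    v[!inCanvas] <- 0
    xt[, , c] <- matrix(v, Tt, Tt)
  }
  fy0 <- flows@flowY[lin]; fx0 <- flows@flowX[lin]
  fwd <- Fm %*% R                    # how source vectors rotate into the tile
  vy <- fwd[1, 1] * fy0 + fwd[1, 2] * fx0
  vx <- fwd[2, 1] * fy0 + fwd[2, 2] * fx0
  ins <- flows@insideProb[lin]
  vy[!inCanvas] <- 0; vx[!inCanvas] <- 0; ins[!inCanvas] <- 0
  list(x = xt, flowY = matrix(vy, Tt, Tt), flowX = matrix(vx, Tt, Tt),
       inside = matrix(ins, Tt, Tt))
}

# ---- loss + SGD -----------------------------------------------------------

# out: (rows x 3) [inside logit, flow y, flow x]; targets as matrices of the
# same row count. Returns loss value and gradient w.r.t. out.
segLoss <- function(out, inside, ty, tx, cfg) {
  n <- nrow(out)
  l <- out[, 1]
  bce <- mean(pmax(l, 0) - l * inside + log1p(exp(-abs(l))))
  amp <- cfg$flowAmplitude
  dy <- out[, 2] - amp * ty
  dx <- out[, 3] - amp * tx
  mse <- mean(dy^2 + dx^2) / 2
  loss <- cfg$bceWeight * bce + cfg$flowWeight * mse
  dOut <- cbind(cfg$bceWeight * (1 / (1 + exp(-l)) - inside) / n,
                cfg$flowWeight * dy / n,
                cfg$flowWeight * dx / n)
  list(loss = loss, dOut = dOut)
}

sgdStep <- function(params, grads, vel, lr, cfg) {
  vel <- mapLeaves(function(v, g, w) {
    if (is.null(g)) return(v * 0)      # non-trainable leaves (running stats)
    wd <- if (is.matrix(w)) cfg$weightDecay else 0
    cfg$momentum * v - lr * (g + wd * w)
  }, vel, grads, params)
  params <- mapLeaves(function(w, v, unused) w + v, params, vel)
  list(params = params, vel = vel)
}

#' Train a segmentation model
#'
#' SGD with momentum on the combined loss (flow-field regression plus
#' inside-cell binary cross-entropy), following the schedule in `cfg`.
#' Initialization is either from scratch (deterministic under the network
#' seed) or from a pretrained checkpoint, whose weights are copied and
#' trained further. Images with fewer than five ROI are excluded.
#'
#' @param init `"scratch"` or a checkpoint/`flowsegNet` to fine-tune.
#' @param images list of [LabeledImage-class] training records.
#' @param cfg a [trainConfig()].
#' @param netCfg a [netConfig()] used when `init == "scratch"`.
#' @param augCfg an [augmentConfig()].
#' @param minRois minimum ROI per image (default 5).
#' @return a checkpoint (class `flowsegNet`): list with `params`, `cfg`
#'   (network config), `trainCfg`, `modelDiameter` (mean training ROI
#'   diameter) and `log` (per-epoch data.frame epoch/lr/loss).
#' @export
trainModel <- function(init, images, cfg = trainConfig("offline"),
                       netCfg = netConfig(), augCfg = augmentConfig(),
                       minRois = 5) {
  images <- filterMinRois(images, minRois)
  if (!length(images)) stop("no training images left after the ROI filter")
  net <- if (identical(init, "scratch")) buildNetwork(netCfg)
         else list(params = init$params, cfg = init$cfg)
  ncfg <- net$cfg
  prep <- lapply(images, function(im) {
    pp <- prepInput(net, im)
    list(x = pp$x, flows = masksToFlows(labelMap(im)))
  })
  set.seed(subSeed(cfg$seed, 101L))
  params <- net$params
  vel <- zeroLike(params)
  logRows <- vector("list", cfg$epochs)
  Tt <- cfg$tileSize
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lrSchedule(cfg, epoch)
    batches <- makeEpoch(length(prep), cfg)
    eloss <- 0
    for (b in batches) {
      N <- length(b)
      xb <- array(0, c(Tt, Tt, ncfg$inChannels, N))
      iy <- matrix(0, Tt * Tt, N); tyb <- matrix(0, Tt * Tt, N)
      txb <- matrix(0, Tt * Tt, N)
      for (j in seq_along(b)) {
        smp <- prep[[b[j]]]
        aug <- augmentSample(smp$x, smp$flows, augCfg, Tt)
        xb[, , , j] <- aug$x
        iy[, j] <- aug$inside; tyb[, j] <- aug$flowY; txb[, j] <- aug$flowX
      }
      fwd <- netForwardCore(list(params = params, cfg = ncfg), xb,
                            withCache = TRUE, train = TRUE)
      ls <- segLoss(fwd$out, as.numeric(iy), as.numeric(tyb),
                    as.numeric(txb), cfg)
      if (!is.finite(ls$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- netBackwardCore(list(params = params, cfg = ncfg), fwd, ls$dOut)
      params <- updateBNStats(params, fwd$cache)
      st <- sgdStep(params, grads, vel, lr, cfg)
      params <- st$params; vel <- st$vel
      eloss <- eloss + ls$loss
    }
    logRows[[epoch + 1]] <- data.frame(epoch = epoch, lr = lr,
                                       loss = eloss / length(batches))
  }
  structure(list(params = params, cfg = ncfg, trainCfg = cfg,
                 modelDiameter = estimateDiameter(images),
                 log = do.call(rbind, logRows),
                 format = "flowseg-checkpoint-v1"),
            class = "flowsegNet")
}

#' Save / load a checkpoint
#'
#' Checkpoints are single-file archives carrying a format tag, the network
#' config and the parameter tensors.
#'
#' @param ckpt a checkpoint from [trainModel()] or [buildNetwork()].
#' @param path file path.
#' @return `path` (save) or the checkpoint (load).
#' @export
saveCheckpoint <- function(ckpt, path) {
  saveRDS(unclass(ckpt), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  structure(x, class = "flowsegNet")
}
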