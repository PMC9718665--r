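test_that("the learning-rate schedule reproduces warmup, plateau and annealing", {
  off <- trainConfig("offline")
  expect_identical(off$epochs, 300L)
  expect_equal(off$weightDecay, 1e-4)
  expect_equal(lrSchedule(off, 100), 0.1)
  expect_equal(lrSchedule(off, 252), 0.05)
  # warmup is linear from 0 to peak over ten epochs
  expect_equal(lrSchedule(off, 0:9), 0.1 * (1:10) / 10)
  # halving every five epochs after epoch 250
  expect_equal(lrSchedule(off, c(251, 255, 256, 261)),
               c(0.05, 0.05, 0.025, 0.0125))
  expect_error(lrSchedule(off, 300), "out of range")
  expect_error(lrSchedule(off, -1), "out of range")

  on <- trainConfig("online")
  expect_identical(on$epochs, 100L)
  expect_equal(lrSchedule(on, 99), 0.1)   # no annealing, ever
  expect_equal(lrSchedule(on, 10:99), rep(0.1, 90))

  gen <- trainConfig("generalist")
  expect_identical(gen$epochs, 500L)
  expect_equal(gen$weightDecay, 1e-5)
  expect_equal(lrSchedule(gen, 200), 0.2)
  expect_equal(lrSchedule(gen, c(401, 410, 411)), c(0.1, 0.1, 0.05))
})

test_that("epoch sampling resamples small sets up to eight images", {
  cfg <- trainConfig("online", seed = 1)
  set.seed(5)
  b <- makeEpoch(3, cfg)
  expect_length(b, 1)
  expect_length(b[[1]], 8)
  expect_true(all(b[[1]] %in% 1:3))

  set.seed(5)
  b16 <- makeEpoch(16, cfg)
  expect_length(b16, 2)
  expect_identical(lengths(b16), c(`1` = 8L, `2` = 8L))

  set.seed(9); b1 <- makeEpoch(5, cfg)
  set.seed(9); b2 <- makeEpoch(5, cfg)
  expect_identical(b1, b2)
  expect_error(makeEpoch(0, cfg), "empty")
})

test_that("augmentation transforms image, labels and flow vectors together", {
  sc <- demoScene(17)
  pp <- flowseg:::normalizeChannels(pixels(sc))
  ft <- masksToFlows(labelMap(sc))

  idT <- list(theta = 0, scale = 1, fy = 1, fx = 1, gain = 1)
  # identity transform (centre crop at native size) keeps everything
  aug <- augmentSample(pp, ft, tileSize = 48, transform = idT)
  expect_equal(aug$x[, , 1], pp[, , 1])
  expect_equal(aug$flowY, ft@flowY)
  expect_equal(aug$inside, ft@insideProb)

  # horizontal flip negates the x flow component
  flipT <- list(theta = 0, scale = 1, fy = 1, fx = -1, gain = 1)
  augF <- augmentSample(pp, ft, tileSize = 48, transform = flipT)
  expect_equal(augF$flowX, -ft@flowX[, 48:1])
  expect_equal(augF$flowY, ft@flowY[, 48:1])
})

test_that("90-degree rotation keeps flows pointing at rotated centers", {
  sc <- demoScene(18)
  pp <- flowseg:::normalizeChannels(pixels(sc))
  ft <- masksToFlows(labelMap(sc))
  rotT <- list(theta = pi / 2, scale = 1, fy = 1, fx = 1, gain = 1)
  aug <- augmentSample(pp, ft, tileSize = 48, transform = rotT)
  # oracle: rotate the label map on the grid, recompute flows from it
  rotIdx <- function(m) t(m)[, nrow(m):1, drop = FALSE]   # 90 deg
  Lr <- labelMap(sc)
  Lr2 <- matrix(0L, 48, 48)
  for (i in 1:48) for (j in 1:48) {
    # same inverse map as the augmenter: source = R(-theta) (out - c) + c
    oy <- i - 24.5; ox <- j - 24.5
    sy <- round(ox + 24.5); sx <- round(-oy + 24.5)
    Lr2[i, j] <- labelMap(sc)[sy, sx]
  }
  ftr <- masksToFlows(Lr2)
  # centre snapping breaks distance ties by pixel order, which is not
  # rotation-equivariant; compare only ROIs whose snapped centre maps
  # exactly under the rotation (typically all but at most one)
  keep <- vapply(roiIds(Lr2), function(id) {
    ix0 <- which(labelMap(sc) == id)
    rr0 <- (ix0 - 1) %% 48 + 1; cc0 <- (ix0 - 1) %/% 48 + 1
    c0 <- flowseg:::roiCenter(rr0, cc0)
    ix1 <- which(Lr2 == id)
    rr1 <- (ix1 - 1) %% 48 + 1; cc1 <- (ix1 - 1) %/% 48 + 1
    c1 <- flowseg:::roiCenter(rr1, cc1)
    # forward map of the augmenter: source (sy,sx) -> output (oy,ox)
    all(c1 == c(round(-(c0[2] - 24.5) + 24.5), round(c0[1] - 24.5 + 24.5)))
  }, TRUE)
  expect_gte(mean(keep), 0.5)
  inner <- EBImage::erode(matrix(as.numeric(Lr2 > 0), 48, 48),
                          EBImage::makeBrush(3, "box")) > 0
  inner <- inner & matrix(Lr2 %in% roiIds(Lr2)[keep], 48, 48)
  z <- function(v) ifelse(v == 0, 0, v)
  expect_equal(z(aug$flowY[inner]), z(ftr@flowY[inner]), tolerance = 1e-6)
  expect_equal(z(aug$flowX[inner]), z(ftr@flowX[inner]), tolerance = 1e-6)
})

test_that("training on one easy scene reaches AP >= 0.6 and logs decreasing loss", {
  ck <- trainedDemoModel()
  sc <- demoScene(11)    # one of the training scenes
  seg <- segmentImage(ck, sc)
  ap <- averagePrecision(seg$labels, labelMap(sc), 0.5)$meanAp[[1]]
  expect_gte(ap, 0.6)
  lg <- ck$log
  expect_identical(nrow(lg), 40L)
  expect_lt(mean(tail(lg$loss, 5)), mean(head(lg$loss, 5)))
  expect_identical(ck$trainCfg$weightDecay, 1e-4)
})

test_that("training is reproducible and initialization-faithful", {
  sc <- list(demoScene(21))
  tc <- trainConfig("online", epochs = 3, warmupEpochs = 2, tileSize = 48,
                    seed = 4)
  nc <- netConfig(nLevels = 2, baseChannels = 4, seed = 2)
  c1 <- trainModel("scratch", sc, tc, nc)
  c2 <- trainModel("scratch", sc, tc, nc)
  expect_identical(c1$params, c2$params)
  expect_identical(c1$log, c2$log)

  # fine-tuning starts from the checkpoint weights, not from scratch
  c3 <- trainModel(c1, sc, tc, nc)
  expect_false(identical(c3$params, c1$params))
})

test_that("the training loss is invariant to ROI id permutation", {
  sc <- demoScene(22)
  lb <- labelMap(sc)
  perm <- sample(roiCount(sc))
  lb2 <- matrix(0L, 48, 48)
  for (i in seq_along(perm)) lb2[lb == i] <- perm[i]
  img2 <- LabeledImage(pixels(sc), lb2)
  tc <- trainConfig("online", epochs = 2, warmupEpochs = 1, tileSize = 48,
                    seed = 6)
  nc <- netConfig(nLevels = 2, baseChannels = 4, seed = 2)
  a <- trainModel("scratch", list(sc), tc, nc)
  b <- trainModel("scratch", list(img2), tc, nc)
  expect_equal(a$log$loss, b$log$loss, tolerance = 1e-10)
})

test_that("the large online learning rate trains tiny sets without divergence", {
  imgs <- lapply(23:25, function(s) demoScene(s))
  tc <- trainConfig("online", epochs = 15, tileSize = 48, seed = 7)
  expect_identical(tc$peakLr, 0.1)
  ck <- trainModel("scratch", imgs, tc,
                   netConfig(nLevels = 2, baseChannels = 8, seed = 1))
  expect_true(all(is.finite(ck$log$loss)))
})
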