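test_that("IoU matrices match dense per-pair pixel counting", {
  set.seed(10)
  for (rep in 1:5) {
    p <- randomInstanceMap(30, 30, 8)
    t <- randomInstanceMap(30, 30, 8)
    expect_equal(iouMatrix(p, t), bruteIouMatrix(p, t), tolerance = 1e-12)
  }
  # identical maps -> unit diagonal
  p <- randomInstanceMap(30, 30, 3)
  m <- iouMatrix(p, p)
  expect_equal(unname(diag(m)), rep(1, 3))
  # 25 px overlap / 75 px union -> 1/3
  a <- matrix(0L, 20, 20); a[1:10, 1:5] <- 1L        # 50 px
  b <- matrix(0L, 20, 20); b[6:15, 1:5] <- 1L        # 50 px, 25 shared
  expect_equal(iouMatrix(a, b)[1, 1], 25 / 75)
})

test_that("mask matching is a one-to-one optimal assignment", {
  # two predictions both best-overlapping the same truth ROI: exactly one
  # matches, the other is a false positive
  t <- matrix(0L, 10, 10); t[2:7, 2:7] <- 1L
  p <- matrix(0L, 10, 10); p[2:7, 2:5] <- 1L; p[2:7, 6:7] <- 2L
  ious <- iouMatrix(p, t)
  mm <- matchMasks(ious, 0.3)
  expect_identical(mm$tp, 1L)
  expect_identical(mm$fp, 1L)
  expect_identical(mm$fn, 0L)
  expect_identical(mm$pairs$pred, 1L)  # the larger-overlap prediction wins

  # perfect predictions
  mm2 <- matchMasks(iouMatrix(t, t), 0.5)
  expect_identical(c(mm2$tp, mm2$fp, mm2$fn), c(1L, 0L, 0L))

  # empty prediction set
  mm3 <- matchMasks(iouMatrix(matrix(0L, 10, 10), t), 0.5)
  expect_identical(c(mm3$tp, mm3$fp, mm3$fn), c(0L, 0L, 1L))
})

test_that("optimal matching equals exhaustive search on small instances", {
  set.seed(11)
  for (rep in 1:40) {
    p <- randomInstanceMap(24, 24, sample(1:6, 1))
    t <- randomInstanceMap(24, 24, sample(1:6, 1))
    ious <- iouMatrix(p, t)
    for (th in c(0.3, 0.5, 0.7)) {
      expect_identical(matchMasks(ious, th)$tp,
                       as.integer(bruteMatchTp(ious, th)))
    }
  }
})

test_that("greedy and optimal matching agree when best matches are uncontested", {
  set.seed(12)
  p <- randomInstanceMap(30, 30, 6)
  ious <- iouMatrix(p, p)   # diagonal-dominant, no contested best match
  expect_identical(matchMasks(ious, 0.5)$pairs,
                   matchMasks(ious, 0.5, method = "greedy")$pairs)
})

test_that("average precision follows TP/(TP+FP+FN) with the stated edge cases", {
  t <- matrix(0L, 12, 12); t[2:5, 2:5] <- 1L; t[8:11, 8:11] <- 2L
  p <- matrix(0L, 12, 12); p[2:5, 2:5] <- 1L     # one exact, one missed
  expect_equal(unname(averagePrecision(p, t, 0.5)$meanAp[1]), 0.5)
  expect_equal(unname(averagePrecision(t, t, c(0.5, 0.9))$meanAp), c(1, 1))
  # empty vs empty -> 1; empty truth with predictions -> 0
  z <- matrix(0L, 12, 12)
  expect_equal(unname(averagePrecision(z, z, 0.5)$meanAp[1]), 1)
  expect_equal(unname(averagePrecision(p, z, 0.5)$meanAp[1]), 0)
  expect_equal(unname(averagePrecision(z, t, 0.5)$meanAp[1]), 0)
})

test_that("average precision equals the exhaustive-matching oracle exactly", {
  set.seed(13)
  for (rep in 1:60) {
    p <- randomInstanceMap(24, 24, sample(0:6, 1))
    t <- randomInstanceMap(24, 24, sample(0:6, 1))
    th <- sample(c(0.5, 0.6, 0.75), 1)
    expect_identical(unname(averagePrecision(p, t, th)$meanAp[1]),
                     bruteAp(p, t, th))
  }
})

test_that("AP is symmetric and non-increasing in the IoU threshold", {
  set.seed(14)
  ths <- seq(0.5, 0.9, by = 0.1)
  for (rep in 1:10) {
    p <- randomInstanceMap(30, 30, 7)
    t <- randomInstanceMap(30, 30, 7)
    ap <- averagePrecision(p, t, ths)$meanAp
    expect_equal(unname(ap), unname(averagePrecision(t, p, ths)$meanAp))
    expect_true(all(diff(ap) <= 1e-12))
  }
})

test_that("dataset AP is the unweighted mean over images", {
  t1 <- matrix(0L, 12, 12); t1[2:5, 2:5] <- 1L
  t2 <- matrix(0L, 12, 12); t2[2:5, 2:5] <- 1L; t2[8:11, 8:11] <- 2L
  p2 <- matrix(0L, 12, 12); p2[2:5, 2:5] <- 1L
  rep <- averagePrecision(list(t1, p2), list(t1, t2), 0.5)
  expect_equal(unname(rep$meanAp[1]), mean(c(1, 0.5)))
  expect_equal(dim(rep$perImage), c(2L, 1L))
})

test_that("the within-annotator bound handles mirroring and dropped ROI", {
  sc <- demoScene(15)
  truthA <- labelMap(sc)
  # second pass = identical annotation performed on the mirrored image
  mirrored <- truthA[48:1, 48:1]
  expect_equal(unname(withinAnnotatorBound(truthA, mirrored)$meanAp[1]), 1)

  # dropping one of n ROI gives (n-1)/n at threshold 0.5
  n <- roiCount(sc)
  dropped <- truthA; dropped[truthA == roiIds(truthA)[1]] <- 0L
  expect_equal(unname(withinAnnotatorBound(truthA, dropped[48:1, 48:1])$meanAp[1]),
               (n - 1) / n)
  # annotator noise (boundary bias) gives reproducible AP < 1
  noisy <- labelMap(applyStyle(sc, annotationStyle(boundaryBias = 1)))
  ap1 <- withinAnnotatorBound(truthA, noisy[48:1, 48:1], 0.9)$meanAp[1]
  ap2 <- withinAnnotatorBound(truthA, noisy[48:1, 48:1], 0.9)$meanAp[1]
  expect_identical(ap1, ap2)
  expect_lt(ap1, 1)

  expect_error(withinAnnotatorBound(truthA, matrix(0L, 10, 10)),
               "canvas mismatch")
})

test_that("AP-vs-training-size reports sizes, ROI budgets and s.e.m.", {
  pool <- lapply(1:4, function(s) demoScene(40 + s))
  test <- list(demoScene(60))
  # a fake trainer keeps this a pure accounting test: it returns a model
  # whose segmentation is the truth of its first training image
  fakeTrain <- function(images, seed) {
    structure(list(first = images[[1]]), class = "fakeModel")
  }
  # patch segmentImage indirection by training on the test image itself
  tab <- apVsTrainingSize(pool, test, sizes = c(1, 2),
                          trainFn = function(imgs, seed)
                            trainedDemoModel(),
                          nReplicates = 2, seed = 3)
  expect_identical(tab$size, c(1, 2))
  expect_true(all(tab$nTrainRoi > 0))
  expect_true(all(tab$sem >= 0))
  expect_error(apVsTrainingSize(pool, test, sizes = 99,
                                trainFn = function(i, s) trainedDemoModel(),
                                nReplicates = 1), "exceeds")
})
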