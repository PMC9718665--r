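test_that("flows are unit vectors inside ROI, zero outside, with symmetric centers", {
  sc <- demoScene(3)
  ft <- masksToFlows(labelMap(sc))
  mag <- sqrt(ft@flowY^2 + ft@flowX^2)
  expect_true(all(mag[labelMap(sc) == 0] == 0))
  inside <- mag[labelMap(sc) > 0]
  expect_true(all(inside <= 1 + 1e-6))
  expect_gt(mean(inside > 0.99), 0.8)   # nearly all inside pixels unit norm
  expect_equal(ft@insideProb, matrix(as.numeric(labelMap(sc) > 0), 48, 48))

  # a centered disk has (near-)zero flow at its center pixel
  lb <- matrix(0L, 21, 21)
  yy <- outer(-10:10, rep(1, 21)); xx <- t(yy)
  lb[yy^2 + xx^2 <= 36] <- 1L
  f <- masksToFlows(lb)
  expect_lt(sqrt(f@flowY[11, 11]^2 + f@flowX[11, 11]^2), 0.2)

  # empty map -> all-zero target
  z <- masksToFlows(matrix(0L, 8, 8))
  expect_true(all(z@flowY == 0) && all(z@flowX == 0) && all(z@insideProb == 0))
})

test_that("flows along a 1-D bar point toward the middle from both ends", {
  lb <- matrix(0L, 5, 13)
  lb[3, 3:11] <- 1L   # 9-px horizontal bar, middle at column 7
  ft <- masksToFlows(lb)
  # independent oracle: brute-force diffusion with 9-point averaging
  Tf <- matrix(0, 5, 13)
  mask <- lb > 0
  for (it in 1:40) {
    Tf[3, 7] <- Tf[3, 7] + 1
    Tn <- matrix(0, 5, 13)
    for (i in 2:4) for (j in 2:12) {
      if (!mask[i, j]) next
      s <- 0
      for (di in -1:1) for (dj in -1:1)
        if (mask[i + di, j + dj]) s <- s + Tf[i + di, j + dj]
      Tn[i, j] <- s / 9
    }
    Tf <- Tn
  }
  gxo <- vapply(4:10, function(j) (Tf[3, j + 1] - Tf[3, j - 1]) / 2, 0)
  expect_true(all(sign(ft@flowX[3, 4:6]) == 1))    # left arm points right
  expect_true(all(sign(ft@flowX[3, 8:10]) == -1))  # right arm points left
  expect_identical(sign(ft@flowX[3, c(4:6, 8:10)]),
                   sign(gxo[c(1:3, 5:7)]))
  expect_true(all(abs(ft@flowY[3, 4:10]) < 1e-8))
})

test_that("mask reconstruction inverts flow generation on random scenes", {
  for (s in c(1, 2, 3)) {
    sc <- demoScene(s, shape = "ellipse")
    ft <- masksToFlows(labelMap(sc))
    rec <- followFlows(ft)
    ious <- iouMatrix(rec, labelMap(sc))
    mm <- matchMasks(ious, 0.5)
    expect_identical(mm$fn, 0L)
    expect_gt(mean(mm$pairs$iou), 0.9)
  }
})

test_that("degenerate flow inputs behave as specified", {
  # all-zero probability -> empty map
  z <- list(flowY = matrix(0, 16, 16), flowX = matrix(0, 16, 16),
            insideProb = matrix(0, 16, 16))
  expect_identical(roiCount(followFlows(z)), 0L)

  # uniform rightward flow over a full-canvas probability -> one ROI at the
  # clamped right edge sink
  u <- list(flowY = matrix(0, 16, 16), flowX = matrix(1, 16, 16),
            insideProb = matrix(1, 16, 16))
  m <- followFlows(u, qc = qcConfig(minRoiSize = 1))
  expect_identical(length(unique(m[m > 0])), 1L)
  expect_true(all(m > 0))

  bad <- u; bad$flowX[3, 3] <- NaN
  expect_error(followFlows(bad), "non-finite")
})

test_that("flow error separates self-consistent flows from noise at 0.4", {
  sc <- demoScene(5)
  ft <- masksToFlows(labelMap(sc))
  rec <- followFlows(ft)
  errSelf <- flowError(ft, rec)
  expect_true(all(errSelf < 0.1))

  set.seed(7)
  th <- matrix(runif(48 * 48, 0, 2 * pi), 48, 48)
  noise <- list(flowY = sin(th), flowX = cos(th))
  errNoise <- flowError(noise, rec)
  expect_true(all(errNoise > 0.4))
  expect_identical(qcConfig()$flowErrorThreshold, 0.4)
})

test_that("equivalent diameters follow the closed form", {
  lb <- matrix(0L, 60, 60)
  yy <- outer(1:60 - 20, rep(1, 60)); xx <- t(yy)
  lb[(yy)^2 + (xx)^2 <= 100] <- 1L   # radius 10 disk at (20, 20)
  expect_equal(estimateDiameter(lb), 2 * sqrt(sum(lb == 1) / pi))
  expect_lt(abs(estimateDiameter(lb) - 20), 0.5)

  lb2 <- matrix(0L, 20, 20); lb2[5:6, 5:6] <- 1L; lb2[15, 15] <- 2L
  d1 <- 2 * sqrt(4 / pi); d2 <- 2 * sqrt(1 / pi)
  expect_equal(estimateDiameter(lb2), mean(c(d1, d2)))
  # dataset level: mean of per-image means
  expect_equal(estimateDiameter(list(lb, lb2)),
               mean(c(estimateDiameter(lb), estimateDiameter(lb2))))
  expect_error(estimateDiameter(matrix(0L, 4, 4)), "empty")
})

test_that("diameter rescaling follows the scaling law and is invertible", {
  sc <- demoScene(8)
  same <- resizeForDiameter(sc, 10, 10)
  expect_identical(labelMap(same), labelMap(sc))

  up <- resizeForDiameter(sc, 15, 30)
  expect_equal(dim(labelMap(up)), c(96, 96))
  a0 <- sum(labelMap(sc) > 0); a1 <- sum(labelMap(up) > 0)
  expect_lt(abs(a1 / a0 - 4), 0.4)
  expect_identical(roiCount(up), roiCount(sc))

  # down then up preserves ROI count at moderate scales
  down <- resizeForDiameter(sc, 18, 9)
  back <- resizeForDiameter(down, 9, 18)
  expect_identical(roiCount(back), roiCount(sc))

  expect_error(resizeForDiameter(sc, 1, 100), "outside")
})

test_that("reconstruction is equivariant to mirroring", {
  sc <- demoScene(9)
  ft <- masksToFlows(labelMap(sc))
  rec <- followFlows(ft)
  m <- function(x) x[nrow(x):1, ncol(x):1]
  ftm <- list(flowY = -m(ft@flowY), flowX = -m(ft@flowX),
              insideProb = m(ft@insideProb))
  recm <- followFlows(ftm)
  # same partition up to relabeling: compare via AP at 0.9
  expect_equal(unname(averagePrecision(recm, m(rec), 0.9)$meanAp[1]), 1)
})
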