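test_that("label maps round-trip bit-exactly through TIFF and PNG", {
  set.seed(1)
  lb <- randomInstanceMap(20, 24, 5)
  f <- tempfile(fileext = ".tif")
  writeLabelMap(lb, f)
  expect_identical(readLabelMap(f), lb)

  # large ids need 16-bit TIFF
  lb2 <- lb
  lb2[lb2 == 1L] <- 60000L
  writeLabelMap(lb2, f)
  expect_identical(readLabelMap(f), lb2)
  expect_error(writeLabelMap(matrix(70000L, 2, 2), f), "16-bit")

  fp <- tempfile(fileext = ".png")
  writeLabelMap(lb, fp)
  expect_identical(readLabelMap(fp), lb)

  # all-zero map stays a valid file with zero ROI
  writeLabelMap(matrix(0L, 4, 4), f)
  expect_identical(roiCount(readLabelMap(f)), 0L)
})

test_that("non-integer pixel data is rejected as a label map", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), f, bits.per.sample = 32L)
  expect_error(readLabelMap(f), "non-integer|negative")
  expect_error(readLabelMap(tempfile(fileext = ".tif")), "not found")
})

test_that("overlap removal drops ROI above the 75% rule and reassigns by centroid", {
  # b (10 px) shares 8 px with a (40 px): 8/10 = 0.8 > 0.75 -> b removed
  a <- cbind(rep(1:5, each = 8), rep(1:8, times = 5))
  b <- cbind(rep(5:6, each = 5), rep(1:5, times = 2))
  b <- rbind(b[1:8, ], c(7, 1), c(7, 2))   # 8 px overlapping row 5-6? build explicitly
  a <- as.matrix(expand.grid(r = 1:5, c = 1:8))          # 40 px
  b <- rbind(as.matrix(expand.grid(r = 4:5, c = 1:4)),   # 8 px inside a
             c(6, 1), c(6, 2))                           # 2 px outside
  m <- removeOverlaps(list(a, b), canvas = c(10, 10))
  expect_identical(sort(unique(m[m > 0])), 1L)
  expect_identical(sum(m == 1L), nrow(a))

  # disjoint ROI survive untouched
  d1 <- as.matrix(expand.grid(r = 1:3, c = 1:3))
  d2 <- as.matrix(expand.grid(r = 7:9, c = 7:9))
  m2 <- removeOverlaps(list(d1, d2), canvas = c(10, 10))
  expect_identical(sum(m2 == 1L), 9L)
  expect_identical(sum(m2 == 2L), 9L)

  expect_identical(removeOverlaps(list(), c(5, 5)),
                   matrix(0L, 5, 5))
})

test_that("contested pixels go to the nearest centroid and sizes add up", {
  # two 50-px ROI sharing 10 px: fraction 0.2 each -> both kept
  r1 <- as.matrix(expand.grid(r = 1:5, c = 1:10))    # centroid col 5.5
  r2 <- as.matrix(expand.grid(r = 1:5, c = 9:18))    # centroid col 13.5
  m <- removeOverlaps(list(r1, r2), canvas = c(6, 20))
  expect_identical(sum(m > 0), 90L)
  shared <- as.matrix(expand.grid(r = 1:5, c = 9:10))
  for (k in seq_len(nrow(shared))) {
    px <- shared[k, ]
    want <- if (abs(px[2] - 5.5) < abs(px[2] - 13.5)) 1L else 2L
    expect_identical(m[px[1], px[2]], want)
  }
  # non-contested pixels never reassigned
  expect_true(all(m[cbind(r1[r1[, 2] < 9, ])] == 1L))
})

test_that("overlap removal matches per-pixel brute force on random sets", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    H <- 30; W <- 30
    sets <- lapply(seq_len(n), function(i) {
      r <- runif(1, 1.5, 4)
      cy <- runif(1, r + 1, H - r); cx <- runif(1, r + 1, W - r)
      yy <- outer(seq_len(H) - cy, rep(1, W))
      xx <- outer(rep(1, H), seq_len(W) - cx)
      px <- which(yy^2 + xx^2 <= r^2, arr.ind = FALSE)
      cbind((px - 1) %% H + 1, (px - 1) %/% H + 1)
    })
    m <- removeOverlaps(sets, canvas = c(H, W))
    # brute force: overlap fractions on original sets
    lin <- lapply(sets, function(p) (p[, 2] - 1) * H + p[, 1])
    cnt <- tabulate(unlist(lin), H * W)
    frac <- vapply(lin, function(ix) mean(cnt[ix] >= 2), 0)
    keep <- which(frac <= 0.75)
    expect_setequal(unique(m[m > 0]), keep)
    # output is overlap-free by construction (instance map), and every
    # contested surviving pixel went to the nearest surviving centroid
    cents <- t(vapply(sets, colMeans, c(0, 0)))
    cnt2 <- tabulate(unlist(lin[keep]), H * W)
    for (px in which(cnt2 >= 2)) {
      owners <- keep[vapply(lin[keep], function(ix) px %in% ix, TRUE)]
      r <- (px - 1) %% H + 1; cc <- (px - 1) %/% H + 1
      d2 <- (cents[owners, 1] - r)^2 + (cents[owners, 2] - cc)^2
      expect_identical(m[px], owners[which.min(d2)])
    }
  }
})

test_that("quartering preserves labeled pixels and halves each axis", {
  img <- demoScene(5)
  q <- splitQuarters(img)
  expect_length(q, 4)
  expect_equal(dim(pixels(q[[1]])), c(24, 24, 1))
  expect_identical(sum(vapply(q, function(t) sum(labelMap(t) > 0), 0L)),
                   sum(labelMap(img) > 0))
  # odd dimensions: remainder goes to the second tile
  odd <- LabeledImage(matrix(runif(35), 5, 7), matrix(0L, 5, 7))
  qo <- splitQuarters(odd)
  expect_equal(dim(pixels(qo[[1]]))[1:2], c(2, 3))
  expect_equal(dim(pixels(qo[[4]]))[1:2], c(3, 4))
  # per-tile labels are consecutive
  for (t in q) {
    ids <- roiIds(t)
    if (length(ids)) expect_identical(ids, seq_along(ids))
  }
})

test_that("contrast enhancement follows (I - G)/(G) with a Gaussian smoother", {
  # constant image -> exactly zero
  expect_equal(enhanceContrast(matrix(3, 8, 8), sigma = 2),
               matrix(0, 8, 8))
  # all-zero image -> zeros, no division blowup
  expect_equal(enhanceContrast(matrix(0, 6, 6)), matrix(0, 6, 6))

  # brute-force oracle: dense renormalized Gaussian kernel, direct loops
  set.seed(3)
  img <- matrix(runif(15 * 12), 15, 12)
  sigma <- 2.5
  sm <- matrix(0, 15, 12)
  for (i in 1:15) for (j in 1:12) {
    wsum <- 0; acc <- 0
    for (a in 1:15) for (b in 1:12) {
      w <- exp(-((i - a)^2) / (2 * sigma^2)) * exp(-((j - b)^2) / (2 * sigma^2))
      acc <- acc + w * img[a, b]; wsum <- wsum + w
    }
    sm[i, j] <- acc / wsum
  }
  want <- (img - sm) / pmax(sm, 1e-6 * max(img))
  expect_equal(enhanceContrast(img, sigma), want, tolerance = 1e-10)

  # single bright pixel: positive peak, negative ring
  spot <- matrix(0.01, 11, 11); spot[6, 6] <- 1
  e <- enhanceContrast(spot, sigma = 2)
  expect_gt(e[6, 6], 0)
  expect_lt(e[6, 9], 0)
})

test_that("contrast enhancement commutes with mirroring", {
  set.seed(4)
  img <- matrix(runif(100), 10, 10)
  m <- function(x) x[nrow(x):1, ncol(x):1]
  expect_equal(enhanceContrast(m(img), 3), m(enhanceContrast(img, 3)),
               tolerance = 1e-12)
})

test_that("mirroring is an involution preserving ROI sizes", {
  img <- demoScene(6)
  mm <- mirrorImage(mirrorImage(img))
  expect_identical(labelMap(mm), labelMap(img))
  expect_equal(pixels(mm), pixels(img))
  expect_identical(labelMap(mirrorImage(img))[1, 1],
                   labelMap(img)[48, 48])
  areas <- function(x) sort(as.integer(table(labelMap(x)[labelMap(x) > 0])))
  expect_equal(areas(mirrorImage(img)), areas(img))
  asym <- LabeledImage(matrix(0, 2, 2), matrix(c(1L, 0L, 0L, 2L), 2, 2))
  expect_identical(labelMap(mirrorImage(asym)),
                   matrix(c(2L, 0L, 0L, 1L), 2, 2))
})

test_that("the minimum-ROI filter drops images below five ROI", {
  img5 <- demoScene(7)   # 8 cells
  few <- LabeledImage(matrix(runif(48 * 48), 48, 48),
                      randomInstanceMap(48, 48, 4))
  kept <- filterMinRois(list(few, img5))
  expect_length(kept, 1)
  expect_identical(kept[[1]]@sourceId, img5@sourceId)
  # boundary: exactly five ROI is kept
  five <- LabeledImage(matrix(runif(48 * 48), 48, 48),
                       randomInstanceMap(48, 48, 5))
  expect_length(filterMinRois(list(five)), 1)
  expect_length(filterMinRois(list()), 0)
})

test_that("manifests round-trip through JSON", {
  entries <- list(list(image = "a.tif", labels = "a_masks.tif",
                       channelRoles = c("cytoplasm", "nucleus")))
  f <- tempfile(fileext = ".json")
  writeManifest(entries, f)
  back <- readManifest(f)
  expect_identical(back[[1]]$image, "a.tif")
  expect_identical(unlist(back[[1]]$channelRoles),
                   c("cytoplasm", "nucleus"))
})
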