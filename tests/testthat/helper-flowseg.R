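# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# A small trained model, computed once per session and reused by tests that
# need a model that actually segments.
.demoCache <- new.env(parent = emptyenv())
trainedDemoModel <- function() {
  if (is.null(.demoCache$model)) {
    scenes <- lapply(c(11, 12), function(s)
      generateScene(sceneConfig(canvas = c(48, 48), nCells = 8,
                                diameterMean = 9, seed = s)))
    .demoCache$model <- trainModel(
      "scratch", scenes,
      trainConfig("online", epochs = 40, tileSize = 48, seed = 1),
      netConfig(nLevels = 2, baseChannels = 8, inChannels = 1, seed = 0))
  }
  .demoCache$model
}

demoScene <- function(seed = 11, ...) {
  generateScene(sceneConfig(canvas = c(48, 48), nCells = 8, diameterMean = 9,
                            seed = seed, ...))
}

# Random instance map with n ROI as blobs of random disks (overlap-free).
randomInstanceMap <- function(H, W, n, rmin = 2, rmax = 4) {
  lb <- matrix(0L, H, W)
  placed <- 0L
  for (i in seq_len(n * 4)) {
    if (placed >= n) break
    r <- stats::runif(1, rmin, rmax)
    cy <- stats::runif(1, r + 1, H - r); cx <- stats::runif(1, r + 1, W - r)
    yy <- outer(seq_len(H) - cy, rep(1, W))
    xx <- outer(rep(1, H), seq_len(W) - cx)
    px <- which(yy^2 + xx^2 <= r^2)
    if (length(px) && all(lb[px] == 0L)) {
      placed <- placed + 1L
      lb[px] <- placed
    }
  }
  lb
}

# Brute-force IoU matrix by per-pair pixel counting (dense loops).
bruteIouMatrix <- function(p, t) {
  pid <- roiIds(p); tid <- roiIds(t)
  m <- matrix(0, length(pid), length(tid), dimnames = list(pid, tid))
  for (i in seq_along(pid)) for (j in seq_along(tid)) {
    a <- p == pid[i]; b <- t == tid[j]
    m[i, j] <- sum(a & b) / sum(a | b)
  }
  m
}

# Exhaustive best matching: enumerate all injective pred->truth matchings
# over pairs with IoU >= threshold, maximizing total matched IoU; returns tp.
bruteMatchTp <- function(ious, threshold) {
  np <- nrow(ious); nt <- ncol(ious)
  if (np == 0 || nt == 0) return(0L)
  best <- 0; bestTp <- 0L
  rec <- function(i, usedT, total, tp) {
    if (i > np) {
      if (total > best + 1e-12 ||
          (abs(total - best) <= 1e-12 && tp > bestTp)) {
        best <<- total; bestTp <<- tp
      }
      return(invisible(NULL))
    }
    rec(i + 1L, usedT, total, tp)          # leave prediction i unmatched
    for (j in seq_len(nt)) {
      if (!usedT[j] && ious[i, j] >= threshold) {
        usedT[j] <- TRUE
        rec(i + 1L, usedT, total + ious[i, j], tp + 1L)
        usedT[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nt), 0, 0L)
  bestTp
}

bruteAp <- function(p, t, threshold) {
  np <- roiCount(p); nt <- roiCount(t)
  if (np == 0 && nt == 0) return(1)
  if (np == 0 || nt == 0) return(0)
  tp <- bruteMatchTp(bruteIouMatrix(p, t), threshold)
  tp / (np + nt - tp)
}

# Adjusted Rand index between two labelings (closed form from the
# contingency table).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
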