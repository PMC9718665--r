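#' Network configuration
#'
#' A small U-net with residual blocks. The encoder halves resolution
#' `nLevels - 1` times; the style vector is the global average pool of the
#' deepest feature maps, so `styleDim` always equals the deepest channel
#' count (`baseChannels * 2^(nLevels-1)`; 256 for the default 4-level,
#' 32-channel network). When `broadcastStyle` is true the (L2-normalized)
#' style vector is linearly projected per decoder level and added as a
#' per-channel bias to the upsampling-path features; when false it is
#' computed but not injected (the ablation switch).
#'
#' @param nLevels downsampling depth (default 4; desk-scale tests use 2).
#' @param baseChannels channels at the finest level (default 32; desk 16).
#' @param styleDim style vector length; must equal the deepest channel count
#'   and is derived from it when `NULL`.
#' @param broadcastStyle inject the style vector into the decoder?
#' @param inChannels 1 or 2 input channels.
#' @param seed parameter-initialization seed.
#' @return list of class `NetConfig`.
#' @export
netConfig <- function(nLevels = 4, baseChannels = 32, styleDim = NULL,
                      broadcastStyle = TRUE, inChannels = 1, seed = 0L) {
  stopifnot(nLevels >= 1, baseChannels >= 1, inChannels %in% 1:2)
  deepest <- baseChannels * 2^(nLevels - 1)
  if (is.null(styleDim)) styleDim <- deepest
  if (styleDim != deepest)
    stop("styleDim must equal the deepest channel count (", deepest, ")")
  structure(list(nLevels = as.integer(nLevels),
                 baseChannels = as.integer(baseChannels),
                 styleDim = as.integer(styleDim),
                 broadcastStyle = isTRUE(broadcastStyle),
                 inChannels = as.integer(inChannels),
                 seed = as.integer(seed)),
            class = "NetConfig")
}

# ---- parameter initialization ---------------------------------------------

convInit <- function(cin, cout) {
  # no bias: every 3x3 conv is followed by a normalization layer
  list(W = matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                  9 * cin, cout))
}
linInit <- function(cin, cout, sd = sqrt(1 / cin)) {
  matrix(stats::rnorm(cin * cout, 0, sd), cin, cout)
}
bnInit <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                           rm = rep(0, c), rv = rep(1, c))

blockInit <- function(cin, cout) {
  list(conv1 = convInit(cin, cout), bn1 = bnInit(cout),
       conv2 = convInit(cout, cout), bn2 = bnInit(cout),
       skip = if (cin != cout) linInit(cin, cout, sqrt(2 / cin)) else NULL)
}

#' Build a network
#'
#' Parameter initialization is deterministic under `cfg$seed`. The forward
#' pass maps an `inChannels x H x W` tile (H, W divisible by
#' `2^(nLevels-1)`) to three output maps of the same size — inside-cell
#' logit, flow in y, flow in x — plus a style vector.
#'
#' @param cfg a [netConfig()].
#' @return a checkpoint-like list of class `flowsegNet` with elements
#'   `params` and `cfg`.
#' @export
buildNetwork <- function(cfg = netConfig()) {
  stopifnot(inherits(cfg, "NetConfig"))
  set.seed(cfg$seed)
  L <- cfg$nLevels
  ch <- cfg$baseChannels * 2^(seq_len(L) - 1)
  enc <- list()
  cin <- cfg$inChannels
  for (l in seq_len(L)) {
    enc[[l]] <- blockInit(cin, ch[l])
    cin <- ch[l]
  }
  dec <- list()
  if (L > 1) {
    for (l in seq_len(L - 1)) {
      # decoder level l combines upsampled ch[l+1] with the skip ch[l]
      dec[[l]] <- blockInit(ch[l + 1] + ch[l], ch[l])
      if (cfg$broadcastStyle)
        dec[[l]]$proj <- linInit(cfg$styleDim, ch[l])
    }
  }
  out <- list(W = linInit(ch[1], 3, sqrt(2 / ch[1])), b = rep(0, 3))
  structure(list(params = list(enc = enc, dec = dec, out = out), cfg = cfg),
            class = "flowsegNet")
}

# ---- primitive layers (matrix representation: (H*W*N) x C) ----------------

convF <- function(x, p, H, W, N) {
  cols <- .im2col3(x, H, W, N)
  list(y = cols %*% p$W, cols = cols)
}
convB <- function(dy, cache, p, H, W, N, cin) {
  dW <- crossprod(cache$cols, dy)
  dx <- .col2im3(tcrossprod(dy, p$W), H, W, N, cin)
  list(dx = dx, g = list(W = dW))
}

bnF <- function(x, p, train = FALSE, eps = 1e-5, bnMomentum = 0.1) {
  .bnFwd(x, p$gamma, p$beta, p$rm, p$rv, train, bnMomentum, eps)
}
bnB <- function(dy, cache, p) {
  b <- .bnBwd(dy, cache$xh, p$gamma, cache$ist)
  list(dx = b$dx, g = list(gamma = b$dgamma, beta = b$dbeta))
}

blockF <- function(x, p, H, W, N, styleBias = NULL, train = FALSE) {
  c1 <- convF(x, p$conv1, H, W, N)
  b1 <- bnF(c1$y, p$bn1, train)
  pre <- b1$y
  if (!is.null(styleBias)) pre <- pre + styleBias[rep(seq_len(N), each = H * W), , drop = FALSE]
  h1 <- pre * (pre > 0)
  c2 <- convF(h1, p$conv2, H, W, N)
  b2 <- bnF(c2$y, p$bn2, train)
  sk <- if (is.null(p$skip)) x else x %*% p$skip
  z <- b2$y + sk
  y <- z * (z > 0)
  list(y = y, c1 = c1, b1 = b1, pre = pre, h1 = h1, c2 = c2, b2 = b2,
       z = z, x = x)
}
blockB <- function(dy, cache, p, H, W, N) {
  dz <- dy * (cache$z > 0)
  bb2 <- bnB(dz, cache$b2, p$bn2)
  cb2 <- convB(bb2$dx, cache$c2, p$conv2, H, W, N, ncol(cache$h1))
  dh1 <- cb2$dx
  dpre <- dh1 * (cache$pre > 0)
  dstyle <- NULL
  if (!is.null(p$proj)) {
    # per-image, per-channel sums of the gradient at the injection point
    grp <- rep(seq_len(N), each = H * W)
    dstyle <- rowsum(dpre, grp)
  }
  bb1 <- bnB(dpre, cache$b1, p$bn1)
  cb1 <- convB(bb1$dx, cache$c1, p$conv1, H, W, N, ncol(cache$x))
  dx <- cb1$dx
  g <- list(conv1 = cb1$g, bn1 = bb1$g, conv2 = cb2$g, bn2 = bb2$g)
  if (is.null(p$skip)) {
    dx <- dx + dz
    g$skip <- NULL
  } else {
    dx <- dx + dz %*% t(p$skip)
    g$skip <- crossprod(cache$x, dz)
  }
  list(dx = dx, g = g, dstyle = dstyle)
}

# ---- full forward / backward ----------------------------------------------

# batch: array (H, W, C, N). Returns output maps (H*W*N x 3), style (N x D,
# L2-normalized), and a cache for the backward pass.
netForwardCore <- function(net, batch, withCache = FALSE, train = FALSE) {
  cfg <- net$cfg; p <- net$params
  d <- dim(batch)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  L <- cfg$nLevels
  div <- 2^(L - 1)
  if (H %% div != 0 || W %% div != 0)
    stop("H and W must be divisible by ", div, " (pad the input)")
  if (C != cfg$inChannels) stop("expected ", cfg$inChannels, " channel(s)")
  if (any(!is.finite(batch))) stop("non-finite values in network input")
  x <- matrix(aperm(batch, c(1, 2, 4, 3)), H * W * N, C)
  dims <- list()
  a <- list(); ac <- list(); pools <- list()
  cur <- x; h <- H; w <- W
  for (l in seq_len(L)) {
    dims[[l]] <- c(h, w)
    bl <- blockF(cur, p$enc[[l]], h, w, N, train = train)
    a[[l]] <- bl$y; ac[[l]] <- bl
    if (l < L) {
      mp <- .maxpool2(bl$y, h, w, N)
      pools[[l]] <- mp$argmax
      cur <- mp$out
      h <- h / 2; w <- w / 2
    }
  }
  hL <- dims[[L]][1]; wL <- dims[[L]][2]
  grp <- rep(seq_len(N), each = hL * wL)
  s <- rowsum(a[[L]], grp) / (hL * wL)
  sn <- sqrt(rowSums(s^2))
  sn[sn == 0] <- 1
  sN <- s / sn
  cur <- a[[L]]
  dc <- list()
  if (L > 1) {
    for (l in rev(seq_len(L - 1))) {
      h <- dims[[l + 1]][1]; w <- dims[[l + 1]][2]
      up <- .upsample2(cur, h, w, N)
      cat <- cbind(up, a[[l]])
      sb <- if (cfg$broadcastStyle) sN %*% p$dec[[l]]$proj else NULL
      bl <- blockF(cat, p$dec[[l]], dims[[l]][1], dims[[l]][2], N, sb, train)
      dc[[l]] <- bl
      cur <- bl$y
    }
  }
  out <- cur %*% p$out$W +
    matrix(p$out$b, nrow(cur), 3, byrow = TRUE)
  res <- list(out = out, style = sN, H = H, W = W, N = N)
  if (withCache)
    res$cache <- list(a = a, ac = ac, pools = pools, dc = dc, dims = dims,
                      cur = cur, s = s, sn = sn, sN = sN, x = x)
  res
}

# dOut: (H*W*N x 3). Returns gradients in the same structure as net$params.
netBackwardCore <- function(net, fwd, dOut) {
  cfg <- net$cfg; p <- net$params
  cache <- fwd$cache
  H <- fwd$H; W <- fwd$W; N <- fwd$N
  L <- cfg$nLevels
  dims <- cache$dims
  g <- list(enc = vector("list", L), dec = list(), out = NULL)
  gOut <- list(W = crossprod(cache$cur, dOut), b = colSums(dOut))
  g$out <- gOut
  dcur <- dOut %*% t(p$out$W)
  dsN <- matrix(0, N, cfg$styleDim)
  da <- vector("list", L)
  if (L > 1) {
    for (l in seq_len(L - 1)) {
      bl <- cache$dc[[l]]
      bw <- blockB(dcur, bl, p$dec[[l]], dims[[l]][1], dims[[l]][2], N)
      g$dec[[l]] <- bw$g
      if (!is.null(bw$dstyle)) {
        g$dec[[l]]$proj <- crossprod(cache$sN, bw$dstyle)
        dsN <- dsN + bw$dstyle %*% t(p$dec[[l]]$proj)
      }
      cUp <- ncol(cache$a[[l + 1]])
      dup <- bw$dx[, seq_len(cUp), drop = FALSE]
      dskip <- bw$dx[, -seq_len(cUp), drop = FALSE]
      if (is.null(da[[l]])) da[[l]] <- dskip else da[[l]] <- da[[l]] + dskip
      dcoarse <- .upsample2_bwd(dup, dims[[l + 1]][1], dims[[l + 1]][2], N)
      dcur <- dcoarse
    }
    if (is.null(da[[L]])) da[[L]] <- dcur else da[[L]] <- da[[L]] + dcur
  } else {
    da[[L]] <- dcur
  }
  # style head: sN = s / ||s||
  s <- cache$s; sn <- cache$sn; sN <- cache$sN
  ds <- (dsN - sN * rowSums(dsN * sN)) / sn
  hL <- dims[[L]][1]; wL <- dims[[L]][2]
  da[[L]] <- da[[L]] + ds[rep(seq_len(N), each = hL * wL), , drop = FALSE] / (hL * wL)
  for (l in rev(seq_len(L))) {
    bw <- blockB(da[[l]], cache$ac[[l]], p$enc[[l]],
                 dims[[l]][1], dims[[l]][2], N)
    g$enc[[l]] <- bw$g
    if (l > 1) {
      dpool <- .maxpool2_bwd(bw$dx, cache$pools[[l - 1]],
                             dims[[l - 1]][1], dims[[l - 1]][2], N)
      da[[l - 1]] <- if (is.null(da[[l - 1]])) dpool else da[[l - 1]] + dpool
    }
  }
  g
}

#' Forward pass on a single tile
#'
#' @param net a `flowsegNet` (from [buildNetwork()]) or checkpoint.
#' @param tile `H x W` matrix or `H x W x C` array, already normalized.
#' @return list with `maps` (`H x W x 3` array: inside logit, flow y, flow x)
#'   and `style` (L2-normalized style vector).
#' @export
netForward <- function(net, tile) {
  if (is.matrix(tile)) tile <- array(tile, c(dim(tile), 1L))
  batch <- array(tile, c(dim(tile), 1L))
  f <- netForwardCore(net, batch)
  maps <- array(f$out, c(f$H, f$W, 3))
  list(maps = maps, style = as.numeric(f$style[1, ]))
}

# Match an image's channels to what the network expects (truncate or
# zero-pad), normalize, and pad spatially to a multiple of 2^(L-1).
prepInput <- function(net, img) {
  px <- if (is(img, "LabeledImage")) pixels(img) else img
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  want <- net$cfg$inChannels
  have <- dim(px)[3]
  if (have > want) px <- px[, , seq_len(want), drop = FALSE]
  if (have < want) {
    pad <- array(0, c(dim(px)[1], dim(px)[2], want - have))
    px <- array(c(px, pad), c(dim(px)[1], dim(px)[2], want))
  }
  px <- normalizeChannels(px)
  padToMultiple(px, 2^(net$cfg$nLevels - 1))
}

#' Extract the style vector of an image
#'
#' Global average pooling of the deepest feature maps, L2-normalized. The
#' result is deterministic: identical images give identical style vectors.
#'
#' @param net a `flowsegNet` or checkpoint.
#' @param img a [LabeledImage-class] or intensity array.
#' @return numeric style vector of length `styleDim` with unit L2 norm.
#' @export
extractStyle <- function(net, img) {
  pp <- prepInput(net, img)
  f <- netForward(net, pp$x)
  f$style
}

#' Total number of trainable parameters of a network
#' @param net a `flowsegNet` or checkpoint.
#' @return integer parameter count.
#' @export
nParameters <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(net$params)
  n
}

# ---- structured parameter arithmetic (SGD) --------------------------------

# Apply f(leafA, leafB, ...) across parallel nested lists of numerics.
mapLeaves <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nms <- names(a)
    byName <- !is.null(nms) && all(nzchar(nms))
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      k <- if (byName) nms[i] else i
      out[[i]] <- mapLeaves(f, a[[i]],
                            if (!is.null(b)) b[[k]],
                            if (!is.null(c)) c[[k]])
    }
    out
  } else {
    f(a, b, c)
  }
}

zeroLike <- function(p) mapLeaves(function(a, b, c) a * 0, p)

# fold the updated batch-norm running statistics of a training forward pass
# back into the parameter structure
updateBNStats <- function(params, cache) {
  for (l in seq_along(cache$ac)) {
    params$enc[[l]]$bn1$rm <- cache$ac[[l]]$b1$newRm
    params$enc[[l]]$bn1$rv <- cache$ac[[l]]$b1$newRv
    params$enc[[l]]$bn2$rm <- cache$ac[[l]]$b2$newRm
    params$enc[[l]]$bn2$rv <- cache$ac[[l]]$b2$newRv
  }
  for (l in seq_along(cache$dc)) {
    params$dec[[l]]$bn1$rm <- cache$dc[[l]]$b1$newRm
    params$dec[[l]]$bn1$rv <- cache$dc[[l]]$b1$newRv
    params$dec[[l]]$bn2$rm <- cache$dc[[l]]$b2$newRm
    params$dec[[l]]$bn2$rv <- cache$dc[[l]]$b2$newRv
  }
  params
}
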