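#' Read an instance label map from a PNG or TIFF file
#'
#' Label maps are single-channel integer images: id 0 is background, every
#' positive id one ROI. TIFF files are read with their stored integer values;
#' PNG values are rescaled back to integers using the file's bit depth.
#'
#' @param path path to an 8/16-bit single-channel PNG or TIFF file.
#' @return integer matrix of labels.
#' @seealso [writeLabelMap()]
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("label map file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    v <- png::readPNG(path)
    depth <- as.integer(readBin(path, "raw", 25L)[25L])
    x <- v * (2^depth - 1)
  } else stop("unsupported label map format: ", ext)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] != 1L) stop("label maps must be single-channel")
    x <- x[, , 1]
  }
  if (max(abs(x - round(x))) > 1e-6)
    stop("label map contains non-integer pixel values")
  x <- round(x)
  if (any(x < 0)) stop("label map contains negative values")
  storage.mode(x) <- "integer"
  x
}

#' Write an instance label map to a PNG or TIFF file
#'
#' The round trip `readLabelMap(writeLabelMap(x))` is bit-exact for ids up to
#' 65535 (16-bit TIFF). PNG output supports ids up to 255 (8-bit); use TIFF
#' for larger id ranges.
#'
#' @param labels integer matrix (0 = background).
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(labels, path) {
  if (is(labels, "LabeledImage")) labels <- labelMap(labels)
  stopifnot(is.matrix(labels))
  mx <- max(labels, 0L)
  if (mx > 65535) stop("label id ", mx, " exceeds the 16-bit range (65535)")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "png") {
    if (mx > 255) stop("PNG label maps support ids up to 255; use TIFF")
    png::writePNG(labels / 255, path)
  } else stop("unsupported label map format: ", ext)
  invisible(path)
}

#' Overlap-removal policy for converting overlapping ROI to a flat map
#'
#' ROI whose overlap fraction with the union of all other ROI exceeds
#' `removalFraction` are dropped entirely; remaining contested pixels are
#' reassigned to the ROI with the closest centroid.
#'
#' @param removalFraction fraction in (0, 1]; default 0.75, i.e. ROI with
#'   more than 75% of their pixels overlapping another ROI are removed.
#' @return a list of class `RoiOverlapPolicy`.
#' @export
roiOverlapPolicy <- function(removalFraction = 0.75) {
  stopifnot(removalFraction > 0, removalFraction <= 1)
  structure(list(removalFraction = removalFraction,
                 reassignment = "closest-centroid"),
            class = "RoiOverlapPolicy")
}

#' Flatten overlapping ROI into an instance map
#'
#' Implements the two-step preparation rule for datasets annotated with
#' overlapping ROI: (1) every ROI with more than `removalFraction` of its
#' pixels overlapping at least one other ROI is removed (fractions are
#' evaluated on the original sets, before any reassignment); (2) each
#' surviving contested pixel is assigned to the surviving ROI whose centroid
#' (mean of the ROI's original pixel coordinates) is nearest in Euclidean
#' distance, ties broken by lower ROI id.
#'
#' @param roiSets list of ROI, each a 2-column matrix of (row, col) pixel
#'   coordinates (1-based) on a shared canvas.
#' @param canvas integer vector `c(H, W)`.
#' @param policy a [roiOverlapPolicy()].
#' @return integer instance map; surviving ROI keep their list index as id.
#' @examples
#' a <- cbind(rep(1:5, each = 8), rep(1:8, 5))   # 40 px
#' b <- cbind(rep(5:6, each = 5), rep(1:5, 2))   # 10 px, 5 shared with a
#' m <- removeOverlaps(list(a, b), canvas = c(10, 10))
#' table(m[m > 0])
#' @export
removeOverlaps <- function(roiSets, canvas, policy = roiOverlapPolicy()) {
  H <- canvas[1]; W <- canvas[2]
  out <- matrix(0L, H, W)
  if (!length(roiSets)) return(out)
  stopifnot(all(vapply(roiSets, nrow, 1L) > 0))
  lin <- lapply(roiSets, function(p) {
    stopifnot(all(p[, 1] >= 1), all(p[, 1] <= H),
              all(p[, 2] >= 1), all(p[, 2] <= W))
    (p[, 2] - 1L) * H + p[, 1]
  })
  counts <- tabulate(unlist(lin), nbins = H * W)
  overlapFrac <- vapply(lin, function(ix) mean(counts[ix] >= 2L), 0)
  keep <- which(overlapFrac <= policy$removalFraction)
  if (!length(keep)) return(out)
  cents <- t(vapply(roiSets, function(p) colMeans(p), c(0, 0)))
  # non-contested pixels first (w.r.t. surviving ROI)
  counts2 <- tabulate(unlist(lin[keep]), nbins = H * W)
  for (i in keep) {
    ix <- lin[[i]]
    solo <- ix[counts2[ix] == 1L]
    out[solo] <- i
  }
  contested <- which(counts2 >= 2L)
  for (px in contested) {
    owners <- keep[vapply(lin[keep], function(ix) px %in% ix, TRUE)]
    r <- (px - 1L) %% H + 1L
    cc <- (px - 1L) %/% H + 1L
    d2 <- (cents[owners, 1] - r)^2 + (cents[owners, 2] - cc)^2
    out[px] <- owners[which.min(d2)]  # which.min breaks ties by lower index
  }
  out
}

#' Split a labeled image into four tiles
#'
#' Halves each axis (floor division; odd remainders attach to the second
#' tile). ROI cut by a tile border keep only their in-tile pixels; labels are
#' re-indexed per tile to consecutive ids. Total labeled pixel count is
#' conserved.
#'
#' @param img a [LabeledImage-class].
#' @return list of four `LabeledImage` tiles in order top-left, top-right,
#'   bottom-left, bottom-right.
#' @export
splitQuarters <- function(img) {
  px <- pixels(img); lb <- labelMap(img)
  H <- dim(px)[1]; W <- dim(px)[2]
  stopifnot(H >= 2, W >= 2)
  h2 <- H %/% 2; w2 <- W %/% 2
  rows <- list(seq_len(h2), (h2 + 1):H)
  cols <- list(seq_len(w2), (w2 + 1):W)
  tiles <- list()
  for (r in 1:2) for (cl in 1:2) {
    tiles[[length(tiles) + 1]] <- LabeledImage(
      pixels = px[rows[[r]], cols[[cl]], , drop = FALSE],
      labels = relabelConsecutive(lb[rows[[r]], cols[[cl]], drop = FALSE]),
      channelRoles = channelRoles(img),
      pixelSize = img@pixelSize,
      sourceId = sprintf("%s_q%d%d", img@sourceId, r, cl)
    )
  }
  tiles
}

#' Local-contrast enhancement by smoothed-image division
#'
#' Subtracts and divides by a Gaussian-smoothed version of the image:
#' `(I - G*I) / (G*I)`, with the denominator floored at `1e-6 * max(I)` so an
#' all-zero image maps to all zeros. The default kernel width is 30 pixels
#' (interpreted as the Gaussian sigma).
#'
#' @param img intensity matrix.
#' @param sigma Gaussian kernel width in pixels (default 30).
#' @return matrix of contrast-enhanced intensities (mean ~0 for slowly
#'   varying images).
#' @export
enhanceContrast <- function(img, sigma = 30) {
  stopifnot(is.matrix(img))
  s <- gaussSmooth(img, sigma)
  eps <- 1e-6 * max(img, 0)
  if (eps == 0) return(matrix(0, nrow(img), ncol(img)))
  (img - s) / pmax(s, eps)
}

#' Mirror an image and its labels along both axes
#'
#' Applying it twice is the identity; ROI pixel counts are unchanged.
#'
#' @param img a [LabeledImage-class].
#' @return the mirrored `LabeledImage`.
#' @export
mirrorImage <- function(img) {
  px <- pixels(img); lb <- labelMap(img)
  H <- dim(px)[1]; W <- dim(px)[2]
  px <- px[H:1, W:1, , drop = FALSE]
  lb <- lb[H:1, W:1, drop = FALSE]
  rd <- roiData(img)
  if (nrow(rd) && all(c("cy", "cx") %in% names(rd))) {
    rd$cy <- H + 1 - rd$cy
    rd$cx <- W + 1 - rd$cx
  }
  LabeledImage(px, lb, channelRoles(img), img@pixelSize,
               img@sourceId, rd)
}

#' Drop images with too few ROI
#'
#' Training protocols exclude images with fewer than five ROI; this filter
#' applies that rule (order preserved).
#'
#' @param images list of [LabeledImage-class].
#' @param minRois minimum ROI count to keep an image (default 5).
#' @return filtered list.
#' @export
filterMinRois <- function(images, minRois = 5) {
  Filter(function(im) roiCount(im) >= minRois, images)
}

#' Write a dataset manifest
#'
#' A plain-text JSON file listing (image path, label path, channel roles)
#' triples.
#'
#' @param entries list of lists with elements `image`, `labels`,
#'   `channelRoles`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(entries, path) {
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest written by [writeManifest()]
#' @param path JSON manifest path.
#' @return list of entries.
#' @export
readManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
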