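#' @useDynLib flowseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' LabeledImage: an image with an instance label map
#'
#' The universal training/evaluation record: a (possibly multi-channel)
#' intensity image together with an integer instance label map on the same
#' canvas. Label id 0 is background; every positive id is one ROI (one cell
#' instance). Ids need not be contiguous but every present id must own at
#' least one pixel.
#'
#' @slot pixels numeric array `H x W x C` of intensities (arbitrary dynamic
#'   range; normalization happens at model input).
#' @slot labels integer matrix `H x W`, `0` = background.
#' @slot channelRoles character vector of length `C` with entries from
#'   `"cytoplasm"`, `"nucleus"`, `"none"`.
#' @slot pixelSize numeric(1), microns per pixel (`NA` if unknown).
#' @slot sourceId character(1) identifier.
#' @slot roiData data.frame of per-ROI metadata (may be empty). When produced
#'   by [generateScene()] it carries `id`, `orphan` (nucleus without
#'   cytoplasm), centroid coordinates and mean intensity.
#'
#' @seealso [LabeledImage()] for the constructor, [generateScene()],
#'   [readLabelMap()]
#' @export
setClass("LabeledImage",
  representation(
    pixels = "array",
    labels = "matrix",
    channelRoles = "character",
    pixelSize = "numeric",
    sourceId = "character",
    roiData = "data.frame"
  ),
  prototype(
    pixelSize = NA_real_,
    sourceId = "",
    roiData = data.frame()
  )
)

setValidity("LabeledImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L)
    msg <- c(msg, "pixels must be an H x W x C array")
  if (!all(dim(object@labels) == d[1:2]))
    msg <- c(msg, "labels and pixels must share spatial shape")
  if (length(object@channelRoles) != d[3])
    msg <- c(msg, "channelRoles must have one entry per channel")
  if (!all(object@channelRoles %in% c("cytoplasm", "nucleus", "none")))
    msg <- c(msg, "channelRoles must be cytoplasm/nucleus/none")
  if (any(object@labels < 0))
    msg <- c(msg, "labels must be >= 0 everywhere")
  if (any(object@labels != floor(object@labels)))
    msg <- c(msg, "labels must be integer-valued")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledImage
#'
#' @param pixels matrix (single channel) or `H x W x C` array of intensities.
#' @param labels integer matrix of instance labels (0 = background). Defaults
#'   to an all-background map.
#' @param channelRoles character vector of channel roles; defaults to
#'   `"cytoplasm"` for the first channel, `"nucleus"` for a second one.
#' @param pixelSize microns per pixel, optional.
#' @param sourceId identifier string.
#' @param roiData optional per-ROI metadata data.frame.
#' @return A [LabeledImage-class] object.
#' @examples
#' img <- LabeledImage(matrix(runif(64), 8, 8),
#'                     matrix(c(rep(0L, 60), rep(1L, 4)), 8, 8))
#' roiCount(img)
#' @export
LabeledImage <- function(pixels, labels = NULL, channelRoles = NULL,
                         pixelSize = NA_real_, sourceId = "",
                         roiData = data.frame()) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (is.null(labels))
    labels <- matrix(0L, dim(pixels)[1], dim(pixels)[2])
  storage.mode(labels) <- "integer"
  if (is.null(channelRoles)) {
    channelRoles <- switch(as.character(dim(pixels)[3]),
      "1" = "cytoplasm",
      "2" = c("cytoplasm", "nucleus"),
      rep("none", dim(pixels)[3])
    )
  }
  new("LabeledImage", pixels = pixels, labels = labels,
      channelRoles = channelRoles, pixelSize = pixelSize,
      sourceId = sourceId, roiData = roiData)
}

#' FlowTarget: per-pixel flow field plus inside-cell map
#'
#' The regression target of the network and the substrate of mask
#' reconstruction: unit vectors pointing toward the centre of the ROI that
#' owns each pixel (zero on background), and an inside-cell indicator or
#' probability map.
#'
#' @slot flowY,flowX numeric matrices with the vector components
#'   (row direction, column direction).
#' @slot insideProb numeric matrix in `[0, 1]`.
#' @seealso [masksToFlows()], [followFlows()]
#' @export
setClass("FlowTarget",
  representation(flowY = "matrix", flowX = "matrix", insideProb = "matrix")
)

setValidity("FlowTarget", function(object) {
  msg <- character()
  if (!all(dim(object@flowY) == dim(object@flowX)) ||
      !all(dim(object@flowY) == dim(object@insideProb)))
    msg <- c(msg, "flowY, flowX and insideProb must share shape")
  mag2 <- object@flowY^2 + object@flowX^2
  if (any(mag2 > (1 + 1e-6)^2))
    msg <- c(msg, "flow magnitude must be <= 1")
  if (any(object@insideProb < 0 | object@insideProb > 1))
    msg <- c(msg, "insideProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' StyleClustering: a Leiden partition of style vectors
#'
#' @slot styles numeric matrix, one style vector per row (L2-normalized).
#' @slot clusterIds integer vector of cluster ids, contiguous from 0.
#' @slot nNeighbors,resolution,seed clustering parameters as used.
#' @seealso [clusterStyles()], [assignCluster()]
#' @export
setClass("StyleClustering",
  representation(
    styles = "matrix",
    clusterIds = "integer",
    nNeighbors = "integer",
    resolution = "numeric",
    seed = "integer"
  )
)

setValidity("StyleClustering", function(object) {
  msg <- character()
  if (nrow(object@styles) != length(object@clusterIds))
    msg <- c(msg, "one cluster id per style vector required")
  ids <- sort(unique(object@clusterIds))
  if (length(ids) && !identical(ids, seq_along(ids) - 1L))
    msg <- c(msg, "cluster ids must be contiguous from 0")
  if (length(msg)) msg else TRUE
})

#' ModelZoo: per-style specialist models plus a K-NN router
#'
#' One trained checkpoint per style cluster; queries are routed by extracting
#' the query's style vector and taking a majority vote among its `k = 5`
#' nearest clustering members (Euclidean distance).
#'
#' @slot clustering the [StyleClustering-class] whose members the router uses.
#' @slot checkpoints list of checkpoints, one per cluster id (in id order).
#' @slot k integer, number of neighbours for routing (default 5).
#' @seealso [buildZoo()], [suggestModel()], [segmentWithEnsemble()]
#' @export
setClass("ModelZoo",
  representation(
    clustering = "StyleClustering",
    checkpoints = "list",
    k = "integer"
  ),
  prototype(k = 5L)
)

setValidity("ModelZoo", function(object) {
  nclust <- length(unique(object@clustering@clusterIds))
  if (length(object@checkpoints) != nclust)
    return("need exactly one checkpoint per cluster id")
  TRUE
})

# ---- accessors -------------------------------------------------------------

#' @describeIn LabeledImage-class the intensity array (`H x W x C`)
#' @param object a `LabeledImage`
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @export
setMethod("pixels", "LabeledImage", function(object) object@pixels)

#' @describeIn LabeledImage-class the instance label matrix
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @export
setMethod("labelMap", "LabeledImage", function(object) object@labels)

#' @describeIn LabeledImage-class channel role tags
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))
#' @export
setMethod("channelRoles", "LabeledImage", function(object) object@channelRoles)

#' @describeIn LabeledImage-class per-ROI metadata data.frame
#' @export
setGeneric("roiData", function(object) standardGeneric("roiData"))
#' @export
setMethod("roiData", "LabeledImage", function(object) object@roiData)

#' Number of ROI in a label map or LabeledImage
#'
#' @param object a `LabeledImage` or an integer label matrix
#' @return integer count of distinct positive label ids
#' @export
setGeneric("roiCount", function(object) standardGeneric("roiCount"))
#' @export
setMethod("roiCount", "LabeledImage",
          function(object) roiCount(object@labels))
#' @export
setMethod("roiCount", "matrix",
          function(object) length(roiIds(object)))

#' Distinct positive label ids of a label map
#' @param labels integer label matrix or `LabeledImage`
#' @return sorted integer vector of ROI ids
#' @export
roiIds <- function(labels) {
  if (is(labels, "LabeledImage")) labels <- labels@labels
  ids <- sort(unique(as.integer(labels)))
  ids[ids > 0L]
}

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("LabeledImage %dx%d, %d channel(s) [%s], %d ROI%s\n",
              d[1], d[2], d[3], paste(object@channelRoles, collapse = ","),
              roiCount(object),
              if (nzchar(object@sourceId))
                paste0(", source=", object@sourceId) else ""))
})

setMethod("show", "FlowTarget", function(object) {
  d <- dim(object@flowY)
  cat(sprintf("FlowTarget %dx%d, %.0f inside pixels\n",
              d[1], d[2], sum(object@insideProb > 0.5)))
})

setMethod("show", "StyleClustering", function(object) {
  cat(sprintf("StyleClustering: %d styles (dim %d) in %d clusters (resolution %.2f, %d neighbours)\n",
              nrow(object@styles), ncol(object@styles),
              length(unique(object@clusterIds)),
              object@resolution, object@nNeighbors))
})

setMethod("show", "ModelZoo", function(object) {
  cat(sprintf("ModelZoo: %d specialist model(s), %d routing members, k=%d\n",
              length(object@checkpoints), nrow(object@clustering@styles),
              object@k))
})
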