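#' Segment an image with a trained model
#'
#' Runs the full inference pipeline: channel matching and percentile
#' normalization, optional rescaling so objects match the model's native
#' diameter, padding to the network stride, the forward pass, mask
#' reconstruction by flow following, and the flow-error quality-control
#' filter (default threshold 0.4). Masks are mapped back to the original
#' frame when the image was rescaled.
#'
#' @param net a trained checkpoint (or untrained `flowsegNet`).
#' @param img a [LabeledImage-class] or intensity array.
#' @param diameter estimated object diameter of `img`; when given together
#'   with a model that knows its native diameter, the image is rescaled
#'   before segmentation (the protocol used for cross-domain evaluation).
#' @param probThreshold inside-probability threshold (default 0.5).
#' @param qc a [qcConfig()].
#' @param nSteps Euler steps for flow following (default 200).
#' @return list with `labels` (integer instance map), `prob`, `flowY`,
#'   `flowX` (cropped prediction maps), `style` (style vector) and
#'   `flowErrors` (per-ROI QC scores before filtering).
#' @export
segmentImage <- function(net, img, diameter = NULL, probThreshold = 0.5,
                         qc = qcConfig(), nSteps = 200) {
  if (!is(img, "LabeledImage")) {
    px <- if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
    img <- LabeledImage(px)
  }
  H0 <- dim(pixels(img))[1]; W0 <- dim(pixels(img))[2]
  work <- img
  rescaled <- FALSE
  if (!is.null(diameter) && !is.null(net$modelDiameter)) {
    f <- net$modelDiameter / diameter
    if (abs(log(f)) > log(1.05)) {
      work <- resizeForDiameter(img, diameter, net$modelDiameter)
      rescaled <- TRUE
    }
  }
  pp <- prepInput(net, work)
  fw <- netForward(net, pp$x)
  maps <- fw$maps[seq_len(pp$H), seq_len(pp$W), , drop = FALSE]
  amp <- if (!is.null(net$trainCfg)) net$trainCfg$flowAmplitude else 5
  prob <- 1 / (1 + exp(-maps[, , 1]))
  fy <- maps[, , 2] / amp
  fx <- maps[, , 3] / amp
  masks <- followFlows(list(flowY = fy, flowX = fx, insideProb = prob),
                       probThreshold = probThreshold, nSteps = nSteps,
                       qc = qc)
  errs <- flowError(list(flowY = fy, flowX = fx), masks)
  bad <- as.integer(names(errs)[errs > qc$flowErrorThreshold])
  if (length(bad)) masks[masks %in% bad] <- 0L
  masks <- relabelConsecutive(masks)
  if (rescaled) masks <- resizeLabelsTo(masks, H0, W0)
  list(labels = masks, prob = prob, flowY = fy, flowX = fx,
       style = fw$style, flowErrors = errs)
}
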