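#' Cluster style vectors into segmentation-style groups
#'
#' Builds a K-nearest-neighbour graph on Euclidean distances between style
#' vectors and partitions it with the Leiden algorithm. The protocol
#' defaults are 100 neighbours and resolution 0.45 (the neighbour count is
#' capped at `n - 1` for small sets). Deterministic under `seed`.
#'
#' @param styles numeric matrix, one style vector per row (or list of
#'   vectors).
#' @param nNeighbors neighbours for the K-NN graph (default 100).
#' @param resolution Leiden resolution parameter (default 0.45).
#' @param seed RNG seed.
#' @return a [StyleClustering-class] with contiguous cluster ids from 0.
#' @export
clusterStyles <- function(styles, nNeighbors = 100, resolution = 0.45,
                          seed = 0L) {
  if (is.list(styles)) styles <- do.call(rbind, styles)
  n <- nrow(styles)
  if (n < 2) stop("need at least 2 style vectors to cluster")
  k <- min(nNeighbors, n - 1)
  d <- as.matrix(stats::dist(styles))
  # locally scaled Gaussian edge weights keep the partition meaningful even
  # when the neighbour cap makes the graph (nearly) complete on small sets
  sigma <- vapply(seq_len(n), function(i)
    sort(d[i, -i])[max(1L, ceiling(k / 3))], 0)
  sigma <- pmax(sigma, 1e-12)
  edges <- integer(0); weights <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    edges <- c(edges, rbind(i, nb))
    weights <- c(weights, exp(-d[i, nb]^2 / (sigma[i] * sigma[nb])))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::E(g)$weight <- weights
  g <- igraph::simplify(g, edge.attr.comb = "max")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               weights = igraph::E(g)$weight,
                               resolution = resolution, n_iterations = 10)
  mem <- igraph::membership(cl)
  ids <- as.integer(match(mem, unique(mem)) - 1L)  # contiguous, first-seen
  new("StyleClustering", styles = styles, clusterIds = ids,
      nNeighbors = as.integer(k), resolution = resolution,
      seed = as.integer(seed))
}

#' Assign a style vector to an existing cluster
#'
#' Majority vote among the five nearest clustering members (Euclidean
#' distance); vote ties break deterministically to the lowest cluster id
#' among the tied clusters.
#'
#' @param clustering a [StyleClustering-class].
#' @param style numeric style vector.
#' @param k neighbours to vote (default 5, capped at the member count).
#' @return integer cluster id.
#' @export
assignCluster <- function(clustering, style, k = 5) {
  st <- clustering@styles
  n <- nrow(st)
  if (n < 1) stop("empty clustering")
  k <- min(k, n)
  d2 <- colSums((t(st) - style)^2)
  nb <- order(d2)[seq_len(k)]
  votes <- table(clustering@clusterIds[nb])
  winners <- as.integer(names(votes)[votes == max(votes)])
  min(winners)
}

#' Train one specialist model per style cluster
#'
#' Each cluster's model is trained only on the images assigned to that
#' cluster, sampled with equal probability within the cluster; the router is
#' the clustering's own members.
#'
#' @param clustering a [StyleClustering-class].
#' @param datasets list of image lists, one per cluster id (in id order).
#' @param cfg a [trainConfig()].
#' @param netCfg a [netConfig()] for scratch initialization.
#' @param init `"scratch"` or a pretrained checkpoint shared by all
#'   specialists.
#' @return a [ModelZoo-class].
#' @export
buildZoo <- function(clustering, datasets, cfg = trainConfig("online"),
                     netCfg = netConfig(), init = "scratch") {
  nclust <- length(unique(clustering@clusterIds))
  stopifnot(length(datasets) == nclust)
  ckpts <- vector("list", nclust)
  for (ci in seq_len(nclust)) {
    imgs <- filterMinRois(datasets[[ci]])
    if (!length(imgs))
      stop("cluster ", ci - 1L, " has no usable training image")
    cfgC <- cfg
    cfgC$seed <- subSeed(cfg$seed, ci)
    ncfgC <- netCfg
    ncfgC$seed <- subSeed(netCfg$seed, ci)
    ckpts[[ci]] <- trainModel(init, imgs, cfgC, ncfgC)
  }
  new("ModelZoo", clustering = clustering, checkpoints = ckpts, k = 5L)
}

#' Suggest the best-matching zoo model for an image
#'
#' Extracts the image's style vector, routes it with the zoo's K-NN
#' classifier and returns that cluster's checkpoint. A pure function of
#' (zoo, image, style network): identical inputs give identical suggestions.
#'
#' @param zoo a [ModelZoo-class].
#' @param img a [LabeledImage-class] or intensity array.
#' @param styleNet the network used to extract style vectors.
#' @return list with `clusterId` and `checkpoint`.
#' @export
suggestModel <- function(zoo, img, styleNet) {
  s <- extractStyle(styleNet, img)
  cid <- assignCluster(zoo@clustering, s, zoo@k)
  list(clusterId = cid, checkpoint = zoo@checkpoints[[cid + 1L]])
}

#' Segment a test set with the routed ensemble
#'
#' Each image is routed to its style cluster's specialist model and segmented
#' by it; the routing decisions are logged (one row per image).
#'
#' @param zoo a [ModelZoo-class].
#' @param images list of images.
#' @param styleNet network used for routing.
#' @param ... passed to [segmentImage()].
#' @return list with `labels` (list of instance maps) and `log`
#'   (data.frame `image`, `clusterId`).
#' @export
segmentWithEnsemble <- function(zoo, images, styleNet, ...) {
  labels <- vector("list", length(images))
  cid <- integer(length(images))
  for (i in seq_along(images)) {
    sug <- suggestModel(zoo, images[[i]], styleNet)
    cid[i] <- sug$clusterId
    labels[[i]] <- segmentImage(sug$checkpoint, images[[i]], ...)$labels
  }
  list(labels = labels, log = data.frame(image = seq_along(images),
                                         clusterId = cid))
}
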