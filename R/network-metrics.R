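#' FDR-thresholded adjacency matrix from correlations
#'
#' Per-edge p-values come from the correlation-to-t transform
#' (`t = r * sqrt((n-2)/(1-r^2))`, `n - 2` degrees of freedom,
#' two-sided); Benjamini-Hochberg step-up at level `alpha` is applied
#' over the `n(n-1)/2` unique edges. Surviving edges keep their signed
#' correlation weight; everything else is zeroed.
#'
#' @param corrMatrix symmetric correlation matrix (|r| <= 1).
#' @param nSamples observations behind each correlation (>= 4).
#' @param alpha FDR level (default 0.05).
#' @param nodeMeta optional per-node metadata carried on the result.
#' @return an [AdjacencyMatrix-class].
#' @export
fdrThresholdAdjacency <- function(corrMatrix, nSamples, alpha = 0.05,
                                  nodeMeta = data.frame()) {
  R <- unname(as.matrix(corrMatrix))
  if (!isSymmetric(R, tol = 1e-8)) stop("corrMatrix must be symmetric")
  if (max(abs(R[upper.tri(R)])) > 1 + 1e-12)
    stop("correlations must satisfy |r| <= 1")
  if (nSamples < 4) stop("nSamples must be >= 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  p <- nrow(R)
  r <- pmin(pmax(R[upper.tri(R)], -1), 1)
  tstat <- ifelse(abs(r) >= 1, Inf,
                  r * sqrt((nSamples - 2) / (1 - r^2)))
  pval <- 2 * stats::pt(-abs(tstat), df = nSamples - 2)
  padj <- stats::p.adjust(pval, method = "BH")
  keep <- padj < alpha
  mask <- matrix(FALSE, p, p)
  mask[upper.tri(mask)] <- keep
  mask <- mask | t(mask)
  W <- R
  diag(W) <- 0
  W[!mask] <- 0
  new("AdjacencyMatrix", weights = W, mask = mask,
      nodeMeta = nodeMeta, nSamples = as.numeric(nSamples))
}

adjacencyToBinary <- function(adj) {
  A <- if (is(adj, "AdjacencyMatrix")) 1 * adj@mask
  else 1 * (unname(as.matrix(adj)) != 0)
  diag(A) <- 0
  A
}

#' Local clustering coefficient
#'
#' For each node `i` with degree `k_i >= 2`,
#' `C_i = 2 * (edges among neighbours of i) / (k_i * (k_i - 1))`;
#' nodes with degree < 2 get `C_i = 0` (documented convention, the
#' defining ratio is undefined there). A high `C_i` means the
#' neighbourhood of `i` is itself densely connected (local efficiency).
#'
#' @param adj binary symmetric adjacency ([AdjacencyMatrix-class] or
#'   0/1 matrix; weighted input is binarized on the surviving mask).
#' @return list with `perNode` and `mean`.
#' @export
clusteringCoefficient <- function(adj) {
  A <- adjacencyToBinary(adj)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0   # degree-1 nodes
  list(perNode = cc, mean = mean(cc))
}

#' Average shortest path length and global efficiency
#'
#' `d(i, j)` is the unweighted shortest hop count; the path length is
#' the mean of `d(i, j)` over all ordered reachable pairs `i != j`, and
#' global efficiency is its reciprocal. On a fully connected network the
#' path length is exactly 1. For disconnected graphs the mean is
#' restricted to reachable pairs and the reachable fraction is reported
#' alongside; with no edges the path length is `NA`.
#'
#' @param adj binary symmetric adjacency (see [clusteringCoefficient()]).
#' @return list with `pathLength`, `globalEfficiency`,
#'   `reachabilityFraction`.
#' @export
averagePathLength <- function(adj) {
  A <- adjacencyToBinary(adj)
  n <- nrow(A)
  if (n < 2) stop("need >= 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(g)
  off <- D[row(D) != col(D)]
  reachable <- is.finite(off)
  frac <- mean(reachable)
  if (!any(reachable))
    return(list(pathLength = NA_real_, globalEfficiency = NA_real_,
                reachabilityFraction = 0))
  pl <- mean(off[reachable])
  list(pathLength = pl, globalEfficiency = 1 / pl,
       reachabilityFraction = frac)
}

#' Network strength and distance-weighted cost
#'
#' Network strength is the sum of absolute edge weights over unique
#' surviving edges; node strength sums the absolute weights incident to
#' each node. The cost of an edge is the Euclidean distance (mm) between
#' the centroids of the nodes it connects times the absolute weight;
#' network cost sums edge costs and node cost sums incident edge costs
#' (so node costs sum to twice the network cost).
#'
#' @param adj an [AdjacencyMatrix-class] (weights + metadata), or a
#'   weighted symmetric matrix with `nodeMeta` supplied separately.
#' @param nodeMeta data.frame with `x`, `y`, `z` centroid columns; taken
#'   from `adj` when absent.
#' @return list with `networkStrength`, `nodeStrength`, `networkCost`,
#'   `nodeCost`, `degree`.
#' @export
strengthAndCost <- function(adj, nodeMeta = NULL) {
  if (is(adj, "AdjacencyMatrix")) {
    W <- adj@weights
    if (is.null(nodeMeta)) nodeMeta <- adj@nodeMeta
  } else W <- unname(as.matrix(adj))
  p <- nrow(W)
  if (is.null(nodeMeta) || !nrow(nodeMeta))
    stop("node centroid metadata required for network cost")
  if (!all(c("x", "y", "z") %in% names(nodeMeta)))
    stop("nodeMeta needs x, y, z centroid columns")
  if (nrow(nodeMeta) != p) stop("nodeMeta rows must equal node count")
  bad <- which(!stats::complete.cases(nodeMeta[, c("x", "y", "z")]))
  if (length(bad))
    stop("missing centroid coordinates for node ",
         paste(if (!is.null(nodeMeta$node)) nodeMeta$node[bad] else bad,
               collapse = ", "))
  xyz <- as.matrix(nodeMeta[, c("x", "y", "z")])
  Dist <- as.matrix(stats::dist(xyz))
  absW <- abs(W)
  cost <- Dist * absW
  list(networkStrength = sum(absW[upper.tri(absW)]),
       nodeStrength = rowSums(absW),
       networkCost = sum(cost[upper.tri(cost)]),
       nodeCost = rowSums(cost),
       degree = rowSums(W != 0))
}

#' Identify hub nodes
#'
#' Hubs are nodes whose metric exceeds the sample mean by more than
#' `sdMultiplier` sample standard deviations (n - 1 denominator). With
#' zero variance no hubs exist (warning).
#'
#' @param nodeMetric numeric node metric vector (degree, strength,
#'   cost, ...), length >= 3, finite.
#' @param sdMultiplier threshold multiplier (default 1.5).
#' @param nodeNames optional names for the returned set.
#' @return integer indices (named if `nodeNames` given) of hub nodes.
#' @export
identifyHubs <- function(nodeMetric, sdMultiplier = 1.5, nodeNames = NULL) {
  if (length(nodeMetric) < 3) stop("need >= 3 nodes")
  if (any(!is.finite(nodeMetric))) stop("node metric must be finite")
  s <- stats::sd(nodeMetric)
  if (s == 0) {
    warning("zero variance in node metric; no hubs identified")
    return(integer(0))
  }
  idx <- which(nodeMetric > mean(nodeMetric) + sdMultiplier * s)
  if (!is.null(nodeNames)) names(idx) <- nodeNames[idx]
  idx
}

#' State centroid as a weighted graph
#'
#' Unvectorizes a state centroid (edge vector) into a symmetric weighted
#' adjacency matrix and applies an edge-retention rule, so state-level
#' graph metrics can be computed on cluster centroids.
#'
#' @param centroidEdges edge vector of length `n(n-1)/2`.
#' @param nodeMeta per-node metadata (row count fixes `n`).
#' @param rule list: `list(type = "abs", cutoff = w)` keeps edges with
#'   `|w_ij| > cutoff`; `list(type = "top_frac", frac = f)` keeps the
#'   `ceiling(f * nEdges)` largest `|w|` edges; `list(type = "none")`
#'   keeps every nonzero edge.
#' @return an [AdjacencyMatrix-class] (the rule is recorded as the
#'   `"thresholdRule"` attribute).
#' @export
centroidToStateGraph <- function(centroidEdges, nodeMeta,
                                 rule = list(type = "none")) {
  p <- nrow(nodeMeta)
  if (length(centroidEdges) != p * (p - 1) / 2)
    stop("centroid length does not match node count from nodeMeta")
  W <- upperTriMat(as.numeric(centroidEdges), p)
  keepUT <- switch(rule$type,
    none = upperTriVec(W) != 0,
    abs = abs(upperTriVec(W)) > rule$cutoff,
    top_frac = {
      v <- abs(upperTriVec(W))
      nKeep <- ceiling(rule$frac * length(v))
      v >= sort(v, decreasing = TRUE)[nKeep] & v > 0
    },
    stop("unknown threshold rule: ", rule$type))
  mask <- matrix(FALSE, p, p)
  mask[upper.tri(mask)] <- keepUT
  mask <- mask | t(mask)
  W[!mask] <- 0
  out <- new("AdjacencyMatrix", weights = W, mask = mask,
             nodeMeta = nodeMeta, nSamples = NA_real_)
  attr(out, "thresholdRule") <- rule
  out
}

#' All graph metrics for one adjacency matrix
#'
#' Binary metrics (clustering coefficient, path length, efficiency,
#' total connections) are computed on the surviving-edge mask; strength
#' and distance-weighted cost on the retained signed weights through
#' their absolute value.
#'
#' @param adj an [AdjacencyMatrix-class].
#' @param sdMultiplier hub threshold (default 1.5 SD above the mean).
#' @param hubMetric which node metric defines hubs: `"degree"`,
#'   `"strength"` or `"cost"` (default `"cost"`).
#' @return list of metrics (see [clusteringCoefficient()],
#'   [averagePathLength()], [strengthAndCost()], [identifyHubs()]).
#' @export
graphMetrics <- function(adj, sdMultiplier = 1.5,
                         hubMetric = c("cost", "strength", "degree")) {
  stopifnot(is(adj, "AdjacencyMatrix"))
  hubMetric <- match.arg(hubMetric)
  cc <- clusteringCoefficient(adj)
  pl <- averagePathLength(adj)
  sc <- strengthAndCost(adj)
  metricVec <- switch(hubMetric, cost = sc$nodeCost,
                      strength = sc$nodeStrength, degree = sc$degree)
  hubs <- if (stats::sd(metricVec) > 0)
    identifyHubs(metricVec, sdMultiplier,
                 nodeNames = adj@nodeMeta$node) else integer(0)
  list(ccPerNode = cc$perNode, meanCC = cc$mean,
       pathLength = pl$pathLength,
       globalEfficiency = pl$globalEfficiency,
       reachabilityFraction = pl$reachabilityFraction,
       totalConnections = sum(adj@mask[upper.tri(adj@mask)]),
       networkStrength = sc$networkStrength,
       nodeStrength = sc$nodeStrength,
       networkCost = sc$networkCost, nodeCost = sc$nodeCost,
       degree = sc$degree, hubMetric = hubMetric, hubs = hubs)
}
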