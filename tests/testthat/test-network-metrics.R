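test_that("FDR thresholding matches a brute-force BH oracle", {
  set.seed(21)
  n <- 120
  for (i in 1:5) {
    p <- 6
    R <- cor(matrix(rnorm(40 * p), 40, p))   # arbitrary correlation matrix
    adj <- fdrThresholdAdjacency(R, nSamples = n, alpha = 0.05)
    ## independent long-form computation
    r <- R[upper.tri(R)]
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    pv <- 2 * pt(-abs(tstat), df = n - 2)
    expect_equal(adjMask(adj)[upper.tri(R)], bfBH(pv, 0.05))
  }
  ## null input yields the empty graph
  z <- fdrThresholdAdjacency(diag(4), nSamples = 100)
  expect_equal(sum(adjMask(z)), 0)
  expect_equal(adjWeights(z), matrix(0, 4, 4))
  ## a single strong edge survives alone
  R1 <- diag(5); R1[1, 2] <- R1[2, 1] <- 0.99
  adj1 <- fdrThresholdAdjacency(R1, nSamples = 240)
  expect_equal(which(adjMask(adj1)[upper.tri(R1)]),
               which(upper.tri(R1)[upper.tri(R1)] &
                       abs(R1[upper.tri(R1)]) > 0))
  expect_equal(adjWeights(adj1)[1, 2], 0.99)
  expect_error(fdrThresholdAdjacency(R1, nSamples = 3), ">= 4")
})

test_that("BH step-up rejects exactly the sorted-threshold set", {
  expect_equal(bfBH(c(0.001, 0.02, 0.03, 0.9), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(stats::p.adjust(c(0.001, 0.02, 0.03, 0.9), "BH") < 0.05,
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("lowering alpha never adds surviving edges", {
  set.seed(3)
  R <- cor(matrix(rnorm(30 * 8), 30, 8))
  masks <- lapply(c(0.2, 0.1, 0.05, 0.01), function(a)
    adjMask(fdrThresholdAdjacency(R, 30, alpha = a)))
  for (i in 1:3)
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
})

test_that("clustering coefficient matches brute-force triangle counting", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(clusteringCoefficient(tri)$perNode, rep(1, 3))
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  cc <- clusteringCoefficient(star)
  expect_equal(cc$perNode[1], 0)       # hub with unconnected neighbours
  expect_equal(cc$perNode[2:5], rep(0, 4))  # degree-1 convention
  set.seed(14)
  for (i in 1:10) {
    p <- sample(5:9, 1)
    A <- matrix(0, p, p)
    A[upper.tri(A)] <- rbinom(p * (p - 1) / 2, 1, runif(1, 0.2, 0.8))
    A <- A + t(A)
    expect_equal(clusteringCoefficient(A)$perNode,
                 bfClusteringCoefficient(A))
  }
})

test_that("average path length matches all-pairs oracles and the
          complete-graph limit", {
  full <- matrix(1, 44, 44) - diag(44)
  pl <- averagePathLength(full)
  expect_identical(pl$pathLength, 1)
  expect_identical(pl$globalEfficiency, 1)
  expect_equal(pl$reachabilityFraction, 1)
  ## hand enumeration on the path graph 1-2-3
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  chain <- chain + t(chain)
  expect_equal(averagePathLength(chain)$pathLength, 4 / 3)
  ## disconnected 8-node graphs against Floyd-Warshall
  set.seed(8)
  for (i in 1:10) {
    A <- matrix(0, 8, 8)
    A[upper.tri(A)] <- rbinom(28, 1, 0.25)
    A <- A + t(A)
    got <- averagePathLength(A)
    ref <- bfPathLength(A)
    expect_equal(got$pathLength, ref$pathLength)
    expect_equal(got$reachabilityFraction, ref$reachabilityFraction)
  }
  ## edgeless graph
  none <- averagePathLength(matrix(0, 4, 4))
  expect_true(is.na(none$pathLength))
  expect_equal(none$reachabilityFraction, 0)
})

test_that("strength and distance-weighted cost follow their definitions", {
  nm <- data.frame(node = c("a", "b", "c"), network = "X",
                   x = c(0, 30, 0), y = c(0, 0, 40), z = c(0, 0, 0))
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- -0.5
  sc <- strengthAndCost(W, nm)
  expect_equal(sc$networkStrength, 0.5)
  expect_equal(sc$networkCost, 15)     # 30 mm x |-0.5|
  expect_equal(unname(sc$nodeCost), c(15, 15, 0))
  expect_equal(sum(sc$nodeCost), 2 * sc$networkCost)
  ## all-zero weights
  sc0 <- strengthAndCost(matrix(0, 3, 3), nm)
  expect_equal(sc0$networkStrength, 0)
  expect_equal(sc0$networkCost, 0)
  ## 4-node toy against an explicit loop computation
  set.seed(5)
  nm4 <- tinyNodeMeta(4)
  W4 <- matrix(0, 4, 4)
  W4[upper.tri(W4)] <- round(runif(6, -1, 1), 2)
  W4 <- W4 + t(W4)
  sc4 <- strengthAndCost(W4, nm4)
  xyz <- as.matrix(nm4[, c("x", "y", "z")])
  manualCost <- 0; manualNode <- numeric(4)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    manualCost <- manualCost + d * abs(W4[i, j])
    manualNode[i] <- manualNode[i] + d * abs(W4[i, j])
    manualNode[j] <- manualNode[j] + d * abs(W4[i, j])
  }
  expect_equal(sc4$networkCost, manualCost, tolerance = 1e-12)
  expect_equal(unname(sc4$nodeCost), manualNode, tolerance = 1e-12)
  expect_equal(sc4$networkStrength, sum(abs(W4[upper.tri(W4)])),
               tolerance = 1e-12)
  ## rigid motion of the centroids leaves cost unchanged
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  nmR <- nm4
  nmR[, c("x", "y", "z")] <- xyz %*% Rz + rep(c(5, -3, 2), each = 4)
  expect_equal(strengthAndCost(W4, nmR)$networkCost, sc4$networkCost,
               tolerance = 1e-10)
  ## missing coordinates are a named error
  nmBad <- nm4; nmBad$x[2] <- NA
  expect_error(strengthAndCost(W4, nmBad), "N02")
})

test_that("hub identification applies the mean + 1.5 SD rule", {
  v <- c(1, 1, 1, 1, 10)
  ## arithmetic oracle: mean 2.8, sd 4.0249, threshold 8.8373
  expect_equal(mean(v) + 1.5 * sd(v), 8.8373, tolerance = 1e-4)
  expect_equal(identifyHubs(v), 5L)
  expect_equal(identifyHubs(v * 3.7), 5L)   # scale invariance
  expect_equal(identifyHubs(v, nodeNames = letters[1:5]),
               c(e = 5L))
  expect_warning(h <- identifyHubs(rep(2, 5)), "zero variance")
  expect_length(h, 0)
  expect_error(identifyHubs(c(1, 2)), ">= 3")
  expect_error(identifyHubs(c(1, 2, Inf)), "finite")
})

test_that("centroid vectors round-trip into state graphs", {
  nm <- tinyNodeMeta(5)
  expect_equal(sum(adjMask(centroidToStateGraph(rep(0, 10), nm))), 0)
  set.seed(6)
  W <- matrix(0, 5, 5)
  W[upper.tri(W)] <- rnorm(10)
  W <- W + t(W)
  adj <- centroidToStateGraph(upperTriVec(W), nm)
  expect_equal(adjWeights(adj), W, tolerance = 1e-15)
  ## top-10% rule keeps exactly ceiling(0.1 * nEdges) edges
  v <- rnorm(10)
  adjT <- centroidToStateGraph(v, nm, rule = list(type = "top_frac",
                                                  frac = 0.1))
  expect_equal(sum(adjMask(adjT)[upper.tri(adjMask(adjT))]),
               ceiling(0.1 * 10))
  ## retained edges are the largest in magnitude
  kept <- upperTriVec(adjWeights(adjT))
  expect_equal(which(kept != 0), which.max(abs(v)))
  expect_error(centroidToStateGraph(rep(0, 7), nm), "does not match")
})

test_that("graphMetrics composes the per-state report", {
  nm <- tinyNodeMeta(6)
  set.seed(9)
  W <- matrix(0, 6, 6)
  W[upper.tri(W)] <- rnorm(15) * rbinom(15, 1, 0.6)
  W <- W + t(W)
  adj <- centroidToStateGraph(upperTriVec(W), nm)
  gm <- graphMetrics(adj, hubMetric = "degree")
  expect_equal(gm$totalConnections, sum(W[upper.tri(W)] != 0))
  expect_true(all(gm$ccPerNode >= 0 & gm$ccPerNode <= 1))
  expect_equal(gm$networkStrength, sum(abs(W[upper.tri(W)])))
  expect_equal(gm$hubMetric, "degree")
})
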