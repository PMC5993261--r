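## Shared fixtures and independent oracles for the test suite.
## Oracles here are deliberately naive (loops, enumeration) and never
## call the package functions they check.

tinyNodeMeta <- function(p, networks = rep(c("A", "B"), length.out = p)) {
  data.frame(node = sprintf("N%02d", seq_len(p)), network = networks,
             x = seq_len(p) * 10, y = rev(seq_len(p)) * 5,
             z = rep(0, p), stringsAsFactors = FALSE)
}

tinyTs <- function(data, tr = 2, subject = "S01", run = "run1",
                   prep = character(0)) {
  data <- as.matrix(data)
  new("ComponentTimeSeries", data = data, trSeconds = tr,
      subjectId = subject, runId = run,
      nodeMeta = tinyNodeMeta(ncol(data)), prepState = prep)
}

## Build a WindowedConnectivity directly from an edge-feature matrix,
## bypassing estimation (for clustering unit tests).
stackFromEdges <- function(E, nNodes, subject = "S01", run = "run1") {
  new("WindowedConnectivity", edges = as.matrix(E),
      nNodes = as.integer(nNodes),
      windowStarts = seq_len(nrow(E)), params = windowParams(),
      subjectId = subject, runId = run, nodeMeta = data.frame())
}

## brute-force local clustering coefficient: enumerate neighbour pairs
bfClusteringCoefficient <- function(A) {
  p <- nrow(A)
  cc <- numeric(p)
  for (i in seq_len(p)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    e <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] != 0) e <- e + 1
    cc[i] <- 2 * e / (k * (k - 1))
  }
  cc
}

## brute-force all-pairs shortest paths: Floyd-Warshall
bfPathLength <- function(A) {
  p <- nrow(A)
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  D[A != 0] <- 1
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  list(pathLength = if (any(reach)) mean(off[reach]) else NA_real_,
       reachabilityFraction = mean(reach))
}

## brute-force k-means optimum: enumerate every label assignment
bfKmeansInertia <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  for (code in 0:(k^n - 1)) {
    lab <- integer(n)
    c0 <- code
    for (i in seq_len(n)) { lab[i] <- c0 %% k + 1; c0 <- c0 %/% k }
    inertia <- 0
    for (c in seq_len(k)) {
      idx <- lab == c
      if (!any(idx)) next
      mu <- colMeans(X[idx, , drop = FALSE])
      inertia <- inertia + sum(sweep(X[idx, , drop = FALSE], 2, mu)^2)
    }
    if (inertia < best) best <- inertia
  }
  best
}

## brute-force Benjamini-Hochberg step-up by its sorted-threshold
## definition
bfBH <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- max(c(0L, which(ps <= alpha * seq_len(m) / m)))
  rej <- logical(m)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}

## penalized Gaussian objective shared with the sparse-precision oracle
gObjective <- function(Theta, S, rho) {
  sum(S * Theta) - determinant(Theta, logarithm = TRUE)$modulus[1] +
    2 * rho * sum(abs(Theta[upper.tri(Theta)]))
}

## independent convex-solver oracle: Nelder-Mead over a Cholesky
## parameterization (log-diagonal), multiple starts
nmPrecisionOracle <- function(S, rho) {
  p <- nrow(S)
  toTheta <- function(par) {
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- par
    diag(L) <- exp(diag(L))
    L %*% t(L)
  }
  f <- function(par) gObjective(toTheta(par), S, rho)
  starts <- list(
    { L0 <- diag(p); L0[lower.tri(L0, diag = TRUE)] * 0 },
    { ch <- chol(solve(S)); L <- t(ch)
      diag(L) <- log(diag(L)); L[lower.tri(L, diag = TRUE)] })
  best <- NULL
  for (st in starts) {
    res <- stats::optim(st, f, method = "Nelder-Mead",
                        control = list(maxit = 50000, reltol = 1e-15))
    for (i in 1:5)
      res <- stats::optim(res$par, f, method = "Nelder-Mead",
                          control = list(maxit = 50000, reltol = 1e-15))
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(precision = toTheta(best$par), objective = best$value)
}
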