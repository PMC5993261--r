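#' Construct WindowParams
#'
#' @param windowLength window length in volumes (default 15 = 30 s at
#'   TR 2 s).
#' @param step step between window starts in volumes (default 1).
#' @param taper `"rectangular"` (default) or `"gaussian"`.
#' @param taperSigma sigma (volumes) for the Gaussian taper.
#' @param estimator `"correlation"` (default) or `"sparse_precision"`.
#' @param l1Penalty L1 penalty for sparse precision (default 0.1).
#' @return a [WindowParams-class].
#' @export
windowParams <- function(windowLength = 15L, step = 1L,
                         taper = c("rectangular", "gaussian"),
                         taperSigma = 3, estimator = c("correlation",
                                                       "sparse_precision"),
                         l1Penalty = 0.1) {
  new("WindowParams", windowLength = as.integer(windowLength),
      step = as.integer(step), taper = match.arg(taper),
      taperSigma = taperSigma, estimator = match.arg(estimator),
      l1Penalty = l1Penalty)
}

#' Sliding-window index pairs
#'
#' Windows are `[start, start + windowLength - 1]`, 1-based inclusive;
#' consecutive starts differ by `step`; the last window ends at or
#' before `nVolumes`. Window count is
#' `floor((nVolumes - windowLength) / step) + 1`.
#'
#' @param nVolumes run length in volumes.
#' @param params a [WindowParams-class] (or anything with
#'   `windowLength`/`step` slots).
#' @return data.frame with columns `start`, `end`.
#' @export
makeWindows <- function(nVolumes, params = windowParams()) {
  L <- params@windowLength
  if (nVolumes < L)
    stop("nVolumes (", nVolumes, ") is below the window length (", L, ")")
  starts <- seq(1L, nVolumes - L + 1L, by = params@step)
  data.frame(start = starts, end = starts + L - 1L)
}

taperWeights <- function(params, L = params@windowLength) {
  if (params@taper == "rectangular") rep(1, L)
  else exp(-0.5 * ((seq_len(L) - (L + 1) / 2) / params@taperSigma)^2)
}

## Weighted Pearson correlation of the rows of X (weights w over rows).
## Constant columns yield zeroed correlations (diag stays 1).
weightedCorrelation <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc * w, Xc)
  s <- sqrt(diag(C))
  const <- s < .Machine$double.eps^0.5 * max(s, 1)
  s[const] <- 1
  R <- C / tcrossprod(s)
  if (any(const)) {
    R[const, ] <- 0
    R[, const] <- 0
  }
  diag(R) <- 1
  R <- (R + t(R)) / 2
  pmin(pmax(R, -1), 1)
}

#' Connectivity of a single window
#'
#' Pearson correlation of the windowed rows, optionally taper-weighted.
#' With the rectangular taper this equals `stats::cor` on the window.
#' A node that is constant within the window gets its correlations set
#' to 0 with a warning (degenerate-input robustness).
#'
#' @param ts a [ComponentTimeSeries-class].
#' @param window length-2 vector or 1-row data.frame giving `start` and
#'   `end` (1-based inclusive).
#' @param params a [WindowParams-class] supplying the taper.
#' @return symmetric node x node correlation matrix, unit diagonal.
#' @export
windowCorrelation <- function(ts, window, params = windowParams()) {
  stopifnot(is(ts, "ComponentTimeSeries"))
  window <- as.integer(unlist(window)[1:2])
  if (window[2] - window[1] + 1L < 3) stop("window length must be >= 3")
  if (window[1] < 1 || window[2] > nrow(ts@data))
    stop("window out of range")
  X <- ts@data[window[1]:window[2], , drop = FALSE]
  ranges <- apply(X, 2, function(col) diff(range(col)))
  if (any(ranges == 0))
    warning(sum(ranges == 0),
            " constant node(s) in window; affected correlations set to 0")
  w <- taperWeights(params, L = nrow(X))
  weightedCorrelation(X, w)
}

## penalized negative log-likelihood: tr(S Theta) - logdet(Theta)
## + rho * sum(|offdiag(Theta)|)
glassoObjective <- function(Theta, S, rho) {
  cd <- chol(Theta)
  sum(S * Theta) - 2 * sum(log(diag(cd))) +
    rho * sum(abs(Theta[upper.tri(Theta)])) * 2
}

#' Sparse precision matrix by L1-penalized Gaussian likelihood
#'
#' Minimizes `tr(S Theta) - log det(Theta) + rho * ||offdiag(Theta)||_1`
#' over positive-definite `Theta` by proximal gradient descent (ISTA)
#' with backtracking line search, which makes the objective
#' non-increasing by construction and produces exact zeros through the
#' soft-threshold step. At `rho = 0` (well-conditioned input) the solver
#' is bypassed and the matrix inverse returned.
#'
#' @param sampleCov symmetric positive-semidefinite sample covariance.
#' @param l1Penalty penalty `rho >= 0` applied to off-diagonal entries.
#' @param tol relative objective-change convergence tolerance.
#' @param maxIter iteration cap; exceeding it is an error.
#' @return list with `precision` (SPD matrix), `partial` (partial
#'   correlations, zero diagonal), `objective` (trace of objective
#'   values), `iterations`.
#' @export
sparsePrecision <- function(sampleCov, l1Penalty = 0.1, tol = 1e-10,
                            maxIter = 5000L) {
  S <- unname(as.matrix(sampleCov))
  if (!isSymmetric(S, tol = 1e-8)) stop("sampleCov must be symmetric")
  S <- (S + t(S)) / 2
  if (l1Penalty < 0) stop("l1Penalty must be >= 0")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("sampleCov must be positive semidefinite")
  p <- nrow(S)
  if (l1Penalty == 0) {
    if (min(ev) < 1e-10 * max(ev))
      stop("unpenalized precision requires a well-conditioned covariance")
    Theta <- solve(S)
    Theta <- (Theta + t(Theta)) / 2
    return(list(precision = Theta, partial = partialFromPrecision(Theta),
                objective = glassoObjective(Theta, S, 0), iterations = 0L))
  }
  rho <- l1Penalty
  Theta <- diag(1 / pmax(diag(S), 1e-8))
  objs <- glassoObjective(Theta, S, rho)
  stepSize <- 1
  offd <- !diag(p)
  for (it in seq_len(maxIter)) {
    W <- chol2inv(chol(Theta))          # Theta^{-1}
    grad <- S - W
    smoothVal <- sum(S * Theta) - 2 * sum(log(diag(chol(Theta))))
    repeat {
      Z <- Theta - stepSize * grad
      ## soft-threshold off-diagonals only
      Znew <- Z
      Znew[offd] <- sign(Z[offd]) * pmax(abs(Z[offd]) - stepSize * rho, 0)
      Znew <- (Znew + t(Znew)) / 2
      cd <- tryCatch(chol(Znew), error = function(e) NULL)
      if (!is.null(cd)) {
        smoothNew <- sum(S * Znew) - 2 * sum(log(diag(cd)))
        D <- Znew - Theta
        quadBound <- smoothVal + sum(grad * D) + sum(D * D) / (2 * stepSize)
        if (smoothNew <= quadBound + 1e-12) break
      }
      stepSize <- stepSize / 2
      if (stepSize < 1e-14)
        stop("sparsePrecision: line search failed (step underflow)")
    }
    ThetaNew <- Znew
    objNew <- glassoObjective(ThetaNew, S, rho)
    objs <- c(objs, objNew)
    delta <- objs[length(objs) - 1] - objNew
    Theta <- ThetaNew
    if (delta >= 0 && delta < tol * (abs(objNew) + 1)) {
      return(list(precision = Theta,
                  partial = partialFromPrecision(Theta),
                  objective = objs, iterations = it))
    }
    stepSize <- min(stepSize * 2, 1e3)  # allow step to grow back
  }
  stop("sparsePrecision did not converge within ", maxIter,
       " iterations (last objective change ",
       signif(objs[length(objs) - 1] - objs[length(objs)], 3), ")")
}

#' Partial correlations from a precision matrix
#'
#' `pcor_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, diagonal set to 0.
#'
#' @param Theta precision matrix.
#' @return symmetric partial-correlation matrix with zero diagonal.
#' @export
partialFromPrecision <- function(Theta) {
  d <- sqrt(diag(Theta))
  P <- -Theta / tcrossprod(d)
  diag(P) <- 0
  (P + t(P)) / 2
}

## Ridge floor for rank-deficient windowed covariances (a 15-volume
## window over more than 15 nodes is always singular; the off-diagonal
## L1 objective is unbounded below on singular inputs).
stabilizeCov <- function(S, floorFrac = 1e-3) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  floorVal <- floorFrac * mean(diag(S))
  if (min(ev) < floorVal) S <- S + diag(floorVal - min(ev), nrow(S))
  S
}

#' Windowed connectivity stack for one subject-run
#'
#' Slides the window over the prepared time series and estimates one
#' connectivity matrix per window. For `estimator = "correlation"` the
#' stored feature vectors are windowed Pearson correlations; for
#' `"sparse_precision"` they are the partial correlations derived from
#' the L1-penalized precision of the (ridge-stabilized, taper-weighted)
#' windowed covariance.
#'
#' @param ts a prepared [ComponentTimeSeries-class] (the discard,
#'   detrend and filter flags must all be set).
#' @param params a [WindowParams-class].
#' @param requirePrep set `FALSE` to allow unprepared input (used in
#'   unit tests and toy examples).
#' @return a [WindowedConnectivity-class].
#' @export
dfcStack <- function(ts, params = windowParams(), requirePrep = TRUE) {
  stopifnot(is(ts, "ComponentTimeSeries"))
  validObject(params)
  if (requirePrep &&
      !all(c("discarded", "detrended", "filtered") %in% ts@prepState))
    stop("dfcStack expects a prepared series (discard/detrend/filter); ",
         "run prepTimeSeries() first or set requirePrep = FALSE")
  win <- makeWindows(nrow(ts@data), params)
  p <- ncol(ts@data)
  E <- matrix(0, nrow(win), p * (p - 1) / 2)
  w <- taperWeights(params)
  wn <- w / sum(w)
  for (i in seq_len(nrow(win))) {
    X <- ts@data[win$start[i]:win$end[i], , drop = FALSE]
    if (params@estimator == "correlation") {
      M <- weightedCorrelation(X, w)
    } else {
      mu <- colSums(X * wn)
      Xc <- sweep(X, 2, mu)
      S <- crossprod(Xc * wn, Xc)
      S <- stabilizeCov((S + t(S)) / 2)
      M <- sparsePrecision(S, params@l1Penalty, tol = 1e-8)$partial
    }
    E[i, ] <- upperTriVec(M)
  }
  new("WindowedConnectivity", edges = E, nNodes = as.integer(p),
      windowStarts = as.integer(win$start), params = params,
      subjectId = ts@subjectId, runId = ts@runId, nodeMeta = ts@nodeMeta)
}
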