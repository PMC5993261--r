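#' @import methods
NULL

## ---------------------------------------------------------------------------
## Generative model classes (synthetic cohorts)
## ---------------------------------------------------------------------------

#' TransitionModel: a Markov chain over connectivity states
#'
#' Row-stochastic transition matrix plus an initial state distribution.
#' Used by the synthetic-cohort generator to drive state switching at the
#' volume level.
#'
#' @slot matrix K x K row-stochastic transition probability matrix.
#' @slot initial length-K initial state probability vector.
#' @exportClass TransitionModel
setClass("TransitionModel",
  representation(matrix = "matrix", initial = "numeric"))

setValidity("TransitionModel", function(object) {
  P <- object@matrix
  msg <- character()
  if (nrow(P) != ncol(P)) msg <- c(msg, "transition matrix must be square")
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    msg <- c(msg, "transition probabilities must lie in [0, 1]")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    msg <- c(msg, "transition matrix rows must sum to 1 (tol 1e-12)")
  if (length(object@initial) != nrow(P))
    msg <- c(msg, "initial distribution length must equal number of states")
  if (abs(sum(object@initial) - 1) > 1e-12)
    msg <- c(msg, "initial distribution must sum to 1 (tol 1e-12)")
  if (any(object@initial < -1e-12))
    msg <- c(msg, "initial probabilities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' StateLibrary: covariance patterns defining latent connectivity states
#'
#' A set of K symmetric positive-definite correlation matrices (unit
#' diagonal), one per latent state, with a record of which subnetwork
#' blocks are coupled in each state.
#'
#' @slot covariances list of K node x node SPD correlation matrices.
#' @slot stateIds integer state labels 1..K.
#' @slot blockDesign list, per state, of the subnetwork blocks that are
#'   strongly coupled in that state.
#' @slot networkLabels character vector assigning each node to a
#'   subnetwork block.
#' @exportClass StateLibrary
setClass("StateLibrary",
  representation(covariances = "list", stateIds = "integer",
                 blockDesign = "list", networkLabels = "character"))

setValidity("StateLibrary", function(object) {
  msg <- character()
  K <- length(object@covariances)
  if (K < 2) msg <- c(msg, "a state library needs K >= 2 states")
  if (length(object@stateIds) != K || !identical(object@stateIds, seq_len(K)))
    msg <- c(msg, "stateIds must be 1..K")
  dims <- vapply(object@covariances, nrow, integer(1))
  if (length(unique(dims)) > 1)
    msg <- c(msg, "all state covariances must share one dimension")
  for (S in object@covariances) {
    if (!isSymmetric(S, tol = 1e-10)) {
      msg <- c(msg, "state covariances must be symmetric"); break
    }
    if (max(abs(diag(S) - 1)) > 1e-10) {
      msg <- c(msg, "state covariances must have unit diagonal"); break
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      msg <- c(msg, "state covariances must be positive definite"); break
    }
  }
  if (length(object@networkLabels) && length(dims) &&
      length(object@networkLabels) != dims[1])
    msg <- c(msg, "networkLabels length must equal node count")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: full description of a synthetic two-group cohort
#'
#' Everything needed to generate a cohort deterministically: the state
#' library, one group-level transition model per group, sample sizes, run
#' structure, sampling interval, observation noise, the subject-level
#' heterogeneity (Dirichlet concentration around the group transition
#' rows), and the master seed.
#'
#' @slot stateLibrary [StateLibrary-class] shared by all groups.
#' @slot groups named list of [TransitionModel-class], one per group.
#' @slot nSubjectsPerGroup integer subjects per group.
#' @slot nRuns integer runs per subject.
#' @slot nVolumes integer volumes per run.
#' @slot trSeconds sampling interval (seconds per volume).
#' @slot noiseSd isotropic observation-noise standard deviation.
#' @slot subjectConcentration Dirichlet concentration of the subject
#'   preference profile (smaller = subjects more strongly locked to
#'   individual dominant states).
#' @slot rateSd SD of the log-normal subject switching-rate multiplier
#'   (0 = all subjects share the group switching rate).
#' @slot seed integer master seed; the cohort is a pure function of the spec.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(stateLibrary = "StateLibrary", groups = "list",
                 nSubjectsPerGroup = "integer", nRuns = "integer",
                 nVolumes = "integer", trSeconds = "numeric",
                 noiseSd = "numeric", subjectConcentration = "numeric",
                 rateSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (!length(object@groups)) msg <- c(msg, "at least one group required")
  gn <- names(object@groups)
  if (is.null(gn) || anyDuplicated(gn) || any(!nzchar(gn)))
    msg <- c(msg, "groups must be uniquely named")
  K <- length(object@stateLibrary@covariances)
  for (g in object@groups) {
    if (!is(g, "TransitionModel")) {
      msg <- c(msg, "each group must hold a TransitionModel"); break
    }
    if (nrow(g@matrix) != K) {
      msg <- c(msg, "group transition models must match library state count")
      break
    }
  }
  if (object@nSubjectsPerGroup < 1) msg <- c(msg, "need >= 1 subject per group")
  if (object@nRuns < 1) msg <- c(msg, "need >= 1 run")
  if (object@nVolumes < 2) msg <- c(msg, "need >= 2 volumes")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@subjectConcentration <= 0)
    msg <- c(msg, "subjectConcentration must be positive")
  if (object@rateSd < 0) msg <- c(msg, "rateSd must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Observed-data classes
## ---------------------------------------------------------------------------

#' ComponentTimeSeries: node time courses for one subject-run
#'
#' A volumes x nodes signal matrix with its sampling interval and per-node
#' metadata (node id, subnetwork label, 3-D centroid in mm). A processing
#' flag records which preparation steps have been applied, so the fixed
#' pipeline order (discard, detrend, low-pass) can be enforced.
#'
#' @slot data volumes x nodes numeric matrix.
#' @slot trSeconds sampling interval in seconds.
#' @slot subjectId,runId identifiers.
#' @slot nodeMeta data.frame with columns `node`, `network`, `x`, `y`, `z`.
#' @slot prepState character subset of
#'   `c("discarded", "detrended", "filtered")`.
#' @exportClass ComponentTimeSeries
setClass("ComponentTimeSeries",
  representation(data = "matrix", trSeconds = "numeric",
                 subjectId = "character", runId = "character",
                 nodeMeta = "data.frame", prepState = "character"))

setValidity("ComponentTimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (any(!is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (nrow(object@nodeMeta) && nrow(object@nodeMeta) != ncol(object@data))
    msg <- c(msg, "nodeMeta rows must equal node (column) count")
  if (nrow(object@nodeMeta) &&
      !all(c("node", "network", "x", "y", "z") %in% names(object@nodeMeta)))
    msg <- c(msg, "nodeMeta needs columns node, network, x, y, z")
  bad <- setdiff(object@prepState, c("discarded", "detrended", "filtered"))
  if (length(bad)) msg <- c(msg, paste("unknown prepState:", bad[1]))
  if (length(msg)) msg else TRUE
})

#' SubjectRecord: one simulated subject with ground truth
#'
#' @slot subjectId identifier.
#' @slot group group name.
#' @slot runs list of [ComponentTimeSeries-class], one per run.
#' @slot stateLabels list of integer ground-truth state sequences (one
#'   label per volume) aligned with `runs`.
#' @slot transitionModel the subject-specific [TransitionModel-class].
#' @exportClass SubjectRecord
setClass("SubjectRecord",
  representation(subjectId = "character", group = "character",
                 runs = "list", stateLabels = "list",
                 transitionModel = "TransitionModel"))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  if (length(object@runs) != length(object@stateLabels))
    msg <- c(msg, "runs and stateLabels must align")
  for (i in seq_along(object@runs)) {
    if (!is(object@runs[[i]], "ComponentTimeSeries")) {
      msg <- c(msg, "runs must hold ComponentTimeSeries"); break
    }
    if (length(object@stateLabels[[i]]) != nrow(object@runs[[i]]@data)) {
      msg <- c(msg, "each label sequence must have one label per volume")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Dynamic-connectivity classes
## ---------------------------------------------------------------------------

#' WindowParams: sliding-window estimation parameters
#'
#' @slot windowLength window length in volumes (default 15, i.e. 30 s at
#'   TR = 2 s).
#' @slot step window step in volumes (default 1).
#' @slot taper `"rectangular"` or `"gaussian"` weight profile.
#' @slot taperSigma Gaussian taper sigma in volumes (ignored for
#'   rectangular).
#' @slot estimator `"correlation"` or `"sparse_precision"`.
#' @slot l1Penalty L1 penalty for the sparse-precision estimator.
#' @exportClass WindowParams
setClass("WindowParams",
  representation(windowLength = "integer", step = "integer",
                 taper = "character", taperSigma = "numeric",
                 estimator = "character", l1Penalty = "numeric"))

setValidity("WindowParams", function(object) {
  msg <- character()
  if (object@windowLength < 3) msg <- c(msg, "windowLength must be >= 3")
  if (object@step < 1) msg <- c(msg, "step must be >= 1")
  if (!object@taper %in% c("rectangular", "gaussian"))
    msg <- c(msg, "taper must be 'rectangular' or 'gaussian'")
  if (object@taper == "gaussian" && object@taperSigma <= 0)
    msg <- c(msg, "taperSigma must be positive for a gaussian taper")
  if (!object@estimator %in% c("correlation", "sparse_precision"))
    msg <- c(msg, "estimator must be 'correlation' or 'sparse_precision'")
  if (object@l1Penalty < 0) msg <- c(msg, "l1Penalty must be >= 0")
  if (length(msg)) msg else TRUE
})

#' WindowedConnectivity: the per-window connectivity stack for one run
#'
#' Windows are stored as vectorized upper triangles (one row per window,
#' one column per node pair), which is the feature representation used
#' for state clustering. Full symmetric matrices are recoverable with
#' [upperTriMat()].
#'
#' @slot edges nWindows x nEdges matrix of vectorized upper triangles.
#' @slot nNodes node count of the underlying matrices.
#' @slot windowStarts integer first-volume index (1-based) of each window.
#' @slot params the [WindowParams-class] used.
#' @slot subjectId,runId identifiers.
#' @slot nodeMeta per-node metadata carried from the time series.
#' @exportClass WindowedConnectivity
setClass("WindowedConnectivity",
  representation(edges = "matrix", nNodes = "integer",
                 windowStarts = "integer", params = "WindowParams",
                 subjectId = "character", runId = "character",
                 nodeMeta = "data.frame"))

setValidity("WindowedConnectivity", function(object) {
  msg <- character()
  p <- object@nNodes
  if (ncol(object@edges) != p * (p - 1) / 2)
    msg <- c(msg, "edge column count must equal nNodes*(nNodes-1)/2")
  if (nrow(object@edges) != length(object@windowStarts))
    msg <- c(msg, "one window start per window row required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Clustering and graph classes
## ---------------------------------------------------------------------------

#' StatePartition: k-means connectivity states over pooled windows
#'
#' @slot k number of states.
#' @slot centroids k x nEdges centroid matrix in edge space.
#' @slot labels named list (one entry per subject-run, names
#'   `"subject.run"`) of integer window-label sequences in 1..k.
#' @slot runTable data.frame with columns `subjectId`, `runId`, `group`
#'   aligned with `labels`.
#' @slot inertia final total within-cluster sum of squared Euclidean
#'   distances over all pooled windows.
#' @slot seed,nReplicates clustering reproducibility parameters.
#' @exportClass StatePartition
setClass("StatePartition",
  representation(k = "integer", centroids = "matrix", labels = "list",
                 runTable = "data.frame", inertia = "numeric",
                 seed = "integer", nReplicates = "integer"))

setValidity("StatePartition", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroid rows must equal k")
  if (length(object@labels) != nrow(object@runTable))
    msg <- c(msg, "labels must align with runTable")
  lab <- unlist(object@labels, use.names = FALSE)
  if (length(lab) && (min(lab) < 1 || max(lab) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' AdjacencyMatrix: thresholded weighted graph over network nodes
#'
#' @slot weights symmetric node x node weight matrix, zero diagonal;
#'   zero outside the surviving mask.
#' @slot mask logical matrix of surviving edges.
#' @slot nodeMeta per-node metadata (`node`, `network`, `x`, `y`, `z`).
#' @slot nSamples observations behind each correlation (for significance),
#'   `NA` when not applicable.
#' @exportClass AdjacencyMatrix
setClass("AdjacencyMatrix",
  representation(weights = "matrix", mask = "matrix",
                 nodeMeta = "data.frame", nSamples = "numeric"))

setValidity("AdjacencyMatrix", function(object) {
  msg <- character()
  W <- object@weights
  if (nrow(W) != ncol(W)) msg <- c(msg, "weights must be square")
  if (!isSymmetric(unname(W), tol = 1e-10)) msg <- c(msg, "weights must be symmetric")
  if (any(abs(diag(W)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (!identical(dim(object@mask), dim(W)))
    msg <- c(msg, "mask must match weights dimension")
  if (any(W[!object@mask] != 0))
    msg <- c(msg, "weights outside the mask must be zero")
  if (length(msg)) msg else TRUE
})
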