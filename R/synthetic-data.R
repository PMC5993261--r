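#' Build a library of block-structured connectivity states
#'
#' Constructs `nStates` distinct symmetric positive-definite correlation
#' matrices over `nNodes` nodes. Nodes are partitioned into subnetwork
#' blocks by `networkLabels`; each state strongly couples a distinct
#' subset of blocks (compound symmetry at `couplingStrength` within each
#' active block, zero elsewhere), emulating the subnetwork-organized
#' connectivity patterns that recur in windowed fMRI connectivity. Block
#' subsets are enumerated deterministically (singletons first, then
#' pairs, ...), so state 1 couples the first block alone, and so on.
#'
#' @param nStates number of states (>= 2, at most `2^B - 1` for `B` blocks).
#' @param nNodes number of nodes (>= 4).
#' @param networkLabels length-`nNodes` block assignment (>= 2 blocks);
#'   defaults to a round-robin assignment over canonical subnetwork names.
#' @param couplingStrength within-block correlation of an active block,
#'   in (0, 1).
#' @param seed integer seed for the small per-state coupling jitter that
#'   keeps states generic (jitter is multiplicative in \[0.9, 1\]).
#' @return a [StateLibrary-class].
#' @examples
#' lib <- buildStateLibrary(2, 4, rep(c("A", "B"), each = 2), 0.8, seed = 1)
#' stateCovariances(lib)[[1]]
#' @export
buildStateLibrary <- function(nStates, nNodes, networkLabels = NULL,
                              couplingStrength = 0.8, seed = 1L) {
  if (nStates < 2) stop("nStates must be >= 2")
  if (nNodes < 4) stop("nNodes must be >= 4")
  if (couplingStrength <= 0 || couplingStrength >= 1)
    stop("couplingStrength must lie in (0, 1): states would not be ",
         "distinct (or not positive definite) otherwise")
  if (is.null(networkLabels))
    networkLabels <- defaultNodeMeta(nNodes)$network
  if (length(networkLabels) != nNodes)
    stop("networkLabels must have one entry per node")
  blocks <- unique(networkLabels)
  B <- length(blocks)
  if (B < 2) stop("networkLabels must define at least 2 blocks")

  ## deterministic subset enumeration: by size, then lexicographic
  subsets <- list()
  for (sz in seq_len(B)) {
    cmb <- utils::combn(B, sz, simplify = FALSE)
    subsets <- c(subsets, cmb)
    if (length(subsets) >= nStates) break
  }
  if (length(subsets) < nStates)
    stop("nStates exceeds the number of distinct block coupling patterns (",
         2^B - 1, ")")
  subsets <- subsets[seq_len(nStates)]

  jitter <- withr::with_seed(as.integer(seed),
                             matrix(stats::runif(nStates * B, 0.9, 1),
                                    nStates, B))
  covs <- vector("list", nStates)
  for (s in seq_len(nStates)) {
    S <- diag(nNodes)
    for (b in subsets[[s]]) {
      idx <- which(networkLabels == blocks[b])
      r <- couplingStrength * jitter[s, b]
      S[idx, idx] <- r
      diag(S)[idx] <- 1
    }
    ## jitter repair: shrink toward identity if numerically non-PD
    for (attempt in 0:5) {
      ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
      if (ev > 1e-8) break
      S <- 0.95 * S + 0.05 * diag(nNodes)
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8)
      stop("state ", s, " covariance is not positive definite after repair ",
           "(min eigenvalue ",
           signif(min(eigen(S, symmetric = TRUE,
                            only.values = TRUE)$values), 3), ")")
    covs[[s]] <- S
  }
  ## distinctness guard
  for (i in seq_len(nStates - 1)) for (j in (i + 1):nStates) {
    if (sqrt(sum((covs[[i]] - covs[[j]])^2)) == 0)
      stop("states ", i, " and ", j, " are identical; increase ",
           "couplingStrength or use more blocks")
  }
  new("StateLibrary", covariances = covs, stateIds = seq_len(nStates),
      blockDesign = lapply(subsets, function(s) blocks[s]),
      networkLabels = as.character(networkLabels))
}

#' Construct a TransitionModel
#'
#' @param matrix K x K row-stochastic matrix.
#' @param initial length-K initial distribution; defaults to the chain's
#'   stationary distribution.
#' @return a [TransitionModel-class].
#' @export
transitionModel <- function(matrix, initial = NULL) {
  if (is.null(initial)) initial <- stationaryDistribution(matrix)
  new("TransitionModel", matrix = unname(as.matrix(matrix)),
      initial = as.numeric(initial))
}

#' Group-level sticky transition matrix
#'
#' Uniform switching among allowed states with a common self-transition
#' probability. States listed in `excludeStates` are made unreachable
#' (their columns zeroed, rows renormalized), which is how a group can
#' be denied access to rare states available to the other group.
#'
#' @param nStates number of states.
#' @param selfProb self-transition probability in \[0, 1).
#' @param excludeStates integer states this group can never enter.
#' @return a [TransitionModel-class].
#' @export
makeGroupTransition <- function(nStates, selfProb, excludeStates = integer(0)) {
  stopifnot(nStates >= 2, selfProb >= 0, selfProb < 1)
  allowed <- setdiff(seq_len(nStates), excludeStates)
  if (length(allowed) < 2) stop("at least 2 states must remain reachable")
  P <- matrix(0, nStates, nStates)
  for (i in seq_len(nStates)) {
    if (i %in% allowed) {
      others <- setdiff(allowed, i)
      P[i, i] <- selfProb
      P[i, others] <- (1 - selfProb) / length(others)
    } else {
      P[i, allowed] <- 1 / length(allowed)  # excluded state exits immediately
    }
  }
  init <- numeric(nStates)
  init[allowed] <- 1 / length(allowed)
  transitionModel(P, init)
}

#' Stationary distribution of a Markov chain
#'
#' Power iteration from the uniform distribution; for reducible chains
#' this returns the stationary distribution reachable from a uniform
#' start (transient states get probability 0).
#'
#' @param P row-stochastic matrix.
#' @param iterations number of power-iteration steps.
#' @return length-K probability vector.
#' @export
stationaryDistribution <- function(P, iterations = 2000L) {
  P <- as.matrix(P)
  pi0 <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iterations)) pi0 <- as.numeric(pi0 %*% P)
  pi0 / sum(pi0)
}

#' Sample a latent state sequence
#'
#' @param model a [TransitionModel-class].
#' @param nVolumes sequence length.
#' @param seed integer seed.
#' @return integer vector of state labels.
#' @export
sampleStateSequence <- function(model, nVolumes, seed = 1L) {
  stopifnot(is(model, "TransitionModel"), nVolumes >= 1)
  validObject(model)
  P <- model@matrix
  K <- nrow(P)
  withr::with_seed(as.integer(seed), {
    s <- integer(nVolumes)
    s[1] <- sample.int(K, 1, prob = model@initial)
    if (nVolumes > 1) {
      u <- stats::runif(nVolumes - 1)
      cum <- t(apply(P, 1, cumsum))
      for (t in 2:nVolumes)
        s[t] <- findInterval(u[t - 1], cum[s[t - 1], ]) + 1L
    }
    s
  })
}

#' Emit node time courses for one run given a state sequence
#'
#' At each volume the observation is a zero-mean Gaussian draw with
#' covariance equal to the active state's correlation matrix plus
#' isotropic noise `noiseSd^2 * I`. State changes occur at volume
#' boundaries.
#'
#' @param library a [StateLibrary-class].
#' @param labelSequence integer state label per volume.
#' @param noiseSd observation-noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param trSeconds sampling interval (default 2 s).
#' @param subjectId,runId identifiers stored on the result.
#' @param nodeMeta optional node metadata; generated if omitted.
#' @return a [ComponentTimeSeries-class].
#' @export
generateSubjectRun <- function(library, labelSequence, noiseSd = 0.5,
                               seed = 1L, trSeconds = 2,
                               subjectId = "S01", runId = "run1",
                               nodeMeta = NULL) {
  stopifnot(is(library, "StateLibrary"))
  if (!length(labelSequence)) stop("labelSequence must be non-empty")
  if (!all(labelSequence %in% library@stateIds))
    stop("labelSequence contains labels missing from the state library")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  p <- nrow(library@covariances[[1]])
  if (is.null(nodeMeta)) nodeMeta <- defaultNodeMeta(p, library@networkLabels)
  sigmas <- lapply(library@covariances,
                   function(S) S + diag(noiseSd^2, p))
  X <- withr::with_seed(as.integer(seed), {
    out <- matrix(0, length(labelSequence), p)
    runs <- rle(as.integer(labelSequence))
    at <- 1L
    for (i in seq_along(runs$lengths)) {
      len <- runs$lengths[i]
      out[at:(at + len - 1L), ] <-
        MASS::mvrnorm(len, mu = rep(0, p), Sigma = sigmas[[runs$values[i]]])
      at <- at + len
    }
    out
  })
  colnames(X) <- nodeMeta$node
  new("ComponentTimeSeries", data = X, trSeconds = trSeconds,
      subjectId = subjectId, runId = runId, nodeMeta = nodeMeta,
      prepState = character(0))
}

#' Construct a CohortSpec
#'
#' @param stateLibrary a [StateLibrary-class].
#' @param groups named list of group-level [TransitionModel-class] objects.
#' @param nSubjectsPerGroup subjects per group.
#' @param nRuns runs per subject.
#' @param nVolumes volumes per run.
#' @param trSeconds sampling interval.
#' @param noiseSd observation-noise SD.
#' @param subjectConcentration Dirichlet concentration of the subject
#'   preference profile (see [perturbTransition()]).
#' @param rateSd SD of the log-normal subject switching-rate multiplier.
#' @param seed master seed; the cohort is a pure function of this spec.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(stateLibrary, groups, nSubjectsPerGroup = 20L,
                       nRuns = 2L, nVolumes = 240L, trSeconds = 2,
                       noiseSd = 0.5, subjectConcentration = 0.4,
                       rateSd = 1.0, seed = 1L) {
  new("CohortSpec", stateLibrary = stateLibrary, groups = groups,
      nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
      nRuns = as.integer(nRuns), nVolumes = as.integer(nVolumes),
      trSeconds = trSeconds, noiseSd = noiseSd,
      subjectConcentration = subjectConcentration, rateSd = rateSd,
      seed = as.integer(seed))
}

#' Default two-group cohort specification
#'
#' The reference study conditions emulated by the package: two groups
#' (a control-like group and a stickier clinical-like group) of 20
#' subjects each, two 240-volume runs at TR = 2 s, 20 nodes in four
#' subnetwork blocks, and four well-separated connectivity states.
#' Self-transition probabilities (0.965 control, 0.972 clinical) put
#' expected volume-level transition counts near 8.4 and 6.7 per run.
#'
#' @param seed master seed.
#' @param nSubjectsPerGroup,nVolumes,nNodes,nStates,noiseSd,
#'   subjectConcentration overrides of the default conditions.
#' @return a [CohortSpec-class].
#' @export
defaultCohortSpec <- function(seed = 1L, nSubjectsPerGroup = 20L,
                              nVolumes = 240L, nNodes = 20L, nStates = 4L,
                              noiseSd = 0.5, subjectConcentration = 0.4) {
  labels <- rep(c("ECN", "DMN", "SN", "SM"), length.out = nNodes)
  lib <- buildStateLibrary(nStates, nNodes, labels, couplingStrength = 0.8,
                           seed = 1L)
  groups <- list(control = makeGroupTransition(nStates, 0.965),
                 clinical = makeGroupTransition(nStates, 0.972))
  cohortSpec(lib, groups, nSubjectsPerGroup = nSubjectsPerGroup,
             nRuns = 2L, nVolumes = nVolumes, trSeconds = 2,
             noiseSd = noiseSd, subjectConcentration = subjectConcentration,
             seed = seed)
}

#' Subject-specific transition model around a group model
#'
#' Draws a subject's state-preference profile `w` from a Dirichlet
#' distribution centred on the group model's stationary distribution
#' (concentration `kappa`; small values give strongly "locked" subjects
#' with one or two dominant states, as observed in real cohorts), and a
#' log-normal subject switching-rate multiplier. The subject's rows
#' then (a) direct switches toward preferred states
#' (`P(i -> j) \propto w_j`), (b) make preferred states stickier (exit
#' rate scaled by `1 - w_i`, normalized so the occupancy-weighted
#' switch rate matches the group rate on average), with per-row exit
#' rates capped at `excursionCap` times the group rate so excursions
#' are not arbitrarily brief, and (c) start every run in the preferred
#' state (initial distribution is a point mass at `argmax w`).
#' Structural zeros of the group matrix are preserved, so
#' group-exclusive states remain exclusive.
#'
#' @param group group-level [TransitionModel-class].
#' @param kappa Dirichlet preference concentration (default 0.4).
#' @param rateSd SD of the log switching-rate multiplier (default 1.0).
#' @param excursionCap per-row exit-rate cap as a multiple of the group
#'   switch rate (default 2).
#' @return a subject-level [TransitionModel-class].
#' @export
perturbTransition <- function(group, kappa = 0.4, rateSd = 1.0,
                              excursionCap = 2) {
  P <- group@matrix
  K <- nrow(P)
  allowed <- which(colSums(P) > 0)
  target <- stationaryDistribution(P)
  w <- numeric(K)
  w[allowed] <- rdirichlet1(kappa * pmax(target[allowed], 1e-8))
  m <- exp(stats::rnorm(1, 0, rateSd))
  Z <- sum(w * (1 - w))
  s <- diag(P)
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) {
    if (i %in% allowed && Z > 0) {
      cap <- min(0.5, excursionCap * (1 - s[i]))
      sw <- min(max((1 - s[i]) * m * (1 - w[i]) / Z, 1e-4), cap)
    } else sw <- 1   # excluded or degenerate state exits immediately
    dest <- w
    dest[i] <- 0
    if (sum(dest) == 0) dest[setdiff(allowed, i)] <- 1
    Q[i, ] <- sw * dest / sum(dest)
    Q[i, i] <- 1 - sw
  }
  init <- numeric(K)
  init[which.max(w)] <- 1
  transitionModel(Q, init)
}

#' Generate a synthetic cohort
#'
#' For each subject, a subject-specific transition model is drawn as a
#' Dirichlet perturbation of the group model (rows perturbed on their
#' support with concentration `subjectConcentration`), the same model is
#' then used for every run of that subject (this is what makes state
#' frequencies test-retest reliable), and each run's latent state
#' sequence and Gaussian emissions are sampled. All randomness derives
#' deterministically from `spec@seed`.
#'
#' @param spec a [CohortSpec-class].
#' @return list of [SubjectRecord-class], one per subject.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  nGroups <- length(spec@groups)
  nSubj <- nGroups * spec@nSubjectsPerGroup
  seeds <- deriveSeeds(spec@seed, nSubj * (1L + spec@nRuns))
  cohort <- vector("list", nSubj)
  si <- 0L
  seedAt <- 0L
  for (g in seq_len(nGroups)) {
    gname <- names(spec@groups)[g]
    for (j in seq_len(spec@nSubjectsPerGroup)) {
      si <- si + 1L
      sid <- sprintf("%s%02d", gname, j)
      subjModel <- withr::with_seed(
        seeds[seedAt <- seedAt + 1L],
        perturbTransition(spec@groups[[g]], spec@subjectConcentration,
                          rateSd = spec@rateSd))
      runs <- vector("list", spec@nRuns)
      labels <- vector("list", spec@nRuns)
      for (r in seq_len(spec@nRuns)) {
        runSeed <- seeds[seedAt <- seedAt + 1L]
        labels[[r]] <- sampleStateSequence(subjModel, spec@nVolumes,
                                           seed = runSeed)
        runs[[r]] <- generateSubjectRun(
          spec@stateLibrary, labels[[r]], noiseSd = spec@noiseSd,
          seed = runSeed + 1L, trSeconds = spec@trSeconds,
          subjectId = sid, runId = sprintf("run%d", r))
      }
      cohort[[si]] <- new("SubjectRecord", subjectId = sid, group = gname,
                          runs = runs, stateLabels = labels,
                          transitionModel = subjModel)
    }
  }
  names(cohort) <- vapply(cohort, function(s) s@subjectId, character(1))
  cohort
}

#' Count ground-truth state changes in a label sequence
#'
#' @param labels integer label sequence.
#' @return number of adjacent unequal label pairs.
#' @export
countTransitions <- function(labels) {
  if (length(labels) < 2) return(0L)
  sum(labels[-1] != labels[-length(labels)])
}
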