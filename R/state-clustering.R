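## Lloyd k-means with deterministic farthest-point re-seeding of empty
## clusters. Centers are supplied explicitly (matrix) so both phases of
## the exemplar-initialized procedure share one engine.
kmeansLloyd <- function(X, centers, maxIter = 200L) {
  k <- nrow(centers)
  n <- nrow(X)
  xsq <- rowSums(X^2)
  labels <- integer(n)
  for (it in seq_len(maxIter)) {
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
    newLabels <- max.col(-d2, ties.method = "first")
    ## empty-cluster rule: re-seed at the point farthest from its centroid
    for (c in which(tabulate(newLabels, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(n), newLabels)])
      centers[c, ] <- X[far, ]
      d2[, c] <- xsq + sum(X[far, ]^2) - 2 * as.numeric(X %*% X[far, ])
      newLabels <- max.col(-d2, ties.method = "first")
    }
    converged <- identical(newLabels, labels)
    labels <- newLabels
    for (c in seq_len(k)) {
      idx <- labels == c
      if (any(idx)) centers[c, ] <- colMeans(X[idx, , drop = FALSE])
    }
    if (converged && it > 1) break
  }
  d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(centers = centers, labels = labels, inertia = max(inertia, 0))
}

#' Select high-variability exemplar windows
#'
#' For each subject-run stack, computes the variance of connectivity
#' values across edges for every window and returns the windows at local
#' maxima of that variance profile (boundary windows count as maxima
#' when they exceed their single neighbour). These exemplars seed the
#' first clustering phase. All-constant profiles fall back to uniform
#' subsampling with a warning.
#'
#' @param stacks list of [WindowedConnectivity-class].
#' @return list (one per stack) of integer window indices.
#' @export
selectExemplars <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  lapply(stacks, function(wc) {
    E <- wc@edges
    n <- nrow(E)
    if (n < 3) return(seq_len(n))
    v <- apply(E, 1, stats::var)
    if (max(v) - min(v) < .Machine$double.eps * max(abs(v), 1)) {
      warning("flat variance profile; falling back to uniform subsampling")
      return(unique(as.integer(seq(1, n, length.out = min(n, 10)))))
    }
    isMax <- logical(n)
    isMax[1] <- v[1] > v[2]
    isMax[n] <- v[n] > v[n - 1]
    if (n > 2) {
      mid <- 2:(n - 1)
      isMax[mid] <- v[mid] > v[mid - 1] & v[mid] >= v[mid + 1]
    }
    if (!any(isMax)) {
      warning("no local variance maxima; falling back to uniform subsampling")
      return(unique(as.integer(seq(1, n, length.out = min(n, 10)))))
    }
    which(isMax)
  })
}

poolStacks <- function(stacks) {
  E <- do.call(rbind, lapply(stacks, function(s) s@edges))
  counts <- vapply(stacks, function(s) nrow(s@edges), integer(1))
  runKey <- vapply(stacks, function(s)
    paste(s@subjectId, s@runId, sep = "."), character(1))
  if (anyDuplicated(runKey)) stop("duplicate subject-run stacks")
  list(E = E, counts = counts, runKey = runKey)
}

#' Cluster windowed connectivity into recurring states
#'
#' Two-phase exemplar-initialized k-means with squared Euclidean
#' distance: (1) k-means on the pooled high-variability exemplar windows,
#' best of `nReplicates` seeded random starts by inertia; (2) a single
#' Lloyd run on all pooled windows initialized at the phase-1 centroids.
#' Windows from all subjects, groups and runs are pooled so the states
#' are shared, then labels are split back per subject-run. Deterministic
#' for a fixed seed; empty clusters are re-seeded at the farthest point.
#'
#' @param stacks list of [WindowedConnectivity-class].
#' @param k number of states (>= 2).
#' @param seed integer seed.
#' @param nReplicates phase-1 replicate count (default 5).
#' @param groups optional named character vector mapping subjectId to
#'   group (recorded in the run table).
#' @return a [StatePartition-class].
#' @export
clusterStates <- function(stacks, k, seed = 1L, nReplicates = 5L,
                          groups = NULL) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  pooled <- poolStacks(stacks)
  E <- pooled$E
  if (nrow(E) < k) stop("k exceeds the total window count")
  if (nrow(E) <= 2000 && nrow(unique(E)) < k)
    stop("k exceeds the number of distinct windows")
  exemplarIdx <- withr::with_seed(as.integer(seed), selectExemplars(stacks))
  offsets <- c(0L, cumsum(pooled$counts))
  exGlobal <- unlist(lapply(seq_along(stacks), function(i)
    exemplarIdx[[i]] + offsets[i]))
  if (length(exGlobal) < k)  # ensure a viable phase-1 set
    exGlobal <- unique(c(exGlobal,
                         as.integer(seq(1, nrow(E), length.out = 2L * k))))
  Ex <- E[exGlobal, , drop = FALSE]

  fit <- withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(nReplicates)) {
      init <- Ex[sample.int(nrow(Ex), k), , drop = FALSE]
      res <- kmeansLloyd(Ex, init)
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
    kmeansLloyd(E, best$centers)   # phase 2: all windows, single run
  })

  labels <- vector("list", length(stacks))
  for (i in seq_along(stacks))
    labels[[i]] <- fit$labels[(offsets[i] + 1L):offsets[i + 1L]]
  names(labels) <- pooled$runKey
  subj <- vapply(stacks, function(s) s@subjectId, character(1))
  grp <- if (is.null(groups)) rep(NA_character_, length(stacks)) else
    unname(groups[subj])
  runTab <- data.frame(
    subjectId = subj,
    runId = vapply(stacks, function(s) s@runId, character(1)),
    group = grp, stringsAsFactors = FALSE)
  new("StatePartition", k = k, centroids = fit$centers, labels = labels,
      runTable = runTab, inertia = fit$inertia, seed = as.integer(seed),
      nReplicates = as.integer(nReplicates))
}

#' State metrics for one label sequence
#'
#' Frequency is the fraction of windows per state; a transition is any
#' adjacent pair of unequal labels; mean dwell time is the mean length
#' of maximal constant-label runs per state (in windows; also in
#' seconds when `stepSeconds` is given), `NA` for unvisited states.
#'
#' @param labels integer window labels in 1..k.
#' @param k number of states (default `max(labels)`).
#' @param stepSeconds seconds advanced per window step (window step x
#'   TR); optional.
#' @return list with `frequency`, `meanDwell`, `meanDwellSeconds`,
#'   `nTransitions`, `nWindows`.
#' @export
stateMetrics <- function(labels, k = max(labels), stepSeconds = NA_real_) {
  if (!length(labels)) stop("labels must be non-empty")
  labels <- as.integer(labels)
  freq <- tabulate(labels, k) / length(labels)
  r <- rle(labels)
  dwell <- vapply(seq_len(k), function(s) {
    runs <- r$lengths[r$values == s]
    if (length(runs)) mean(runs) else NA_real_
  }, numeric(1))
  names(freq) <- names(dwell) <- paste0("state", seq_len(k))
  list(frequency = freq, meanDwell = dwell,
       meanDwellSeconds = dwell * stepSeconds,
       nTransitions = countTransitions(labels), nWindows = length(labels))
}

#' Per subject-run state metric table
#'
#' @param partition a [StatePartition-class].
#' @param stepSeconds seconds per window step (optional; used for dwell
#'   time in seconds).
#' @return data.frame: one row per subject-run with frequency and dwell
#'   columns per state plus the transition count.
#' @export
stateMetricsTable <- function(partition, stepSeconds = NA_real_) {
  stopifnot(is(partition, "StatePartition"))
  k <- partition@k
  rows <- lapply(seq_along(partition@labels), function(i) {
    m <- stateMetrics(partition@labels[[i]], k = k,
                      stepSeconds = stepSeconds)
    cbind(partition@runTable[i, , drop = FALSE],
          nWindows = m$nWindows, nTransitions = m$nTransitions,
          as.data.frame(as.list(stats::setNames(
            m$frequency, paste0("freq_", seq_len(k))))),
          as.data.frame(as.list(stats::setNames(
            m$meanDwell, paste0("dwell_", seq_len(k))))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Occupancy scan over candidate state counts
#'
#' Clusters the pooled windows at every `k` in `kRange` and inspects the
#' cohort-mean state frequencies. A `k` is flagged when more than half
#' of its states fall below the top of the low-occupancy band (states
#' with mean frequency of only a few percent indicate an over-split
#' solution). The recommended `k` is the largest unflagged value.
#'
#' @param stacks list of [WindowedConnectivity-class].
#' @param kRange candidate state counts (default 2:8).
#' @param lowBand low-occupancy frequency band (default c(0.02, 0.04));
#'   the upper edge is the flagging threshold.
#' @param seed,nReplicates,groups passed to [clusterStates()].
#' @return list with `table` (k, nLowOccupancy, flagged), `frequencies`
#'   (per-k cohort-mean frequency vectors) and `recommendedK` (`NA` if
#'   every k is flagged).
#' @export
occupancyScan <- function(stacks, kRange = 2:8, lowBand = c(0.02, 0.04),
                          seed = 1L, nReplicates = 5L, groups = NULL) {
  pooled <- poolStacks(stacks)
  if (min(kRange) < 2 || max(kRange) > nrow(pooled$E))
    stop("kRange must lie within [2, total window count]")
  freqs <- vector("list", length(kRange))
  nLow <- integer(length(kRange))
  flagged <- logical(length(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    part <- clusterStates(stacks, k, seed = seed, nReplicates = nReplicates,
                          groups = groups)
    fm <- do.call(rbind, lapply(part@labels, function(l)
      tabulate(l, k) / length(l)))
    freqs[[i]] <- colMeans(fm)
    nLow[i] <- sum(freqs[[i]] < lowBand[2])
    flagged[i] <- nLow[i] > k / 2
  }
  names(freqs) <- paste0("k", kRange)
  tab <- data.frame(k = kRange, nLowOccupancy = nLow, flagged = flagged)
  recommended <- if (any(!flagged)) max(kRange[!flagged]) else NA_integer_
  if (is.na(recommended))
    warning("every k in the scan is flagged for low occupancy")
  list(table = tab, frequencies = freqs, recommendedK = recommended)
}

#' Group-mean transitions as a function of k
#'
#' Clusters the pooled windows at every `k` in `kRange`, computes each
#' subject's mean transition count (averaged over runs), and compares
#' the two groups with Welch's t-test at each `k`.
#'
#' @param stacks list of [WindowedConnectivity-class].
#' @param groups named character vector mapping subjectId to group
#'   (exactly 2 groups, >= 2 subjects each).
#' @param kRange candidate state counts (default 2:8).
#' @param seed,nReplicates passed to [clusterStates()].
#' @return data.frame with one row per k: group means, SDs, standard
#'   errors, Welch statistic and p-value.
#' @export
transitionsVsK <- function(stacks, groups, kRange = 2:8, seed = 1L,
                           nReplicates = 5L) {
  gl <- sort(unique(groups))
  if (length(gl) != 2) stop("transitionsVsK needs exactly 2 groups")
  out <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    part <- clusterStates(stacks, k, seed = seed, nReplicates = nReplicates,
                          groups = groups)
    tr <- vapply(part@labels, countTransitions, integer(1))
    bySubj <- tapply(tr, part@runTable$subjectId, mean)
    grpOf <- groups[names(bySubj)]
    x <- bySubj[grpOf == gl[1]]
    y <- bySubj[grpOf == gl[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("each group needs >= 2 subjects")
    tt <- stats::t.test(x, y, var.equal = FALSE)
    out[[i]] <- data.frame(
      k = k, group1 = gl[1], mean1 = mean(x), sd1 = stats::sd(x),
      se1 = stats::sd(x) / sqrt(length(x)),
      group2 = gl[2], mean2 = mean(y), sd2 = stats::sd(y),
      se2 = stats::sd(y) / sqrt(length(y)),
      statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Majority ground-truth label per window
#'
#' Maps a volume-level state sequence onto windows: each window gets the
#' most frequent volume label it covers (ties broken to the lowest
#' label). Used to compare estimated window labels with generator
#' ground truth.
#'
#' @param volumeLabels integer label per volume.
#' @param windows data.frame from [makeWindows()].
#' @return integer label per window.
#' @export
windowMajorityLabels <- function(volumeLabels, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    seg <- volumeLabels[windows$start[i]:windows$end[i]]
    tab <- tabulate(seg)
    which.max(tab)
  }, integer(1))
}
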