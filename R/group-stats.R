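#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation after pairwise deletion of missing
#' values; the two-sided p-value uses the t transform with `n - 2`
#' degrees of freedom. Zero variance in either vector yields `NA`
#' with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  tstat <- if (abs(r) >= 1) Inf else r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Test-retest reliability report
#'
#' Correlates each metric column between run 1 and run 2, per group.
#' Subjects missing either run are excluded (count reported per row).
#'
#' @param metricsRun1,metricsRun2 data.frames with a `subjectId` column
#'   plus numeric metric columns (shared names are correlated).
#' @param groupMap named character vector subjectId -> group; `NULL`
#'   pools all subjects as group `"all"`.
#' @return data.frame with `group`, `metric`, `r`, `p`, `n`,
#'   `nExcluded`.
#' @export
testretestReport <- function(metricsRun1, metricsRun2, groupMap = NULL) {
  common <- intersect(metricsRun1$subjectId, metricsRun2$subjectId)
  if (!length(common)) stop("no overlapping subjects between runs")
  nExcluded <- length(union(metricsRun1$subjectId,
                            metricsRun2$subjectId)) - length(common)
  m1 <- metricsRun1[match(common, metricsRun1$subjectId), , drop = FALSE]
  m2 <- metricsRun2[match(common, metricsRun2$subjectId), , drop = FALSE]
  metrics <- intersect(names(m1), names(m2))
  metrics <- metrics[vapply(m1[metrics], is.numeric, logical(1))]
  grp <- if (is.null(groupMap)) rep("all", length(common)) else
    unname(groupMap[common])
  rows <- list()
  for (g in unique(grp)) {
    idx <- grp == g
    for (met in metrics) {
      res <- tryCatch(
        suppressWarnings(pearsonR(m1[[met]][idx], m2[[met]][idx])),
        error = function(e) list(r = NA_real_, p = NA_real_,
                                 n = sum(idx)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = met, r = res$r, p = res$p, n = res$n,
        nExcluded = nExcluded, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dominant-state contingency test between groups
#'
#' Each subject is assigned the state it visits most frequently (ties
#' broken to the lowest state id); the group x dominant-state table is
#' tested with Pearson's chi-square (no continuity correction). Expected
#' counts below 5 trigger a small-cell warning.
#'
#' @param dominantState integer (or factor) dominant state per subject.
#' @param groupMap character group per subject (aligned).
#' @return list with `statistic`, `df`, `p`, `table`, `expected`.
#' @export
dominantStateTest <- function(dominantState, groupMap) {
  if (length(dominantState) != length(groupMap))
    stop("dominantState and groupMap must align")
  if (any(table(groupMap) == 0) || length(unique(groupMap)) < 2)
    stop("need >= 2 non-empty groups")
  tab <- table(group = groupMap, state = dominantState)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(res$expected < 5))
    warning("expected cell counts below 5; chi-square approximation weak")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, table = tab, expected = res$expected)
}

#' Dominant state per subject from a metrics table
#'
#' Averages each subject's state frequencies over runs and returns the
#' state with maximal mean frequency (ties to the lowest state id).
#'
#' @param metricsTable output of [stateMetricsTable()].
#' @return named integer vector (subjectId -> dominant state).
#' @export
dominantStates <- function(metricsTable) {
  freqCols <- grep("^freq_", names(metricsTable), value = TRUE)
  subj <- unique(metricsTable$subjectId)
  out <- vapply(subj, function(s) {
    f <- colMeans(metricsTable[metricsTable$subjectId == s, freqCols,
                               drop = FALSE])
    which.max(f)   # ties resolved to the lowest state id
  }, integer(1))
  names(out) <- subj
  out
}

#' All-pairs correlation table
#'
#' Correlates every predictor column with every outcome column (raw
#' Pearson correlations; sign conventions of the inputs are not
#' altered). An optional Benjamini-Hochberg column adjusts across the
#' whole table.
#'
#' @param predictors,outcomes data.frames (or matrices) of aligned
#'   numeric columns.
#' @param adjust add a BH-adjusted p column (default TRUE).
#' @return data.frame with `predictor`, `outcome`, `r`, `p`, `n` (and
#'   `p.adj`).
#' @export
correlationTable <- function(predictors, outcomes, adjust = TRUE) {
  predictors <- as.data.frame(predictors)
  outcomes <- as.data.frame(outcomes)
  if (nrow(predictors) != nrow(outcomes))
    stop("predictors and outcomes must have aligned rows")
  rows <- list()
  for (pv in names(predictors)) for (ov in names(outcomes)) {
    res <- tryCatch(
      suppressWarnings(pearsonR(predictors[[pv]], outcomes[[ov]])),
      error = function(e) list(r = NA_real_, p = NA_real_, n = NA_integer_))
    rows[[length(rows) + 1L]] <- data.frame(
      predictor = pv, outcome = ov, r = res$r, p = res$p, n = res$n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p.adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Two-group comparison (Welch)
#'
#' Welch's two-sample t-test (unequal variances) with per-group
#' descriptives.
#'
#' @param values numeric vector.
#' @param groupMap character group per value (exactly 2 groups, >= 2
#'   values each).
#' @return list with `means`, `sds`, `ns`, `statistic`, `df`, `p`.
#' @export
groupMeanCompare <- function(values, groupMap) {
  if (length(values) != length(groupMap))
    stop("values and groupMap must align")
  gl <- sort(unique(groupMap))
  if (length(gl) != 2) stop("need exactly 2 groups")
  x <- values[groupMap == gl[1]]
  y <- values[groupMap == gl[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 values")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(means = stats::setNames(c(mean(x), mean(y)), gl),
       sds = stats::setNames(c(stats::sd(x), stats::sd(y)), gl),
       ns = stats::setNames(c(length(x), length(y)), gl),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
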