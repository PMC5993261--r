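pipelineDefaults <- function() list(
  cohort = list(nSubjectsPerGroup = 20L, nVolumes = 240L, nNodes = 20L,
                nStates = 4L, noiseSd = 0.5, subjectConcentration = 0.4,
                selfProbControl = 0.965, selfProbClinical = 0.972),
  input = list(dir = NULL),
  prep = list(nDiscard = 4L, cutoffHz = 0.15, splitHz = 0.10),
  window = list(windowLength = 15L, step = 1L, taper = "rectangular",
                taperSigma = 3, estimator = "correlation",
                l1Penalty = 0.1),
  clustering = list(k = 6L, kRange = NULL, nReplicates = 5L),
  metrics = list(alpha = 0.05, sdMultiplier = 1.5,
                 edgeThreshold = list(type = "top_frac", frac = 0.1),
                 hubMetric = "cost"))

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, checks every field
#' against its contract, rejects unknown keys, and fills defaults.
#' Every violation is reported (with its config path) in a single
#' error; nothing is partially accepted.
#'
#' @param config path to a YAML config file, or a nested list; `NULL`
#'   uses all defaults.
#' @return the validated config list with defaults filled in; the
#'   defaulted keys are recorded in the `"defaulted"` attribute.
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- pipelineDefaults()
  errs <- character()
  unknownTop <- setdiff(names(config), names(def))
  if (length(unknownTop))
    errs <- c(errs, paste0("unknown section(s): ",
                           paste(unknownTop, collapse = ", ")))
  defaulted <- character()
  merged <- def
  for (sec in intersect(names(config), names(def))) {
    unknown <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(unknown))
      errs <- c(errs, paste0(sec, ": unknown key(s) ",
                             paste(unknown, collapse = ", ")))
    for (key in intersect(names(config[[sec]]), names(def[[sec]])))
      merged[[sec]][[key]] <- config[[sec]][[key]]
  }
  for (sec in names(def))
    for (key in names(def[[sec]]))
      if (is.null(config[[sec]][[key]]))
        defaulted <- c(defaulted, paste(sec, key, sep = "."))

  chk <- function(cond, path, reason)
    if (!isTRUE(cond)) errs <<- c(errs, paste0(path, ": ", reason))
  m <- merged
  chk(m$prep$nDiscard >= 0, "prep.nDiscard", "must be >= 0")
  chk(m$prep$cutoffHz > 0, "prep.cutoffHz", "must be positive")
  chk(m$window$windowLength >= 3, "window.windowLength", "minimum is 3")
  chk(m$window$step >= 1, "window.step", "must be >= 1")
  chk(m$window$taper %in% c("rectangular", "gaussian"), "window.taper",
      "must be rectangular or gaussian")
  chk(m$window$estimator %in% c("correlation", "sparse_precision"),
      "window.estimator", "must be correlation or sparse_precision")
  chk(m$window$l1Penalty >= 0, "window.l1Penalty", "must be >= 0")
  if (!is.null(m$clustering$kRange)) {
    chk(length(m$clustering$kRange) >= 1 && min(m$clustering$kRange) >= 2,
        "clustering.kRange", "entries must be >= 2")
  } else {
    chk(m$clustering$k >= 2, "clustering.k", "must be >= 2")
  }
  chk(m$clustering$nReplicates >= 1, "clustering.nReplicates",
      "must be >= 1")
  chk(m$metrics$alpha > 0 && m$metrics$alpha < 1, "metrics.alpha",
      "must be in (0, 1)")
  chk(m$metrics$sdMultiplier > 0, "metrics.sdMultiplier",
      "must be positive")
  chk(m$metrics$edgeThreshold$type %in% c("none", "abs", "top_frac"),
      "metrics.edgeThreshold.type", "must be none, abs or top_frac")
  chk(m$metrics$hubMetric %in% c("cost", "strength", "degree"),
      "metrics.hubMetric", "must be cost, strength or degree")
  chk(m$cohort$nVolumes > m$window$windowLength, "cohort.nVolumes",
      "must exceed the window length")
  chk(m$cohort$noiseSd >= 0, "cohort.noiseSd", "must be >= 0")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  attr(merged, "defaulted") <- defaulted
  merged
}

readCohortDir <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"),
                                header = TRUE, sep = "\t",
                                comment.char = "#")
  nodeMeta <- utils::read.table(file.path(dir, "node_meta.tsv"),
                                header = TRUE, sep = "\t",
                                comment.char = "#")
  tc <- manifest[manifest$type == "timecourses", ]
  subjects <- unique(tc$subjectId)
  lapply(subjects, function(sid) {
    rows <- tc[tc$subjectId == sid, ]
    runs <- lapply(rows$file, function(f)
      readTimeCourses(file.path(dir, f), nodeMeta = nodeMeta))
    labels <- lapply(seq_len(nrow(rows)), function(i) {
      lf <- manifest[manifest$type == "labels" &
                       manifest$subjectId == sid &
                       manifest$runId == rows$runId[i], "file"]
      if (length(lf)) readStateLabels(file.path(dir, lf[1])) else
        rep(NA_integer_, nrow(runs[[i]]@data))
    })
    grp <- sub("[0-9]+$", "", sid)
    new("SubjectRecord", subjectId = sid, group = grp, runs = runs,
        stateLabels = labels,
        transitionModel = makeGroupTransition(2, 0.5))
  })
}

#' Run the full dynamic-connectivity analysis pipeline
#'
#' Orchestrates: cohort synthesis (or loading), preparation + QC,
#' windowed connectivity, state clustering (with an occupancy scan when
#' a `kRange` is configured), state metrics, static and state-level
#' graph metrics, test-retest reliability and group statistics. Every
#' output table carries a provenance header (config hash, seed,
#' package version) and is listed with its checksum in
#' `manifest.tsv`. Rerunning with the same config and seed reproduces
#' the tables bit-identically.
#'
#' @param config validated config (see [validateConfig()]), a YAML
#'   path, or `NULL` for defaults.
#' @param seed master seed for cohort synthesis and clustering.
#' @param outDir output directory (must not already contain a
#'   manifest; outputs are write-once per run directory).
#' @param cohort optionally, a pre-built cohort (list of
#'   [SubjectRecord-class]) to analyse instead of synthesizing one.
#' @return invisible list with the main in-memory results
#'   (`stateMetrics`, `partition`, `reliability`, `groupStats`,
#'   `occupancy`, `qc`, `staticMetrics`, `stateGraphs`).
#' @export
runPipeline <- function(config = NULL, seed = 1L, outDir = tempfile("dfc"),
                        cohort = NULL) {
  cfg <- if (is.list(config) && !is.null(attr(config, "defaulted")))
    config else validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(outDir, "manifest.tsv")))
    stop("outDir already contains a pipeline run; outputs are write-once")
  cfgHash <- objectHash(cfg)
  prov <- c(paste0("config_hash: ", cfgHash),
            paste0("seed: ", seed),
            paste0("package: dfcstates ",
                   as.character(utils::packageVersion("dfcstates"))))
  emit <- function(df, name) {
    writeTsv(df, file.path(outDir, name), prov)
    name
  }
  files <- character()

  ## stage 1: cohort ---------------------------------------------------------
  if (is.null(cohort)) {
    if (!is.null(cfg$input$dir)) {
      cohort <- readCohortDir(cfg$input$dir)
    } else {
      spec <- defaultCohortSpec(
        seed = seed,
        nSubjectsPerGroup = cfg$cohort$nSubjectsPerGroup,
        nVolumes = cfg$cohort$nVolumes, nNodes = cfg$cohort$nNodes,
        nStates = cfg$cohort$nStates, noiseSd = cfg$cohort$noiseSd,
        subjectConcentration = cfg$cohort$subjectConcentration)
      spec@groups <- list(
        control = makeGroupTransition(cfg$cohort$nStates,
                                      cfg$cohort$selfProbControl),
        clinical = makeGroupTransition(cfg$cohort$nStates,
                                       cfg$cohort$selfProbClinical))
      cohort <- generateCohort(spec)
    }
  }
  groups <- vapply(cohort, function(s) s@group, character(1))
  names(groups) <- vapply(cohort, function(s) s@subjectId, character(1))

  ## stage 2: prep + QC ------------------------------------------------------
  qcRows <- list()
  prepped <- lapply(cohort, function(s) {
    s@runs <- lapply(s@runs, function(ts) {
      qc <- tryCatch(componentQC(ts, splitHz = cfg$prep$splitHz),
                     error = function(e) NULL)
      if (!is.null(qc))
        qcRows[[length(qcRows) + 1L]] <<-
          cbind(subjectId = ts@subjectId, runId = ts@runId, qc)
      prepTimeSeries(ts, nDiscard = min(cfg$prep$nDiscard,
                                        nrow(ts@data) - 1L),
                     cutoffHz = cfg$prep$cutoffHz)
    })
    s@stateLabels <- lapply(seq_along(s@stateLabels), function(i) {
      l <- s@stateLabels[[i]]
      nd <- length(l) - nrow(s@runs[[i]]@data)
      if (nd > 0) l[-seq_len(nd)] else l
    })
    s
  })
  if (length(qcRows))
    files <- c(files, emit(do.call(rbind, qcRows), "qc_report.tsv"))

  ## stage 3: windowed connectivity ------------------------------------------
  wp <- windowParams(cfg$window$windowLength, cfg$window$step,
                     cfg$window$taper, cfg$window$taperSigma,
                     cfg$window$estimator, cfg$window$l1Penalty)
  stacks <- list()
  for (s in prepped) for (ts in s@runs)
    stacks[[length(stacks) + 1L]] <- dfcStack(ts, wp)

  ## stage 4: state clustering -----------------------------------------------
  occ <- NULL
  k <- cfg$clustering$k
  if (!is.null(cfg$clustering$kRange)) {
    occ <- occupancyScan(stacks, kRange = cfg$clustering$kRange,
                         seed = seed,
                         nReplicates = cfg$clustering$nReplicates,
                         groups = groups)
    files <- c(files, emit(occ$table, "occupancy_scan.tsv"))
    k <- if (!is.na(occ$recommendedK)) occ$recommendedK else
      max(cfg$clustering$kRange)
    message("occupancy scan selected k = ", k)
  }
  part <- clusterStates(stacks, k, seed = seed,
                        nReplicates = cfg$clustering$nReplicates,
                        groups = groups)
  cent <- as.data.frame(part@centroids)
  names(cent) <- paste0("e", seq_len(ncol(cent)))
  files <- c(files, emit(cent, "state_centroids.tsv"))

  ## stage 5: state metrics --------------------------------------------------
  tr0 <- prepped[[1]]@runs[[1]]@trSeconds
  sm <- stateMetricsTable(part, stepSeconds = cfg$window$step * tr0)
  files <- c(files, emit(sm, "state_metrics.tsv"))

  ## stage 6: static graph metrics per subject-run ---------------------------
  nodeMeta <- prepped[[1]]@runs[[1]]@nodeMeta
  statRows <- list()
  for (s in prepped) for (ts in s@runs) {
    R <- stats::cor(ts@data)
    adj <- fdrThresholdAdjacency(R, nSamples = nrow(ts@data),
                                 alpha = cfg$metrics$alpha,
                                 nodeMeta = nodeMeta)
    gm <- graphMetrics(adj, sdMultiplier = cfg$metrics$sdMultiplier,
                       hubMetric = cfg$metrics$hubMetric)
    statRows[[length(statRows) + 1L]] <- data.frame(
      subjectId = ts@subjectId, runId = ts@runId,
      group = groups[[ts@subjectId]],
      totalConnections = gm$totalConnections, meanCC = gm$meanCC,
      pathLength = gm$pathLength,
      globalEfficiency = gm$globalEfficiency,
      networkStrength = gm$networkStrength,
      networkCost = gm$networkCost,
      nHubs = length(gm$hubs))
  }
  staticTab <- do.call(rbind, statRows)
  files <- c(files, emit(staticTab, "static_graph_metrics.tsv"))

  ## stage 7: state-level graph metrics on centroids -------------------------
  stateRows <- list()
  stateGraphs <- list()
  for (s in seq_len(part@k)) {
    adj <- centroidToStateGraph(part@centroids[s, ], nodeMeta,
                                rule = cfg$metrics$edgeThreshold)
    gm <- graphMetrics(adj, sdMultiplier = cfg$metrics$sdMultiplier,
                       hubMetric = cfg$metrics$hubMetric)
    stateGraphs[[s]] <- gm
    stateRows[[s]] <- data.frame(
      state = s, totalConnections = gm$totalConnections,
      meanCC = gm$meanCC, pathLength = gm$pathLength,
      globalEfficiency = gm$globalEfficiency,
      networkStrength = gm$networkStrength,
      networkCost = gm$networkCost,
      hubs = paste(names(gm$hubs) %||% gm$hubs, collapse = ","))
  }
  files <- c(files, emit(do.call(rbind, stateRows),
                         "state_graph_metrics.tsv"))

  ## stage 8: reliability ----------------------------------------------------
  rel <- NULL
  runIds <- unique(sm$runId)
  if (length(runIds) >= 2) {
    keep <- c("subjectId", "nTransitions",
              grep("^freq_", names(sm), value = TRUE))
    m1 <- sm[sm$runId == runIds[1], keep]
    m2 <- sm[sm$runId == runIds[2], keep]
    st1 <- staticTab[staticTab$runId == runIds[1],
                     c("subjectId", "meanCC", "pathLength")]
    st2 <- staticTab[staticTab$runId == runIds[2],
                     c("subjectId", "meanCC", "pathLength")]
    rel <- rbind(testretestReport(m1, m2, groups),
                 testretestReport(st1, st2, groups))
    files <- c(files, emit(rel, "reliability.tsv"))
  }

  ## stage 9: group statistics -----------------------------------------------
  gstats <- list()
  if (length(unique(groups)) == 2) {
    bySubj <- tapply(sm$nTransitions, sm$subjectId, mean)
    cmp <- groupMeanCompare(as.numeric(bySubj), groups[names(bySubj)])
    dom <- dominantStates(sm)
    chi <- tryCatch(dominantStateTest(dom, groups[names(dom)]),
                    error = function(e) NULL)
    gstats <- list(transitions = cmp, dominantState = chi)
    gl <- names(cmp$means)
    gdf <- data.frame(
      comparison = c("transitions_welch",
                     if (!is.null(chi)) "dominant_state_chisq"),
      statistic = c(cmp$statistic, if (!is.null(chi)) chi$statistic),
      df = c(cmp$df, if (!is.null(chi)) chi$df),
      p = c(cmp$p, if (!is.null(chi)) chi$p),
      detail = c(sprintf("%s mean %.2f vs %s mean %.2f", gl[1],
                         cmp$means[1], gl[2], cmp$means[2]),
                 if (!is.null(chi)) paste(dim(chi$table), collapse = "x")))
    files <- c(files, emit(gdf, "group_stats.tsv"))
  }

  ## manifest ----------------------------------------------------------------
  manifest <- data.frame(
    file = files,
    md5 = vapply(files, function(f)
      unname(tools::md5sum(file.path(outDir, f))), character(1)))
  writeTsv(manifest, file.path(outDir, "manifest.tsv"), prov)

  invisible(list(stateMetrics = sm, partition = part, reliability = rel,
                 groupStats = gstats, occupancy = occ,
                 staticMetrics = staticTab, stateGraphs = stateGraphs,
                 outDir = outDir))
}
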