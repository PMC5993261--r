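## Tab-separated I/O with '#'-prefixed provenance/metadata headers.

writeTsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

readTsvMeta <- function(path) {
  lines <- readLines(path, n = 50)
  meta <- sub("^# ", "", lines[startsWith(lines, "#")])
  out <- list()
  for (m in meta) {
    kv <- strsplit(m, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) out[[kv[1]]] <- kv[2]
  }
  out
}

#' Write / read node time courses
#'
#' Tab-separated, volumes as rows, nodes as columns, header row of node
#' ids; subject, run and TR are carried in `#`-prefixed header lines.
#'
#' @param ts a [ComponentTimeSeries-class].
#' @param path file path.
#' @return `writeTimeCourses` returns `path` invisibly;
#'   `readTimeCourses` returns a [ComponentTimeSeries-class].
#' @export
writeTimeCourses <- function(ts, path) {
  stopifnot(is(ts, "ComponentTimeSeries"))
  hdr <- c(paste0("subject: ", ts@subjectId),
           paste0("run: ", ts@runId),
           paste0("tr_seconds: ", format(ts@trSeconds, digits = 17)),
           paste0("prep: ", paste(ts@prepState, collapse = ",")))
  df <- as.data.frame(ts@data)
  names(df) <- if (nrow(ts@nodeMeta)) ts@nodeMeta$node else
    sprintf("N%02d", seq_len(ncol(ts@data)))
  writeTsv(df, path, hdr)
  invisible(path)
}

#' @rdname writeTimeCourses
#' @param nodeMeta optional node metadata to attach on read.
#' @export
readTimeCourses <- function(path, nodeMeta = data.frame()) {
  meta <- readTsvMeta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  prep <- if (!is.null(meta$prep) && nzchar(meta$prep))
    strsplit(meta$prep, ",", fixed = TRUE)[[1]] else character(0)
  new("ComponentTimeSeries", data = as.matrix(df),
      trSeconds = as.numeric(meta$tr_seconds %||% 2),
      subjectId = meta$subject %||% "unknown",
      runId = meta$run %||% "unknown",
      nodeMeta = nodeMeta, prepState = prep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a ground-truth state label sequence
#'
#' One integer label per line.
#'
#' @param labels integer labels.
#' @param path file path.
#' @export
writeStateLabels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' @rdname writeStateLabels
#' @export
readStateLabels <- function(path) as.integer(readLines(path))

#' Write / read a transition model
#'
#' The K x K matrix as TSV; the initial distribution in a header line.
#'
#' @param model a [TransitionModel-class].
#' @param path file path.
#' @export
writeTransitionModel <- function(model, path) {
  stopifnot(is(model, "TransitionModel"))
  hdr <- paste0("initial: ",
                paste(format(model@initial, digits = 17), collapse = ","))
  writeTsv(as.data.frame(model@matrix), path, hdr)
  invisible(path)
}

#' @rdname writeTransitionModel
#' @export
readTransitionModel <- function(path) {
  meta <- readTsvMeta(path)
  P <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   comment.char = "#"))
  init <- as.numeric(strsplit(meta$initial, ",", fixed = TRUE)[[1]])
  ## re-normalize away round-trip float noise, preserving stochasticity
  P <- P / rowSums(P)
  new("TransitionModel", matrix = unname(P), initial = init / sum(init))
}

#' Write / read a windowed connectivity stack
#'
#' Long format: one row per (window, edge) with columns `window`,
#' `node_i`, `node_j`, `value`; estimator parameters in header lines.
#'
#' @param wc a [WindowedConnectivity-class].
#' @param path file path.
#' @export
writeWindowedConnectivity <- function(wc, path) {
  stopifnot(is(wc, "WindowedConnectivity"))
  p <- wc@nNodes
  ij <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  nW <- nrow(wc@edges)
  df <- data.frame(
    window = rep(seq_len(nW), each = nrow(ij)),
    node_i = rep(ij[, "row"], nW), node_j = rep(ij[, "col"], nW),
    value = as.numeric(t(wc@edges)))
  hdr <- c(paste0("subject: ", wc@subjectId), paste0("run: ", wc@runId),
           paste0("n_nodes: ", p),
           paste0("window_length: ", wc@params@windowLength),
           paste0("step: ", wc@params@step),
           paste0("taper: ", wc@params@taper),
           paste0("estimator: ", wc@params@estimator),
           paste0("l1_penalty: ", wc@params@l1Penalty),
           paste0("window_starts: ",
                  paste(wc@windowStarts, collapse = ",")))
  writeTsv(df, path, hdr)
  invisible(path)
}

#' @rdname writeWindowedConnectivity
#' @export
readWindowedConnectivity <- function(path) {
  meta <- readTsvMeta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  p <- as.integer(meta$n_nodes)
  nE <- p * (p - 1) / 2
  E <- matrix(df$value, ncol = nE, byrow = TRUE)
  params <- windowParams(
    windowLength = as.integer(meta$window_length),
    step = as.integer(meta$step), taper = meta$taper,
    estimator = meta$estimator, l1Penalty = as.numeric(meta$l1_penalty))
  new("WindowedConnectivity", edges = E, nNodes = p,
      windowStarts = as.integer(
        strsplit(meta$window_starts, ",", fixed = TRUE)[[1]]),
      params = params, subjectId = meta$subject %||% "unknown",
      runId = meta$run %||% "unknown", nodeMeta = data.frame())
}

#' Write a synthetic cohort to disk
#'
#' One time-course TSV and one ground-truth label file per subject-run,
#' the node metadata table, each subject's transition model, and a
#' manifest listing every file.
#'
#' @param cohort list of [SubjectRecord-class] from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- cohort[[1]]@runs[[1]]@nodeMeta
  writeTsv(nm, file.path(dir, "node_meta.tsv"))
  rows <- list(data.frame(subjectId = NA, runId = NA, type = "node_meta",
                          file = "node_meta.tsv"))
  for (s in cohort) {
    tmFile <- paste0(s@subjectId, "_transitions.tsv")
    writeTransitionModel(s@transitionModel, file.path(dir, tmFile))
    rows[[length(rows) + 1L]] <- data.frame(
      subjectId = s@subjectId, runId = NA, type = "transition_model",
      file = tmFile)
    for (r in seq_along(s@runs)) {
      tcFile <- sprintf("%s_run%d_timecourses.tsv", s@subjectId, r)
      lbFile <- sprintf("%s_run%d_labels.txt", s@subjectId, r)
      writeTimeCourses(s@runs[[r]], file.path(dir, tcFile))
      writeStateLabels(s@stateLabels[[r]], file.path(dir, lbFile))
      rows[[length(rows) + 1L]] <- data.frame(
        subjectId = s@subjectId, runId = sprintf("run%d", r),
        type = "timecourses", file = tcFile)
      rows[[length(rows) + 1L]] <- data.frame(
        subjectId = s@subjectId, runId = sprintf("run%d", r),
        type = "labels", file = lbFile)
    }
  }
  manifest <- do.call(rbind, rows)
  writeTsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
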