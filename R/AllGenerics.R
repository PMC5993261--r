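#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; use these
#' rather than reaching into slots.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The corresponding component (matrix, numeric, data.frame, ...).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("nodeMeta", function(x) standardGeneric("nodeMeta"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname accessors
#' @export
setGeneric("prepState", function(x) standardGeneric("prepState"))

#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname accessors
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' @rdname accessors
#' @export
setGeneric("stateCentroids", function(x) standardGeneric("stateCentroids"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("runTable", function(x) standardGeneric("runTable"))

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setGeneric("stateCovariances", function(x) standardGeneric("stateCovariances"))

#' @rdname accessors
#' @export
setGeneric("adjWeights", function(x) standardGeneric("adjWeights"))

#' @rdname accessors
#' @export
setGeneric("adjMask", function(x) standardGeneric("adjMask"))

setMethod("tsData", "ComponentTimeSeries", function(x) x@data)
setMethod("trSeconds", "ComponentTimeSeries", function(x) x@trSeconds)
setMethod("nodeMeta", "ComponentTimeSeries", function(x) x@nodeMeta)
setMethod("nNodes", "ComponentTimeSeries", function(x) ncol(x@data))
setMethod("nVolumes", "ComponentTimeSeries", function(x) nrow(x@data))
setMethod("prepState", "ComponentTimeSeries", function(x) x@prepState)

setMethod("nWindows", "WindowedConnectivity", function(x) nrow(x@edges))
setMethod("nNodes", "WindowedConnectivity", function(x) x@nNodes)
setMethod("edgeMatrix", "WindowedConnectivity", function(x) x@edges)
setMethod("windowStarts", "WindowedConnectivity", function(x) x@windowStarts)
setMethod("nodeMeta", "WindowedConnectivity", function(x) x@nodeMeta)

setMethod("stateCentroids", "StatePartition", function(x) x@centroids)
setMethod("stateLabels", "StatePartition", function(x) x@labels)
setMethod("runTable", "StatePartition", function(x) x@runTable)

setMethod("transitionMatrix", "TransitionModel", function(x) x@matrix)
setMethod("stateCovariances", "StateLibrary", function(x) x@covariances)

setMethod("adjWeights", "AdjacencyMatrix", function(x) x@weights)
setMethod("adjMask", "AdjacencyMatrix", function(x) x@mask)

## show methods --------------------------------------------------------------

setMethod("show", "ComponentTimeSeries", function(object) {
  cat(sprintf("ComponentTimeSeries: %d volumes x %d nodes (TR = %gs)\n",
              nrow(object@data), ncol(object@data), object@trSeconds))
  cat(sprintf("  subject %s, run %s; prep: %s\n", object@subjectId,
              object@runId,
              if (length(object@prepState))
                paste(object@prepState, collapse = ", ") else "none"))
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel over %d states (mean self-transition %.3f)\n",
              nrow(object@matrix), mean(diag(object@matrix))))
})

setMethod("show", "StateLibrary", function(object) {
  cat(sprintf("StateLibrary: %d states over %d nodes, %d subnetwork blocks\n",
              length(object@covariances), nrow(object@covariances[[1]]),
              length(unique(object@networkLabels))))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d group(s) x %d subjects x %d run(s) x %d volumes (TR %gs)\n",
    length(object@groups), object@nSubjectsPerGroup, object@nRuns,
    object@nVolumes, object@trSeconds))
  cat(sprintf("  %d states, noiseSd %g, concentration %g, seed %d\n",
              length(object@stateLibrary@covariances), object@noiseSd,
              object@subjectConcentration, object@seed))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s (group %s): %d run(s)\n",
              object@subjectId, object@group, length(object@runs)))
})

setMethod("show", "WindowedConnectivity", function(object) {
  cat(sprintf(
    "WindowedConnectivity: %d windows x %d edges (%d nodes), %s estimator\n",
    nrow(object@edges), ncol(object@edges), object@nNodes,
    object@params@estimator))
  cat(sprintf("  subject %s, run %s; window %d volumes, step %d, %s taper\n",
              object@subjectId, object@runId, object@params@windowLength,
              object@params@step, object@params@taper))
})

setMethod("show", "StatePartition", function(object) {
  cat(sprintf(
    "StatePartition: k = %d states over %d subject-run(s), inertia %.4g\n",
    object@k, length(object@labels), object@inertia))
})

setMethod("show", "AdjacencyMatrix", function(object) {
  p <- nrow(object@weights)
  cat(sprintf("AdjacencyMatrix: %d nodes, %d/%d surviving edges\n",
              p, sum(object@mask[upper.tri(object@mask)]), p * (p - 1) / 2))
})
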