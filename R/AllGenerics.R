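#' Accessors for klsnet classes
#'
#' `subjectId()`, `regionIds()`, `regionTable()`, `sparsity()` and
#' `gammaThreshold()` retrieve the corresponding slots; `weights()` (the
#' standard stats generic) returns the adjacency matrix of a network.
#'
#' @param object a klsnet object.
#' @param ... unused.
#' @return The slot value: a character scalar, character vector, data.frame,
#'   numeric scalar or numeric matrix as appropriate.
#' @name accessors
#' @aliases subjectId regionIds regionTable sparsity gammaThreshold
#' @examples
#' cohort <- simulateConnectivityDirect(simulationConfig(
#'   nPatients = 2, nControls = 2, nRegions = 4, seed = 1))
#' net <- cohort$networks[[1]]
#' subjectId(net)
#' dim(weights(net))
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("regionIds", function(object) standardGeneric("regionIds"))

#' @rdname accessors
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))

#' @rdname accessors
#' @export
setGeneric("sparsity", function(object) standardGeneric("sparsity"))

#' @rdname accessors
#' @export
setGeneric("gammaThreshold", function(object) standardGeneric("gammaThreshold"))

#' @rdname accessors
#' @export
setMethod("subjectId", "ROISampleSet", function(object) object@subjectId)

#' @rdname accessors
#' @export
setMethod("subjectId", "KLSNetwork", function(object) object@subjectId)

#' @rdname accessors
#' @export
setMethod("regionIds", "ROISampleSet", function(object) names(object@samples))

#' @rdname accessors
#' @export
setMethod("regionIds", "KLSNetwork", function(object) rownames(object@weights))

#' @rdname accessors
#' @export
setMethod("regionIds", "LabelAtlas", function(object) as.character(object@regions$id))

#' @rdname accessors
#' @export
setMethod("regionTable", "LabelAtlas", function(object) object@regions)

#' @rdname accessors
#' @importFrom stats weights
#' @export
setMethod("weights", "KLSNetwork", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("weights", "ThresholdedNetwork", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("sparsity", "ThresholdedNetwork", function(object) object@sparsity)

#' @rdname accessors
#' @export
setMethod("gammaThreshold", "ThresholdedNetwork", function(object) object@gammaThreshold)

#' @rdname accessors
#' @param x a [ROISampleSet].
#' @param name region id.
#' @export
roiSamples <- function(x, name = NULL) {
  stopifnot(is(x, "ROISampleSet"))
  if (is.null(name)) x@samples else x@samples[[as.character(name)]]
}

#' @rdname accessors
#' @export
globalMean <- function(x) {
  stopifnot(is(x, "ROISampleSet"))
  x@globalMean
}
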