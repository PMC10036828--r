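#' @import methods
#' @importFrom stats density bw.nrd0 bw.SJ sd cor lm.fit pt p.adjust
#'   setNames rnorm runif quantile var integrate plogis qlogis optim
#'   complete.cases aggregate
#' @importFrom utils read.delim write.table head
NULL

#' BrainVolume: a 3D uptake image in a common template space
#'
#' Container for a single volumetric image: a 3D array of uptake values,
#' the voxel size in millimetres along each axis and the 4x4 voxel-to-world
#' affine. Inputs are assumed already registered to the template grid that
#' the label atlas lives on; no spatial normalization is performed here.
#'
#' @slot data 3D numeric array of voxel uptake values (arbitrary units).
#' @slot voxelSize numeric(3), voxel edge lengths (dx, dy, dz) in mm.
#' @slot affine 4x4 voxel-to-world matrix.
#'
#' @seealso [readBrainVolume()], [smoothGaussian()], [normalizeGlobalMean()]
#' @export
setClass("BrainVolume",
  representation(data = "array", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
      msg <- c(msg, "'data' must be a 3D array with all dimensions >= 1")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "'voxelSize' must be three positive finite values")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "'affine' must be a 4x4 matrix")
    if (length(msg)) msg else TRUE
  })

#' LabelAtlas: an integer parcellation with region metadata
#'
#' A 3D integer label image on the same grid as the subject volumes, plus a
#' region lookup table. The reference configuration is a 90-region cortical
#' and subcortical parcellation (45 per hemisphere, cerebellum excluded),
#' with every region assigned to one of six lobar groups: frontal, temporal,
#' parietal, occipital, central structures, and insula-and-cingulate.
#'
#' @slot labels 3D integer array; 0 marks out-of-atlas voxels.
#' @slot regions data.frame with columns `id` (positive integer), `name`
#'   (character) and `lobe` (character), one row per region, in the order
#'   that defines the rows/columns of all downstream matrices.
#'
#' @seealso [readLabelAtlas()], [extractROISamples()]
#' @export
setClass("LabelAtlas",
  representation(labels = "array", regions = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "'labels' must be a 3D array")
    r <- object@regions
    if (!all(c("id", "name", "lobe") %in% names(r)))
      msg <- c(msg, "'regions' needs columns id, name, lobe")
    else {
      if (anyDuplicated(r$id)) msg <- c(msg, "region ids must be unique")
      if (any(r$id <= 0)) msg <- c(msg, "region ids must be positive")
      present <- unique(as.vector(object@labels))
      present <- present[present != 0]
      if (!all(present %in% r$id))
        msg <- c(msg, "every nonzero voxel label must appear in regions$id")
      if (any(is.na(r$lobe) | !nzchar(r$lobe)))
        msg <- c(msg, "every region must map to a lobe")
    }
    if (length(msg)) msg else TRUE
  })

#' ROISampleSet: per-region voxel samples for one subject
#'
#' The normalized voxel uptake values of one subject, partitioned by atlas
#' region. Sample vectors are stored in atlas region order; the stored
#' global mean is the in-atlas mean prior to normalization.
#'
#' @slot subjectId character scalar.
#' @slot samples named list of numeric vectors, names are region ids.
#' @slot globalMean in-atlas mean uptake of the image the samples came from,
#'   before global-mean normalization.
#'
#' @seealso [extractROISamples()], [buildNetwork()]
#' @export
setClass("ROISampleSet",
  representation(subjectId = "character", samples = "list",
                 globalMean = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@subjectId) != 1L)
      msg <- c(msg, "'subjectId' must be a single string")
    if (length(object@samples) < 1L || is.null(names(object@samples)))
      msg <- c(msg, "'samples' must be a non-empty named list")
    else if (any(vapply(object@samples, length, 1L) == 0L))
      msg <- c(msg, "every region sample must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' KLSNetwork: a subject's KLS connectivity matrix
#'
#' Symmetric R x R adjacency of divergence-based similarities. Off-diagonal
#' entries lie in (0, 1] (1 means the two regional intensity distributions
#' are identical); the diagonal is fixed at 0 since self-connections play no
#' role in any of the graph analyses.
#'
#' @slot subjectId character scalar.
#' @slot weights symmetric numeric matrix with region ids as dimnames.
#'
#' @seealso [buildNetwork()], [applySparsityThreshold()]
#' @export
setClass("KLSNetwork",
  representation(subjectId = "character", weights = "matrix"),
  validity = function(object) {
    msg <- character()
    w <- object@weights
    if (nrow(w) != ncol(w)) msg <- c(msg, "'weights' must be square")
    else {
      if (max(abs(w - t(w))) > 1e-9) msg <- c(msg, "'weights' must be symmetric")
      if (any(abs(diag(w)) > 0)) msg <- c(msg, "diagonal must be 0")
      off <- w[upper.tri(w)]
      if (any(off <= 0 | off > 1 + 1e-12))
        msg <- c(msg, "off-diagonal entries must lie in (0, 1]")
      if (is.null(rownames(w))) msg <- c(msg, "'weights' needs region dimnames")
    }
    if (length(msg)) msg else TRUE
  })

#' ThresholdedNetwork: a sparsity-thresholded weighted network
#'
#' The result of retaining the strongest S * R(R-1)/2 connections of a
#' [KLSNetwork] and zeroing the rest. Surviving edges keep their weights
#' (the network stays weighted, not binarized).
#'
#' @slot weights symmetric numeric matrix, zeros off the retained edge set.
#' @slot sparsity achieved fraction of possible edges retained, in (0, 1].
#' @slot gammaThreshold the connection-strength cutoff realizing the
#'   sparsity: the weakest retained weight.
#'
#' @seealso [applySparsityThreshold()], [computeGlobalMetrics()]
#' @export
setClass("ThresholdedNetwork",
  representation(weights = "matrix", sparsity = "numeric",
                 gammaThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    w <- object@weights
    if (nrow(w) != ncol(w) || max(abs(w - t(w))) > 1e-9)
      msg <- c(msg, "'weights' must be square symmetric")
    if (object@sparsity <= 0 || object@sparsity > 1)
      msg <- c(msg, "'sparsity' must lie in (0, 1]")
    if (any(w[upper.tri(w)] < 0))
      msg <- c(msg, "thresholded weights must be non-negative")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat("BrainVolume:", paste(d, collapse = " x "),
      sprintf("voxels of %s mm\n",
              paste(format(object@voxelSize, digits = 3), collapse = " x ")))
})

setMethod("show", "LabelAtlas", function(object) {
  cat("LabelAtlas:", nrow(object@regions), "regions,",
      sum(object@labels != 0), "labelled voxels,",
      length(unique(object@regions$lobe)), "lobe groups\n")
})

setMethod("show", "ROISampleSet", function(object) {
  n <- vapply(object@samples, length, 1L)
  cat("ROISampleSet for subject", object@subjectId, "\n ",
      length(n), "regions;", sum(n), "voxels;",
      sprintf("pre-normalization global mean %.4g\n", object@globalMean))
})

setMethod("show", "KLSNetwork", function(object) {
  w <- object@weights[upper.tri(object@weights)]
  cat("KLSNetwork for subject", object@subjectId, "\n ",
      nrow(object@weights), "regions; KLS range",
      sprintf("[%.3f, %.3f]\n", min(w), max(w)))
})

setMethod("show", "ThresholdedNetwork", function(object) {
  cat(sprintf("ThresholdedNetwork: %d nodes, %d edges (sparsity %.3f, cutoff %.4f)\n",
              nrow(object@weights), sum(object@weights[upper.tri(object@weights)] > 0),
              object@sparsity, object@gammaThreshold))
})
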