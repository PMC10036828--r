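#' Read a volumetric image from NIfTI
#'
#' Loads a `.nii`/`.nii.gz` image into a [BrainVolume-class]. The image is
#' expected to already sit on the common template grid shared with the atlas.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [BrainVolume-class].
#' @export
plainArray <- function(img) {
  d <- dim(img)
  a <- array(as.numeric(img), d)
  if (length(d) == 4L && d[4] == 1L) dim(a) <- d[1:3]
  a
}

readBrainVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- plainArray(img)
  vx <- RNifti::pixdim(img)[1:3]
  new("BrainVolume", data = arr, voxelSize = as.numeric(vx),
      affine = unclass(RNifti::xform(img)))
}

#' Construct a BrainVolume from an array
#'
#' @param data 3D numeric array.
#' @param voxelSize numeric(3) voxel size in mm (default 2 mm isotropic).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `voxelSize`.
#' @return A [BrainVolume-class].
#' @export
brainVolume <- function(data, voxelSize = c(2, 2, 2), affine = NULL) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("BrainVolume", data = data, voxelSize = voxelSize, affine = affine)
}

#' Read a label atlas and its region lookup table
#'
#' The parcellation is a NIfTI integer image; region metadata comes from a
#' tab-separated lookup file with columns `id`, `name`, `lobe`. The lobe
#' column assigns each region to one of the six lobar groups used for
#' weight aggregation (frontal, temporal, parietal, occipital, central
#' structures, insula-and-cingulate).
#'
#' @param labelPath NIfTI file of integer labels (0 = outside the atlas).
#' @param lookupPath tab-separated lookup with columns id, name, lobe.
#' @return A [LabelAtlas-class].
#' @export
readLabelAtlas <- function(labelPath, lookupPath) {
  img <- RNifti::readNifti(labelPath)
  arr <- plainArray(img)
  storage.mode(arr) <- "integer"
  aff <- unclass(RNifti::xform(img))
  lut <- read.delim(lookupPath, stringsAsFactors = FALSE)
  out <- labelAtlas(arr, lut)
  attr(out@labels, "affine") <- aff
  out
}

#' Construct a LabelAtlas from an array and region table
#'
#' @param labels 3D integer array.
#' @param regions data.frame with columns id, name, lobe.
#' @return A [LabelAtlas-class].
#' @export
labelAtlas <- function(labels, regions) {
  storage.mode(labels) <- "integer"
  regions$id <- as.integer(regions$id)
  new("LabelAtlas", labels = labels,
      regions = regions[, c("id", "name", "lobe")])
}

gaussianKernel1d <- function(sigma) {
  # radius of 4 sigma keeps truncation error below 1e-4 of the mass
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

convolveAlongDim <- function(arr, kernel, dim) {
  d <- base::dim(arr)
  r <- (length(kernel) - 1L) / 2L
  # fold the target dimension to the front, pad with zeros, convolve rows
  perm <- c(dim, setdiff(1:3, dim))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[dim])
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, nrow(m), ncol(m))
  for (o in seq_along(kernel))
    out <- out + kernel[o] * padded[(o - 1L) + seq_len(nrow(m)), , drop = FALSE]
  a[] <- out
  aperm(a, order(perm))
}

#' Gaussian smoothing of a volumetric image
#'
#' Convolves the image with a separable 3D Gaussian whose full width at half
#' maximum is given in millimetres; the per-axis standard deviation in voxel
#' units is `fwhm / (2 sqrt(2 log 2)) / voxelSize`. Voxels beyond the image
#' edge are treated as zero (constant-zero boundary), so intensity leaks out
#' at the border but interior mass is preserved.
#'
#' @param img a [BrainVolume-class].
#' @param fwhm full width at half maximum of the kernel, mm. `0` returns the
#'   input unchanged. Default 6 mm.
#' @return A smoothed [BrainVolume-class].
#' @export
smoothGaussian <- function(img, fwhm = 6) {
  stopifnot(is(img, "BrainVolume"), fwhm >= 0)
  if (any(img@voxelSize <= 0)) stop("voxel size must be positive")
  if (fwhm == 0) return(img)
  sigmaVox <- fwhm / (2 * sqrt(2 * log(2))) / img@voxelSize
  arr <- img@data
  for (ax in 1:3) arr <- convolveAlongDim(arr, gaussianKernel1d(sigmaVox[ax]), ax)
  new("BrainVolume", data = arr, voxelSize = img@voxelSize, affine = img@affine)
}

#' Global-mean intensity normalization
#'
#' Divides every voxel by the mean uptake over the in-atlas (nonzero-label)
#' voxels, so that after normalization the whole-brain mean equals 1 and
#' intensities are comparable across subjects. An explicit logical mask may
#' replace the atlas-derived brain definition.
#'
#' @param img a [BrainVolume-class].
#' @param atlas a [LabelAtlas-class] on the same grid.
#' @param mask optional logical array overriding the nonzero-label mask.
#' @return List with `image` (normalized [BrainVolume-class]) and
#'   `globalMean` (the divisor used).
#' @export
normalizeGlobalMean <- function(img, atlas, mask = NULL) {
  stopifnot(is(img, "BrainVolume"))
  if (is.null(mask)) {
    stopifnot(is(atlas, "LabelAtlas"))
    if (!all(dim(img@data) == dim(atlas@labels)))
      stop("image and atlas dimensions differ")
    mask <- atlas@labels != 0L
  }
  if (!any(mask)) stop("brain mask is empty")
  gm <- mean(img@data[mask])
  if (!is.finite(gm) || gm <= 0)
    stop("degenerate image: in-mask mean is not positive")
  out <- new("BrainVolume", data = img@data / gm,
             voxelSize = img@voxelSize, affine = img@affine)
  list(image = out, globalMean = gm)
}

#' Extract per-region voxel samples
#'
#' Collects, for each atlas region, the values of the voxels carrying that
#' label, in ascending linear-index (array storage) order so downstream
#' density estimation is reproducible. Every region must contain at least
#' one voxel.
#'
#' @param img a (typically smoothed and normalized) [BrainVolume-class].
#' @param atlas a [LabelAtlas-class] on the same grid.
#' @param subjectId subject identifier stored with the samples.
#' @param globalMean pre-normalization global mean to record (default `NA`).
#' @param affineTol warn if image and atlas affines differ beyond this.
#' @return A [ROISampleSet-class] with one sample vector per region, in
#'   atlas region order.
#' @export
extractROISamples <- function(img, atlas, subjectId = "subject",
                              globalMean = NA_real_, affineTol = 1e-4) {
  stopifnot(is(img, "BrainVolume"), is(atlas, "LabelAtlas"))
  if (!all(dim(img@data) == dim(atlas@labels)))
    stop("image and atlas dimensions differ")
  atlasAffine <- attr(atlas@labels, "affine")
  if (!is.null(atlasAffine) &&
      max(abs(img@affine - atlasAffine)) > affineTol)
    warning("image and atlas affines differ beyond tolerance; ",
            "inputs are assumed pre-registered")
  ids <- atlas@regions$id
  lab <- as.vector(atlas@labels)
  val <- as.vector(img@data)
  samples <- lapply(ids, function(r) val[lab == r])
  empty <- vapply(samples, length, 1L) == 0L
  if (any(empty))
    stop("atlas regions with no voxels: ",
         paste(ids[empty], collapse = ", "))
  names(samples) <- as.character(ids)
  new("ROISampleSet", subjectId = subjectId, samples = samples,
      globalMean = as.numeric(globalMean))
}

#' One-call ROI extraction pipeline for a subject image
#'
#' Smooth, globally normalize, and extract region samples in the standard
#' order (smoothing first, then normalization to the whole-brain mean).
#'
#' @param img a [BrainVolume-class].
#' @param atlas a [LabelAtlas-class].
#' @param subjectId subject identifier.
#' @param fwhm smoothing kernel FWHM in mm (default 6; 0 disables).
#' @param normalize divide by in-atlas mean (default TRUE).
#' @return A [ROISampleSet-class].
#' @export
processSubjectImage <- function(img, atlas, subjectId = "subject",
                                fwhm = 6, normalize = TRUE) {
  sm <- smoothGaussian(img, fwhm)
  gm <- NA_real_
  if (normalize) {
    nz <- normalizeGlobalMean(sm, atlas)
    sm <- nz$image
    gm <- nz$globalMean
  }
  extractROISamples(sm, atlas, subjectId = subjectId, globalMean = gm)
}

#' Write / read ROI samples as columnar text
#'
#' Serializes a [ROISampleSet-class] to a tab-separated table with columns
#' `subject_id`, `region_id`, `value` (one row per voxel), and reads it back.
#'
#' @param x a [ROISampleSet-class].
#' @param path file path.
#' @return `writeROISamples` returns `path` invisibly; `readROISamples`
#'   returns a [ROISampleSet-class].
#' @export
writeROISamples <- function(x, path) {
  stopifnot(is(x, "ROISampleSet"))
  n <- vapply(x@samples, length, 1L)
  df <- data.frame(subject_id = x@subjectId,
                   region_id = rep(names(x@samples), n),
                   value = unlist(x@samples, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeROISamples
#' @export
readROISamples <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  sid <- unique(df$subject_id)
  stopifnot(length(sid) == 1L)
  ids <- unique(as.character(df$region_id))
  samples <- split(df$value, factor(as.character(df$region_id), levels = ids))
  new("ROISampleSet", subjectId = as.character(sid), samples = samples,
      globalMean = NA_real_)
}
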