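#' Automatic kernel bandwidth
#'
#' Default rule is Silverman's rule of thumb
#' \eqn{h = 0.9 \min(\hat\sigma, IQR/1.34) n^{-1/5}} (as implemented by
#' [stats::bw.nrd0()]); `method = "SJ"` selects the Sheather-Jones
#' solve-the-equation bandwidth instead. A zero-variance sample falls back
#' to `max(1e-6, 1e-3 |v|)` so degenerate regions never abort network
#' construction.
#'
#' @param sample numeric vector, length >= 2.
#' @param method "nrd0" (Silverman, default) or "SJ" (Sheather-Jones).
#' @return Positive bandwidth on the data scale.
#' @export
klsBandwidth <- function(sample, method = c("nrd0", "SJ")) {
  method <- match.arg(method)
  if (length(sample) < 2L) stop("need at least 2 values for a bandwidth")
  if (stats::sd(sample) == 0)
    return(max(1e-6, 1e-3 * abs(sample[1])))
  h <- switch(method,
    nrd0 = stats::bw.nrd0(sample),
    SJ = tryCatch(stats::bw.SJ(sample), error = function(e) stats::bw.nrd0(sample)))
  max(h, 1e-12)
}

#' Discrete probability distribution from a voxel sample
#'
#' Gaussian kernel density estimation on a fixed, equally spaced grid,
#' converted to a discrete probability mass function: density values are
#' multiplied by the grid spacing, floored at `floorEps` (Kullback-Leibler
#' divergence is undefined at zero probabilities) and renormalized to sum 1.
#'
#' @param sample numeric vector of voxel values, length >= 2.
#' @param grid strictly increasing, equally spaced evaluation points that
#'   cover the sample range.
#' @param bw bandwidth; `NULL` (default) selects it with [klsBandwidth()].
#' @param bwMethod automatic bandwidth rule passed to [klsBandwidth()].
#' @param floorEps probability floor applied before renormalization.
#' @return List of class `DiscretePDF` with elements `grid`, `prob`, `bw`.
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' p <- estimatePDF(x, seq(-5, 5, length.out = 512))
#' sum(p$prob)  # 1
#' @export
estimatePDF <- function(sample, grid, bw = NULL, bwMethod = "nrd0",
                        floorEps = 1e-10) {
  if (length(sample) < 2L) stop("need at least 2 sample values")
  n <- length(grid)
  if (n < 2L || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing with >= 2 points")
  step <- diff(grid)
  if (max(abs(step - step[1])) > 1e-8 * abs(step[1]))
    stop("grid must be equally spaced")
  if (is.null(bw)) bw <- klsBandwidth(sample, bwMethod)
  d <- stats::density(sample, bw = bw, kernel = "gaussian",
                      from = grid[1], to = grid[n], n = n)
  prob <- pmax(d$y * step[1], floorEps)
  # renormalize over the un-floored entries only, so the floor is respected
  # exactly and the total stays 1 to floating-point accuracy
  free <- prob > floorEps
  if (any(free)) {
    prob[free] <- prob[free] * (1 - sum(prob[!free])) / sum(prob[free])
    prob <- pmax(prob, floorEps)
  } else prob <- prob / sum(prob)
  structure(list(grid = grid, prob = prob, bw = bw), class = "DiscretePDF")
}

checkSharedGrid <- function(p, q) {
  if (length(p$grid) != length(q$grid) ||
      max(abs(p$grid - q$grid)) > 1e-9)
    stop("distributions must share the same grid")
  if (any(p$prob <= 0) || any(q$prob <= 0))
    stop("probabilities must be strictly positive (flooring failed upstream)")
}

#' Symmetric Kullback-Leibler divergence
#'
#' \deqn{KL(P,Q) = \sum_i P(i)\,\ln\frac{P(i)}{Q(i)} +
#'                 Q(i)\,\ln\frac{Q(i)}{P(i)}}
#' computed in nats on a shared grid; non-negative and zero iff P = Q.
#'
#' @param p,q `DiscretePDF` objects on the same grid (see [estimatePDF()]).
#' @return Non-negative scalar divergence.
#' @export
symmetricKL <- function(p, q) {
  checkSharedGrid(p, q)
  # (P - Q) (ln P - ln Q) summed: algebraically KL(P||Q) + KL(Q||P), and
  # bitwise symmetric under swapping the arguments
  lr <- log(p$prob) - log(q$prob)
  sum((p$prob - q$prob) * lr)
}

#' Kullback-Leibler divergence based similarity (KLS)
#'
#' \deqn{KLS(P,Q) = e^{-KL(P,Q)}} with the symmetric divergence of
#' [symmetricKL()]; ranges over (0, 1], with 1 for identical distributions.
#' This is the connection intensity between two regions' intensity
#' distributions.
#'
#' @inheritParams symmetricKL
#' @return Similarity in (0, 1].
#' @export
kls <- function(p, q) exp(-symmetricKL(p, q))

#' Shared evaluation grid for a region pair
#'
#' 512 equally spaced points spanning the pooled sample range padded by 3
#' bandwidths on each side, so neither density is truncated at the support
#' boundary.
#'
#' @param s1,s2 the two samples.
#' @param h1,h2 their bandwidths.
#' @param nGrid number of grid points (default 512).
#' @return Numeric vector of grid points.
#' @export
sharedGrid <- function(s1, s2, h1, h2, nGrid = 512L) {
  h <- max(h1, h2)
  lo <- min(s1, s2) - 3 * h
  hi <- max(s1, s2) + 3 * h
  seq(lo, hi, length.out = nGrid)
}

#' Build the subject-level KLS connectivity matrix
#'
#' For every unordered region pair a shared grid is laid over the pooled
#' samples, both probability distributions are estimated by kernel density
#' estimation on that grid, and the edge weight is their KLS. The result is
#' a symmetric adjacency with zero diagonal.
#'
#' @param rois a [ROISampleSet-class] with >= 2 regions.
#' @param nGrid grid resolution per pair (default 512).
#' @param bwMethod automatic bandwidth rule, see [klsBandwidth()].
#' @param floorEps probability floor, see [estimatePDF()].
#' @return A [KLSNetwork-class].
#' @examples
#' cfg <- simulationConfig(nPatients = 1, nControls = 0, nRegions = 5,
#'                         voxelsPerRegion = 60, seed = 7)
#' roi <- simulateROISamples(cfg)$samples[[1]]
#' net <- buildNetwork(roi)
#' weights(net)[1:3, 1:3]
#' @export
buildNetwork <- function(rois, nGrid = 512L, bwMethod = "nrd0",
                         floorEps = 1e-10) {
  stopifnot(is(rois, "ROISampleSet"))
  ids <- names(rois@samples)
  R <- length(ids)
  if (R < 2L) stop("need at least 2 regions")
  bw <- vapply(rois@samples, klsBandwidth, 1.0, method = bwMethod)
  W <- matrix(0, R, R, dimnames = list(ids, ids))
  for (i in seq_len(R - 1L)) {
    si <- rois@samples[[i]]
    for (j in (i + 1L):R) {
      sj <- rois@samples[[j]]
      g <- sharedGrid(si, sj, bw[i], bw[j], nGrid)
      p <- estimatePDF(si, g, bw = bw[i], floorEps = floorEps)
      q <- estimatePDF(sj, g, bw = bw[j], floorEps = floorEps)
      W[i, j] <- W[j, i] <- kls(p, q)
    }
  }
  new("KLSNetwork", subjectId = rois@subjectId, weights = W)
}

#' Write / read a KLS connectivity matrix
#'
#' Square numeric matrix as tab-separated text with a header row of region
#' ids; by convention one file per subject named `<subject_id>.klsnet.tsv`.
#'
#' @param net a [KLSNetwork-class].
#' @param path file path.
#' @param subjectId subject id to attach on read (default: file name stem).
#' @return `writeKLSNetwork` returns `path` invisibly; `readKLSNetwork`
#'   returns a [KLSNetwork-class].
#' @export
writeKLSNetwork <- function(net, path) {
  stopifnot(is(net, "KLSNetwork"))
  w <- format(net@weights, digits = 17, trim = TRUE, scientific = TRUE)
  lines <- c(paste(colnames(net@weights), collapse = "\t"),
             apply(w, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeKLSNetwork
#' @export
readKLSNetwork <- function(path, subjectId = NULL) {
  if (is.null(subjectId))
    subjectId <- sub("\\.klsnet\\.tsv$", "", basename(path))
  m <- as.matrix(read.delim(path, check.names = FALSE))
  rownames(m) <- colnames(m)
  new("KLSNetwork", subjectId = subjectId, weights = m)
}
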