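# Shared fixture builders (all generated in code; nothing on disk).

# a DiscretePDF from explicit probabilities (bypasses KDE)
makePDF <- function(prob, grid = seq_along(prob)) {
  structure(list(grid = grid, prob = prob / sum(prob), bw = NA_real_),
            class = "DiscretePDF")
}

# tiny two-region atlas over a 3x2x1 volume: region 1 = 3 voxels,
# region 2 = 2 voxels, 1 background voxel
toyAtlas2 <- function() {
  lab <- array(c(1L, 1L, 1L, 2L, 2L, 0L), dim = c(3, 2, 1))
  labelAtlas(lab, data.frame(id = 1:2, name = c("a", "b"),
                             lobe = c("frontal", "temporal")))
}

toyVolume <- function(values = 1:6, dim = c(3, 2, 1), voxelSize = c(2, 2, 2)) {
  brainVolume(array(as.numeric(values), dim), voxelSize = voxelSize)
}

# impulse volume: zeros with a single 1 at `at`
impulseVolume <- function(dim = c(11, 11, 11), at = c(6, 6, 6),
                          voxelSize = c(2, 2, 2)) {
  a <- array(0, dim)
  a[at[1], at[2], at[3]] <- 1
  brainVolume(a, voxelSize = voxelSize)
}

# ROISampleSet straight from a named list of samples
makeROISet <- function(samples, subjectId = "S1") {
  new("ROISampleSet", subjectId = subjectId,
      samples = samples, globalMean = NA_real_)
}

# binary adjacency fixtures
ringGraph <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    W[i, j] <- W[j, i] <- 1
  }
  dimnames(W) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  W
}

completeGraph <- function(n) {
  W <- matrix(1, n, n) - diag(n)
  dimnames(W) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  W
}

# two triangles joined by a single bridge edge: unambiguous 2-community graph
twoTriangles <- function() {
  W <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  W[edges] <- 1
  W <- W + t(W)
  dimnames(W) <- list(as.character(1:6), as.character(1:6))
  W
}

# reference-scale coupled cohort + LOOCV result, computed once per run and
# shared by the structural and recovery acceptance checks
acceptanceCohortResult <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfgC <- simulationConfig(nPatients = 78, nControls = 60, nRegions = 90,
                             plantedEdges = data.frame(i = 1:19, j = 21:39,
                                                       d = 1.5),
                             beta = 8, noiseSd = 0, seed = 51)
    coh <- simulateConnectivityDirect(cfgC)
    feat <- connectivityFeatures(coh$networks)
    covar <- cbind(age = coh$cohort$age, sex = coh$cohort$sex)
    isP <- coh$cohort$group == "patient"
    res <- loocvPredict(feat[isP, ], covar[isP, ],
                        coh$cohort$overall_survival[isP],
                        feat[!isP, ], covar[!isP, ])
    cache <<- list(nEdges = ncol(feat), result = res)
    cache
  }
})

asTN <- function(W) {
  R <- nrow(W)
  new("ThresholdedNetwork", weights = W,
      sparsity = sum(W[upper.tri(W)] > 0) / (R * (R - 1) / 2),
      gammaThreshold = min(W[W > 0]))
}
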