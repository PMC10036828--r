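#' Simulation configuration for synthetic cohorts
#'
#' Defines a two-group study: `nPatients` and `nControls` subjects (defaults
#' 78 and 60, the reference cohort size), `nRegions` parcels (default 90),
#' per-region baseline intensity distributions, a set of planted edges whose
#' regional distributions differ between groups by `d` standard deviations,
#' and a patient outcome (overall survival in months) linearly coupled to
#' the planted connection strengths plus age/sex confounding and Gaussian
#' noise, truncated below at 1 month.
#'
#' @param nPatients,nControls group sizes (defaults 78 / 60).
#' @param nRegions number of atlas regions R (default 90).
#' @param voxelsPerRegion voxels per region for the voxel-level simulator
#'   (default 300, a realistic parcel size at 2 mm resolution).
#' @param baseMean,baseSd length-R (or scalar) per-region voxel intensity
#'   mean and sd; defaults: means spread over [0.8, 1.2] (global-mean
#'   normalized units), sd 0.1.
#' @param plantedEdges data.frame with columns `i`, `j`, `d` (region pair
#'   indices and effect size in sd units); the direct-matrix simulator also
#'   honours an optional `shift` column (raw similarity-scale group shift,
#'   overriding `d`). `NULL` for a null cohort.
#' @param beta outcome coefficients over the planted edges (recycled);
#'   default 0 (no outcome coupling).
#' @param noiseSd outcome noise sd in months (default 6).
#' @param survivalMean mean overall survival in months (default 16, matching
#'   an advanced-cancer cohort with median follow-up around 15 months).
#' @param ageRange,pFemale age uniform range (default 45-75) and female
#'   probability (default 0.35).
#' @param ageBeta,sexBeta confounding coefficients of age (per year) and
#'   sex on survival (defaults -0.1 and 1).
#' @param logitMean,logitSd direct-mode KLS edge distribution parameters on
#'   the logit scale (defaults qlogis(0.6) and 0.5).
#' @param seed master seed; all randomness derives from it.
#' @return List of class `simulationConfig`.
#' @export
simulationConfig <- function(nPatients = 78L, nControls = 60L,
                             nRegions = 90L, voxelsPerRegion = 300L,
                             baseMean = NULL, baseSd = 0.1,
                             plantedEdges = NULL, beta = 0,
                             noiseSd = 6, survivalMean = 16,
                             ageRange = c(45, 75), pFemale = 0.35,
                             ageBeta = -0.1, sexBeta = 1,
                             logitMean = stats::qlogis(0.6), logitSd = 0.5,
                             seed = 1L) {
  if (is.null(baseMean))
    baseMean <- seq(0.8, 1.2, length.out = nRegions)
  baseMean <- rep_len(baseMean, nRegions)
  baseSd <- rep_len(baseSd, nRegions)
  if (!is.null(plantedEdges)) {
    stopifnot(all(c("i", "j") %in% names(plantedEdges)),
              any(c("d", "shift") %in% names(plantedEdges)),
              all(plantedEdges$i >= 1), all(plantedEdges$j <= nRegions),
              all(plantedEdges$i != plantedEdges$j))
    if (is.null(plantedEdges$d)) plantedEdges$d <- 0
    stopifnot(all(is.finite(plantedEdges$d)))
  }
  structure(list(nPatients = as.integer(nPatients),
                 nControls = as.integer(nControls),
                 nRegions = as.integer(nRegions),
                 voxelsPerRegion = as.integer(voxelsPerRegion),
                 baseMean = baseMean, baseSd = baseSd,
                 plantedEdges = plantedEdges, beta = beta,
                 noiseSd = noiseSd, survivalMean = survivalMean,
                 ageRange = ageRange, pFemale = pFemale,
                 ageBeta = ageBeta, sexBeta = sexBeta,
                 logitMean = logitMean, logitSd = logitSd,
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

simulateDemographics <- function(cfg) {
  n <- cfg$nPatients + cfg$nControls
  data.frame(
    subject_id = c(sprintf("P%03d", seq_len(cfg$nPatients)),
                   sprintf("C%03d", seq_len(cfg$nControls))),
    group = c(rep("patient", cfg$nPatients), rep("control", cfg$nControls)),
    age = stats::runif(n, cfg$ageRange[1], cfg$ageRange[2]),
    sex = stats::rbinom(n, 1, cfg$pFemale))
}

survivalFromEdges <- function(cfg, edgeStrength, demog) {
  # linear coupling to planted-edge connection strengths + confounders
  pat <- demog$group == "patient"
  n <- sum(pat)
  base <- cfg$survivalMean +
    cfg$ageBeta * (demog$age[pat] - mean(cfg$ageRange)) +
    cfg$sexBeta * (demog$sex[pat] - cfg$pFemale)
  coupling <- if (is.null(cfg$plantedEdges) || all(cfg$beta == 0)) 0
  else {
    b <- rep_len(cfg$beta, nrow(cfg$plantedEdges))
    drop(edgeStrength %*% b)
  }
  pmax(1, base + coupling + stats::rnorm(n, 0, cfg$noiseSd))
}

#' Simulate voxel-level ROI samples for a cohort
#'
#' Every region of every subject receives voxel values drawn from a
#' Gaussian with that region's baseline mean and sd. For patients, each
#' planted edge `(i, j, d)` shifts region `j`'s mean by `d * sd_j`,
#' creating a between-group difference in the regional intensity
#' distribution that moves the KLS of edge (i, j) relative to controls.
#' Patient survival is `sum(beta_e * KLS_e)` over the planted edges plus
#' age/sex confounding and Gaussian noise, truncated at 1 month. The same
#' `(config, seed)` always regenerates an identical cohort.
#'
#' @param cfg a [simulationConfig()].
#' @return List of class `syntheticCohort`: `samples` (list of
#'   [ROISampleSet-class]), `cohort` (demographics + survival data.frame),
#'   `groundTruth` (planted edges and beta), `config`.
#' @export
simulateROISamples <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  set.seed(cfg$seed)
  demog <- simulateDemographics(cfg)
  n <- nrow(demog)
  ids <- as.character(seq_len(cfg$nRegions))
  shift <- rep(0, cfg$nRegions)
  if (!is.null(cfg$plantedEdges))
    for (r in seq_len(nrow(cfg$plantedEdges)))
      shift[cfg$plantedEdges$j[r]] <- shift[cfg$plantedEdges$j[r]] +
        cfg$plantedEdges$d[r] * cfg$baseSd[cfg$plantedEdges$j[r]]
  samples <- vector("list", n)
  edgeStrength <- if (!is.null(cfg$plantedEdges))
    matrix(0, cfg$nPatients, nrow(cfg$plantedEdges)) else NULL
  for (s in seq_len(n)) {
    pat <- demog$group[s] == "patient"
    mu <- cfg$baseMean + if (pat) shift else 0
    sam <- lapply(seq_len(cfg$nRegions), function(r)
      stats::rnorm(cfg$voxelsPerRegion, mu[r], cfg$baseSd[r]))
    names(sam) <- ids
    samples[[s]] <- new("ROISampleSet", subjectId = demog$subject_id[s],
                        samples = sam, globalMean = NA_real_)
    if (pat && !is.null(edgeStrength)) {
      for (r in seq_len(nrow(cfg$plantedEdges))) {
        i <- cfg$plantedEdges$i[r]; j <- cfg$plantedEdges$j[r]
        bwi <- klsBandwidth(sam[[i]]); bwj <- klsBandwidth(sam[[j]])
        g <- sharedGrid(sam[[i]], sam[[j]], bwi, bwj)
        edgeStrength[s, r] <- kls(estimatePDF(sam[[i]], g, bw = bwi),
                                  estimatePDF(sam[[j]], g, bw = bwj))
      }
    }
  }
  demog$overall_survival <- NA_real_
  demog$overall_survival[demog$group == "patient"] <-
    survivalFromEdges(cfg, edgeStrength, demog)
  structure(list(samples = samples, cohort = demog,
                 groundTruth = list(plantedEdges = cfg$plantedEdges,
                                    beta = cfg$beta),
                 config = cfg),
            class = "syntheticCohort")
}

logitNormalSd <- function(mu, sigma) {
  # moments of plogis(N(mu, sigma)) by numerical integration
  m1 <- stats::integrate(function(z) stats::plogis(mu + sigma * z) * stats::dnorm(z),
                         -Inf, Inf)$value
  m2 <- stats::integrate(function(z) stats::plogis(mu + sigma * z)^2 * stats::dnorm(z),
                         -Inf, Inf)$value
  sqrt(max(m2 - m1^2, 0))
}

#' Simulate KLS connectivity matrices directly
#'
#' Skips the voxel level: subject matrices get independent logit-normal
#' edge weights in (0, 1); on planted edges the patient group's mean is
#' shifted by `d` edge-level standard deviations (the sd of the logit-normal
#' edge distribution, computed by numerical integration), applied on the
#' similarity scale and clamped into (0, 1). Patient survival couples to
#' the planted edge weights exactly as in [simulateROISamples()].
#'
#' @param cfg a [simulationConfig()].
#' @return List of class `syntheticCohort`: `networks` (list of
#'   [KLSNetwork-class]), `cohort`, `groundTruth`, `config`.
#' @export
simulateConnectivityDirect <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  set.seed(cfg$seed)
  demog <- simulateDemographics(cfg)
  n <- nrow(demog)
  R <- cfg$nRegions
  ids <- as.character(seq_len(R))
  nEdge <- R * (R - 1) / 2
  sdEdge <- logitNormalSd(cfg$logitMean, cfg$logitSd)
  plantIdx <- NULL
  utIdx <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  if (!is.null(cfg$plantedEdges)) {
    key <- paste(pmin(utIdx[, 1], utIdx[, 2]), pmax(utIdx[, 1], utIdx[, 2]))
    want <- paste(pmin(cfg$plantedEdges$i, cfg$plantedEdges$j),
                  pmax(cfg$plantedEdges$i, cfg$plantedEdges$j))
    plantIdx <- match(want, key)
  }
  networks <- vector("list", n)
  edgeStrength <- if (!is.null(cfg$plantedEdges))
    matrix(0, cfg$nPatients, nrow(cfg$plantedEdges)) else NULL
  pRow <- 0L
  for (s in seq_len(n)) {
    w <- stats::plogis(stats::rnorm(nEdge, cfg$logitMean, cfg$logitSd))
    if (demog$group[s] == "patient" && !is.null(plantIdx)) {
      # `shift` column (if present) is a raw similarity-scale shift;
      # otherwise `d` is an effect size in edge-level sd units
      delta <- if (!is.null(cfg$plantedEdges$shift)) cfg$plantedEdges$shift
      else cfg$plantedEdges$d * sdEdge
      w[plantIdx] <- pmin(pmax(w[plantIdx] + delta, 1e-9), 1)
    }
    W <- matrix(0, R, R, dimnames = list(ids, ids))
    W[utIdx] <- w
    W[utIdx[, c(2, 1)]] <- w
    networks[[s]] <- new("KLSNetwork", subjectId = demog$subject_id[s],
                         weights = W)
    if (demog$group[s] == "patient" && !is.null(edgeStrength)) {
      pRow <- pRow + 1L
      edgeStrength[pRow, ] <- w[plantIdx]
    }
  }
  demog$overall_survival <- NA_real_
  demog$overall_survival[demog$group == "patient"] <-
    survivalFromEdges(cfg, edgeStrength, demog)
  structure(list(networks = networks, cohort = demog,
                 groundTruth = list(plantedEdges = cfg$plantedEdges,
                                    beta = cfg$beta),
                 config = cfg),
            class = "syntheticCohort")
}

#' Write a synthetic cohort to the pipeline's file formats
#'
#' Emits the same files the real pipeline reads: one `<subject>.klsnet.tsv`
#' per subject (direct mode) or ROI sample tables (voxel mode), a cohort
#' table `cohort.tsv` (subject_id, group, age, sex, overall_survival), and
#' `ground_truth.tsv` with the planted edges and coefficients.
#'
#' @param cohort a `syntheticCohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$networks))
    for (net in cohort$networks)
      writeKLSNetwork(net, file.path(dir, paste0(net@subjectId, ".klsnet.tsv")))
  if (!is.null(cohort$samples))
    for (ss in cohort$samples)
      writeROISamples(ss, file.path(dir, paste0(ss@subjectId, ".roi.tsv")))
  write.table(cohort$cohort, file.path(dir, "cohort.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort$groundTruth$plantedEdges
  if (is.null(gt)) gt <- data.frame(i = integer(), j = integer(), d = numeric())
  gt$beta <- rep_len(cohort$groundTruth$beta, nrow(gt))
  write.table(gt, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Build a synthetic block-parcellation atlas
#'
#' Partitions a cuboid volume into `nRegions` contiguous blocks (a synthetic
#' stand-in for an anatomical parcellation, useful for end-to-end tests),
#' with regions assigned round-robin to the six lobar groups.
#'
#' @param dim volume dimensions (default `c(12, 12, 10)`).
#' @param nRegions number of regions (default 90).
#' @return A [LabelAtlas-class].
#' @export
syntheticAtlas <- function(dim = c(12, 12, 10), nRegions = 90L) {
  nv <- prod(dim)
  if (nv < nRegions) stop("volume too small for the requested regions")
  lab <- array(as.integer(cut(seq_len(nv), nRegions, labels = FALSE)), dim)
  lobes <- c("frontal", "temporal", "parietal", "occipital",
             "central structures", "insula-and-cingulate")
  labelAtlas(lab, data.frame(
    id = seq_len(nRegions),
    name = sprintf("region_%02d", seq_len(nRegions)),
    lobe = rep_len(lobes, nRegions)))
}
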