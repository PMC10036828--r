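#' Read and validate a pipeline run configuration
#'
#' A single flat YAML file drives every pipeline stage, for
#' reproducibility: a `paths` block (image dir, atlas, lookup table, cohort
#' table, output dir), per-stage parameter blocks (`roi`, `network`,
#' `graph`, `stats`, `survival`) and a master `seed`. Missing blocks take
#' the package defaults. Referenced input paths must exist.
#'
#' @param path YAML file path.
#' @param checkPaths verify that referenced input paths exist (default TRUE).
#' @return Named list of class `runConfig`.
#' @export
readRunConfig <- function(path, checkPaths = TRUE) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    roi = list(fwhm = 6, normalize = TRUE),
    network = list(nGrid = 512L, bwMethod = "nrd0", floorEps = 1e-10),
    graph = list(sparsityMin = 0.02, sparsityMax = 0.50, sparsityStep = 0.01,
                 nRandomNetworks = 100L),
    stats = list(q = 0.05, welch = FALSE),
    survival = list(C = 1, epsilon = 0.1, alpha = 0.05, nPerm = 10000L,
                    permMode = "fast", selection = "per-fold"),
    seed = 1L)
  for (blk in names(defaults)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- defaults[[blk]]
    else if (is.list(defaults[[blk]]))
      for (k in names(defaults[[blk]]))
        if (is.null(cfg[[blk]][[k]])) cfg[[blk]][[k]] <- defaults[[blk]][[k]]
  }
  if (checkPaths && !is.null(cfg$paths)) {
    inputs <- cfg$paths[setdiff(names(cfg$paths), "outputDir")]
    missing <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing))
      stop("missing input paths: ", paste(missing, collapse = ", "))
  }
  class(cfg) <- "runConfig"
  cfg
}

configSeed <- function(cfg, offset = 0L) as.integer(cfg$seed) + as.integer(offset)

sparsityGrid <- function(cfg)
  seq(cfg$graph$sparsityMin, cfg$graph$sparsityMax, by = cfg$graph$sparsityStep)

#' Build per-subject KLS networks from images
#'
#' For every subject listed in the cohort table, reads the NIfTI image from
#' `paths$imageDir/<subject_id>.nii[.gz]`, runs smoothing, global-mean
#' normalization and ROI extraction against the atlas, builds the KLS
#' network and writes `<subject_id>.klsnet.tsv` to the output directory.
#' A missing subject image aborts with a per-subject report; previously
#' written subjects are left in place.
#'
#' @param cfg a `runConfig` (see [readRunConfig()]).
#' @return Character vector of written file paths, invisibly.
#' @export
runBuildNetworks <- function(cfg) {
  atlas <- readLabelAtlas(cfg$paths$atlas, cfg$paths$lookup)
  cohort <- read.delim(cfg$paths$cohort, stringsAsFactors = FALSE)
  dir.create(cfg$paths$outputDir, showWarnings = FALSE, recursive = TRUE)
  candidates <- function(sid)
    file.path(cfg$paths$imageDir, paste0(sid, c(".nii", ".nii.gz")))
  found <- vapply(cohort$subject_id,
                  function(sid) any(file.exists(candidates(sid))), TRUE)
  if (!all(found))
    stop("missing subject images: ",
         paste(cohort$subject_id[!found], collapse = ", "))
  out <- character(nrow(cohort))
  for (s in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[s]
    img <- readBrainVolume(candidates(sid)[file.exists(candidates(sid))][1])
    rois <- processSubjectImage(img, atlas, subjectId = sid,
                                fwhm = cfg$roi$fwhm,
                                normalize = cfg$roi$normalize)
    net <- buildNetwork(rois, nGrid = cfg$network$nGrid,
                        bwMethod = cfg$network$bwMethod,
                        floorEps = cfg$network$floorEps)
    out[s] <- file.path(cfg$paths$outputDir, paste0(sid, ".klsnet.tsv"))
    writeKLSNetwork(net, out[s])
  }
  invisible(out)
}

loadCohortNetworks <- function(cfg) {
  cohort <- read.delim(cfg$paths$cohort, stringsAsFactors = FALSE)
  nets <- lapply(cohort$subject_id, function(sid)
    readKLSNetwork(file.path(cfg$paths$networkDir %||% cfg$paths$outputDir,
                             paste0(sid, ".klsnet.tsv")), subjectId = sid))
  list(cohort = cohort, networks = nets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare groups on metrics and connections
#'
#' Runs the sparsity sweep and AUC summaries on every subject network, then
#' the covariate-adjusted two-sample comparisons: global metric AUCs, nodal
#' metric AUCs and edgewise connections, each family FDR-corrected
#' separately. Writes tidy tab-separated tables to the output directory.
#'
#' @param cfg a `runConfig`.
#' @return List with `global`, `nodalDc`, `nodalBc`, `edges` comparison
#'   data.frames (also written to `outputDir`).
#' @export
runCompareGroups <- function(cfg) {
  dat <- loadCohortNetworks(cfg)
  sw <- sparsityGrid(cfg)
  curves <- lapply(dat$networks, metricCurves, sparsities = sw,
                   nRand = cfg$graph$nRandomNetworks, seed = configSeed(cfg))
  covar <- cbind(age = dat$cohort$age, sex = dat$cohort$sex)
  gAuc <- t(vapply(curves, `[[`, curves[[1]]$auc, "auc"))
  dcAuc <- t(vapply(curves, function(cu) cu$nodalAuc$Dc, curves[[1]]$nodalAuc$Dc))
  bcAuc <- t(vapply(curves, function(cu) cu$nodalAuc$Bc, curves[[1]]$nodalAuc$Bc))
  colnames(dcAuc) <- colnames(bcAuc) <- regionIds(dat$networks[[1]])
  feat <- connectivityFeatures(dat$networks)
  # metrics undefined at some thresholds (e.g. hierarchy on triangle-free
  # sparse graphs) propagate NA into their AUC; such features are excluded
  # from the comparison family
  keepFinite <- function(m) m[, colSums(!is.finite(m)) == 0, drop = FALSE]
  gAuc <- keepFinite(gAuc)
  out <- list(
    global = edgewiseComparison(gAuc, dat$cohort$group, covar, q = cfg$stats$q),
    nodalDc = edgewiseComparison(dcAuc, dat$cohort$group, covar, q = cfg$stats$q),
    nodalBc = edgewiseComparison(bcAuc, dat$cohort$group, covar, q = cfg$stats$q),
    edges = edgewiseComparison(feat, dat$cohort$group, covar, q = cfg$stats$q))
  dir.create(cfg$paths$outputDir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(out))
    write.table(out[[nm]],
                file.path(cfg$paths$outputDir, paste0("compare_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Predict patient survival from significant connections
#'
#' Runs the leave-one-out SVR pipeline on the patients (controls enter only
#' the per-fold feature selection), the permutation test of the
#' observed-vs-predicted correlation, and the lobar aggregation of the
#' averaged connection weights. Writes predictions, per-edge mean weights,
#' per-lobe weights and a permutation summary.
#'
#' @param cfg a `runConfig`; `paths$lookup` supplies the lobe mapping.
#' @return List with the `predictionResult`, permutation summary and lobe
#'   weights.
#' @export
runPredictSurvival <- function(cfg) {
  dat <- loadCohortNetworks(cfg)
  feat <- connectivityFeatures(dat$networks)
  isPat <- dat$cohort$group == "patient"
  covar <- cbind(age = dat$cohort$age, sex = dat$cohort$sex)
  res <- loocvPredict(feat[isPat, , drop = FALSE],
                      covar[isPat, , drop = FALSE],
                      dat$cohort$overall_survival[isPat],
                      feat[!isPat, , drop = FALSE],
                      covar[!isPat, , drop = FALSE],
                      alpha = cfg$survival$alpha, C = cfg$survival$C,
                      eps = cfg$survival$epsilon,
                      selection = cfg$survival$selection)
  perm <- permutationTest(res, nPerm = cfg$survival$nPerm,
                          seed = configSeed(cfg, 7L),
                          mode = cfg$survival$permMode)
  lut <- read.delim(cfg$paths$lookup, stringsAsFactors = FALSE)
  lobeW <- summarizeWeights(res$meanWeights,
                            stats::setNames(lut$lobe, as.character(lut$id)))
  dir.create(cfg$paths$outputDir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(subject_id = dat$cohort$subject_id[isPat],
                         observed = res$observed, predicted = res$predicted),
              file.path(cfg$paths$outputDir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(edge = names(res$meanWeights),
                         mean_weight = res$meanWeights),
              file.path(cfg$paths$outputDir, "edge_weights.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(lobe = names(lobeW), weight = lobeW),
              file.path(cfg$paths$outputDir, "lobe_weights.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("pearson_r\t%.6f", res$pearsonR),
               sprintf("permutation_p\t%.6g", perm$p),
               sprintf("n_permutations\t%d", as.integer(cfg$survival$nPerm)),
               sprintf("seed\t%d", configSeed(cfg))),
             file.path(cfg$paths$outputDir, "permutation_summary.tsv"))
  list(result = res, permutation = perm, lobeWeights = lobeW)
}
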