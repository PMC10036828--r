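test_that("the SVR recovers an exact linear relation in the least-squares limit", {
  set.seed(1)
  x <- rnorm(60)
  fit <- trainSVR(matrix(x), 3.5 * x, C = 1e4, eps = 0)
  expect_lt(abs(fit$w - 3.5) / 3.5, 0.01)   # within 1% of the true slope

  # constant-zero outcome: the regularizer keeps the origin optimal
  f0 <- trainSVR(matrix(x), rep(0, 60), C = 1, eps = 0.1)
  expect_equal(unname(f0$w), 0)
})

test_that("the returned SVR weights are a local (hence global) optimum", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40)
  y <- drop(X %*% c(1, -0.5, 2)) + rnorm(40, sd = 0.3)
  C <- 1; eps <- 0.1
  fit <- trainSVR(X, y, C = C, eps = eps)
  obj <- function(w) {
    r <- y - drop(X %*% w)
    0.5 * sum(w^2) + C * sum(pmax(0, abs(r) - eps)^2)
  }
  fobj <- obj(fit$w)
  expect_lte(fobj, obj(rep(0, 3)))
  for (k in 1:50) {
    expect_lte(fobj, obj(fit$w + rnorm(3, sd = 0.05)) + 1e-10)
  }
  expect_error(trainSVR(X, c(y[-1], NA)), "non-finite")
})

test_that("LOOCV produces one prediction per patient and recovers noiseless coupling", {
  cfg <- simulationConfig(nPatients = 40, nControls = 30, nRegions = 12,
                          plantedEdges = data.frame(i = 1:4, j = 7:10, d = 2),
                          beta = 10, noiseSd = 0, ageBeta = 0, sexBeta = 0,
                          seed = 17)
  coh <- simulateConnectivityDirect(cfg)
  feat <- connectivityFeatures(coh$networks)
  covar <- cbind(age = coh$cohort$age, sex = coh$cohort$sex)
  isP <- coh$cohort$group == "patient"
  res <- loocvPredict(feat[isP, ], covar[isP, ],
                      coh$cohort$overall_survival[isP],
                      feat[!isP, ], covar[!isP, ])
  expect_length(res$predicted, 40L)
  expect_length(res$observed, 40L)
  expect_gte(res$pearsonR, 0.95)
  expect_true(all(res$nSelected >= 4))
  expect_error(loocvPredict(feat[isP, ][1:2, ], covar[isP, ][1:2, ],
                            c(3, 4), feat[!isP, ], covar[!isP, ]),
               "at least 3")
})

test_that("no information leaks from the held-out patient into their fold", {
  cfg <- simulationConfig(nPatients = 20, nControls = 15, nRegions = 8,
                          plantedEdges = data.frame(i = 1:2, j = 5:6, d = 2),
                          beta = 10, noiseSd = 2, seed = 23)
  coh <- simulateConnectivityDirect(cfg)
  feat <- connectivityFeatures(coh$networks)
  covar <- cbind(age = coh$cohort$age, sex = coh$cohort$sex)
  isP <- coh$cohort$group == "patient"
  y <- coh$cohort$overall_survival[isP]
  res1 <- loocvPredict(feat[isP, ], covar[isP, ], y,
                       feat[!isP, ], covar[!isP, ])
  # perturbing patient 5's outcome must leave fold 5's trained weights and
  # prediction untouched (their fold never sees that outcome)
  y2 <- y
  y2[5] <- y2[5] + 100
  res2 <- loocvPredict(feat[isP, ], covar[isP, ], y2,
                       feat[!isP, ], covar[!isP, ])
  expect_identical(res1$foldWeights[5, ], res2$foldWeights[5, ])
  expect_identical(res1$predicted[5], res2$predicted[5])
})

test_that("LOOCV correlation tracks the planted signal-to-noise level", {
  # population r designed at 0.5: noise sd = sqrt(3) x signal sd; the
  # cross-validated estimate is attenuated but stays in the pinned interval
  sdE <- 0.1142911   # edge-level sd of the logit-normal weights
  b <- 30
  noise <- b * sdE * sqrt(5) * sqrt(3)
  rs <- vapply(1:20, function(s) {
    cfg <- simulationConfig(nPatients = 60, nControls = 40, nRegions = 10,
                            plantedEdges = data.frame(i = 1:5, j = 6:10, d = 1.5),
                            beta = b, noiseSd = noise, ageBeta = 0,
                            sexBeta = 0, seed = 1000 + s)
    coh <- simulateConnectivityDirect(cfg)
    feat <- connectivityFeatures(coh$networks)
    covar <- cbind(age = coh$cohort$age, sex = coh$cohort$sex)
    isP <- coh$cohort$group == "patient"
    loocvPredict(feat[isP, ], covar[isP, ],
                 coh$cohort$overall_survival[isP],
                 feat[!isP, ], covar[!isP, ])$pearsonR
  }, 1.0)
  expect_gte(mean(rs), 0.3)
  expect_lte(mean(rs), 0.6)
})

test_that("permutation p follows the add-one convention at both extremes", {
  # observed correlation no permutation can reach
  res <- list(predicted = sin(1:20), observed = sin(1:20),
              rawObserved = sin(1:20), pearsonR = 1)
  p <- permutationTest(res, nPerm = 9999, seed = 7)
  expect_equal(p$p, (1 + sum(p$rPerm >= 1)) / 10000)
  expect_lte(p$p, 3 / 10000)

  # observed correlation below every permutation
  res2 <- res
  res2$pearsonR <- -2   # sentinel below any achievable correlation
  p2 <- permutationTest(res2, nPerm = 99, seed = 8)
  expect_equal(p2$p, 1)

  # a strongly coupled cohort is called significant
  cfg <- simulationConfig(nPatients = 30, nControls = 20, nRegions = 8,
                          plantedEdges = data.frame(i = 1:3, j = 5:7, d = 2),
                          beta = 12, noiseSd = 1, seed = 41)
  coh <- simulateConnectivityDirect(cfg)
  feat <- connectivityFeatures(coh$networks)
  covar <- cbind(age = coh$cohort$age, sex = coh$cohort$sex)
  isP <- coh$cohort$group == "patient"
  res3 <- loocvPredict(feat[isP, ], covar[isP, ],
                       coh$cohort$overall_survival[isP],
                       feat[!isP, ], covar[!isP, ])
  expect_lte(permutationTest(res3, nPerm = 999, seed = 9)$p, 0.01)
})

test_that("full-mode permutation reruns the cross-validation per shuffle", {
  cfg <- simulationConfig(nPatients = 12, nControls = 8, nRegions = 4,
                          beta = 0, noiseSd = 6, ageBeta = 0, sexBeta = 0,
                          seed = 61)
  coh <- simulateConnectivityDirect(cfg)
  feat <- connectivityFeatures(coh$networks)
  covar <- cbind(age = coh$cohort$age, sex = coh$cohort$sex)
  isP <- coh$cohort$group == "patient"
  Xp <- feat[isP, ]; Zp <- covar[isP, ]
  Xc <- feat[!isP, ]; Zc <- covar[!isP, ]
  y <- coh$cohort$overall_survival[isP]
  res <- suppressWarnings(
    loocvPredict(Xp, Zp, y, Xc, Zc, alpha = 0.5, useFDR = FALSE,
                 selection = "fixed"))
  refit <- function(yp) suppressWarnings(
    loocvPredict(Xp, Zp, yp, Xc, Zc, alpha = 0.5, useFDR = FALSE,
                 selection = "fixed"))$pearsonR
  p <- permutationTest(res, nPerm = 19, seed = 3, mode = "full", refit = refit)
  expect_true(p$p > 0 && p$p <= 1)
  expect_length(p$rPerm, 19L)
  expect_error(permutationTest(res, nPerm = 5, mode = "full"), "refit")
})

test_that("lobar weight aggregation sums absolute weights over touching lobes", {
  lobeMap <- c("1" = "temporal", "2" = "temporal", "3" = "temporal",
               "4" = "temporal", "5" = "frontal", "6" = "occipital")
  w <- c("1_2" = -13.70, "3_4" = 15.04, "5_6" = 0)
  lw <- summarizeWeights(w, lobeMap)
  expect_equal(unname(lw["temporal"]), 28.74)
  expect_equal(unname(lw["frontal"]), 0)

  # a cross-lobe edge counts toward both endpoint lobes
  w2 <- c("1_5" = -2)
  lw2 <- summarizeWeights(w2, lobeMap)
  expect_equal(unname(lw2["temporal"]), 2)
  expect_equal(unname(lw2["frontal"]), 2)

  expect_equal(unname(summarizeWeights(c("1_2" = 0), lobeMap)),
               rep(0, 3))
  expect_error(summarizeWeights(c("1_9" = 1), lobeMap), "no lobe mapping")
})
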