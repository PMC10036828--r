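test_that("sparsity thresholding keeps exactly the strongest edges", {
  set.seed(2)
  W <- randomWeightedGraph(4, p = 1, seed = 2)   # complete weighted K4
  tn <- applySparsityThreshold(W, 0.5)
  expect_equal(sum(weights(tn)[upper.tri(weights(tn))] > 0), 3L)
  kept <- sort(weights(tn)[upper.tri(weights(tn))], decreasing = TRUE)[1:3]
  expect_equal(kept, sort(W[upper.tri(W)], decreasing = TRUE)[1:3])

  # explicit strengths: S = 1/3 of 6 edges keeps the top two
  W6 <- matrix(0, 4, 4)
  W6[upper.tri(W6)] <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  W6 <- W6 + t(W6)
  dimnames(W6) <- list(1:4, 1:4)
  tn6 <- applySparsityThreshold(W6, 1 / 3)
  expect_setequal(weights(tn6)[upper.tri(weights(tn6))][weights(tn6)[upper.tri(weights(tn6))] > 0],
                  c(0.9, 0.8))
  expect_equal(gammaThreshold(tn6), 0.8)

  # S = 1 is the identity off the diagonal
  tn1 <- applySparsityThreshold(W, 1)
  expect_equal(weights(tn1), abs(W))
  expect_error(applySparsityThreshold(W, 0.01), "zero edges")
  expect_error(applySparsityThreshold(W, 1.2), "in \\(0, 1]")
})

test_that("threshold tie-breaking is deterministic and the edge count is as requested", {
  W <- matrix(0.5, 6, 6); diag(W) <- 0
  dimnames(W) <- list(1:6, 1:6)
  a <- applySparsityThreshold(W, 0.4)
  b <- applySparsityThreshold(W, 0.4)
  expect_identical(weights(a), weights(b))
  expect_equal(sum(weights(a)[upper.tri(weights(a))] > 0), round(0.4 * 15))
})

test_that("complete and ring graphs give their closed-form global metrics", {
  k4 <- computeGlobalMetrics(asTN(completeGraph(4)), nRand = 0)
  expect_equal(k4$Cp, 1)
  expect_equal(k4$Lp, 1)
  expect_equal(k4$Eglobal, 1)

  ring <- computeGlobalMetrics(asTN(ringGraph(10)), nRand = 0)
  expect_equal(ring$Lp, 25 / 9, tolerance = 1e-9)  # exhaustive BFS pattern
  expect_equal(ring$Lp, bruteLp(ringGraph(10)), tolerance = 1e-9)
})

test_that("all global metrics match brute-force oracles on small weighted fixtures", {
  for (seed in c(1, 2, 3)) {
    W <- randomWeightedGraph(8, p = 0.7, seed = seed)
    m <- computeGlobalMetrics(asTN(W), nRand = 0)
    expect_equal(m$Lp, bruteLp(W), tolerance = 1e-9)
    expect_equal(m$Eglobal, bruteEglobal(W), tolerance = 1e-9)
    expect_equal(m$Cp, mean(bruteOnnela(W)), tolerance = 1e-9)
    expect_equal(m$Elocal, bruteElocal(W), tolerance = 1e-9)
    expect_equal(m$Ar, bruteAssortativity(W), tolerance = 1e-9)
    expect_equal(m$Hr, bruteHierarchy(W), tolerance = 1e-9)
    expect_equal(m$Sr, bruteSynchronization(W), tolerance = 1e-9)
  }
})

test_that("greedy modularity attains the exhaustive optimum on a clear 2-community graph", {
  W <- twoTriangles()
  m <- computeGlobalMetrics(asTN(W), nRand = 0)
  expect_equal(m$Q, bruteBestModularity(W), tolerance = 1e-9)
})

test_that("normalized metrics satisfy their definitional identities", {
  W <- randomWeightedGraph(12, p = 0.4, seed = 9)
  m <- computeGlobalMetrics(asTN(W), nRand = 10, seed = 42)
  expect_equal(m$gamma, m$Cp / mean(m$null["Cp", ]), tolerance = 1e-9)
  expect_equal(m$lambda, m$Lp / mean(m$null["Lp", ]), tolerance = 1e-9)
  expect_equal(m$sigma, m$gamma / m$lambda, tolerance = 1e-9)
})

test_that("z-scored summaries are (metric - null mean) / null sd", {
  W <- randomWeightedGraph(10, p = 0.5, seed = 3)
  m <- computeGlobalMetrics(asTN(W), nRand = 8, seed = 11, zscore = TRUE)
  expect_equal(unname(m$z["Sr"]),
               (m$Sr - mean(m$null["Sr", ])) / sd(m$null["Sr", ]),
               tolerance = 1e-9)
})

test_that("nodal metrics have their closed forms on stars and paths", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  dimnames(star) <- list(1:5, 1:5)
  nm <- computeNodalMetrics(asTN(star))
  expect_equal(nm$Bc, c(6, 0, 0, 0, 0))       # C(4,2) pairs through the hub
  expect_equal(unname(nm$Dc), c(4, 1, 1, 1, 1))

  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  dimnames(path) <- list(1:3, 1:3)
  nmp <- computeNodalMetrics(asTN(path))
  expect_equal(unname(nmp$Dc), c(1, 2, 1))
  expect_equal(nmp$Bc, c(0, 1, 0))
})

test_that("weighted betweenness and strength match exhaustive enumeration", {
  for (seed in c(4, 7)) {
    W <- randomWeightedGraph(8, p = 0.5, seed = seed)
    nm <- computeNodalMetrics(asTN(W))
    expect_equal(nm$Bc, bruteBetweenness(W), tolerance = 1e-9)
    expect_equal(unname(nm$Dc), rowSums(W), ignore_attr = TRUE)
    expect_equal(sum(nm$Dc), 2 * sum(W[upper.tri(W)]), tolerance = 1e-12)
  }
})

test_that("rewired nulls preserve the binary degree sequence and edge count", {
  W <- randomWeightedGraph(12, p = 0.35, seed = 6)
  for (s in 1:5) {
    Wb <- randomRewire(W, seed = s)
    expect_equal(sort(rowSums(Wb > 0)), sort(rowSums(W > 0)))
    expect_equal(sum(Wb > 0), sum(W > 0))
    expect_equal(sort(Wb[upper.tri(Wb) & Wb > 0]),
                 sort(W[upper.tri(W) & W > 0]))   # weights are a permutation
    expect_lt(max(abs(Wb - t(Wb))), 1e-12)
  }
})

test_that("rewiring destroys lattice clustering", {
  # ring with chords to next-nearest neighbours: positive lattice clustering
  n <- 12
  W <- ringGraph(n)
  for (i in seq_len(n)) {
    j <- (i + 1) %% n + 1
    W[i, j] <- W[j, i] <- 1
  }
  cp0 <- mean(onnelaClustering(W))
  expect_gt(cp0, 0)
  cps <- vapply(1:200, function(s) mean(onnelaClustering(randomRewire(W, seed = s))), 1.0)
  expect_lt(mean(cps), cp0)
})

test_that("degree-matched nulls on random graphs give gamma and lambda near 1", {
  W <- randomWeightedGraph(30, p = 0.3, seed = 15)   # ER-like topology
  m <- computeGlobalMetrics(asTN(W), nRand = 100, seed = 5)
  expect_lt(abs(m$gamma - 1), 0.15)
  expect_lt(abs(m$lambda - 1), 0.15)
})

test_that("global efficiency never decreases as the network densifies", {
  w <- randomWeightedGraph(15, p = 1, seed = 8)
  eg <- vapply(seq(0.1, 1, by = 0.1), function(S)
    computeGlobalMetrics(applySparsityThreshold(w, S), nRand = 0)$Eglobal, 1.0)
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("the AUC summary is the mean-height trapezoid integral", {
  s <- seq(0.02, 0.50, by = 0.01)
  expect_equal(aucOverThresholds(rep(1, length(s)), s), 1)
  lin <- seq(0, 1, length.out = length(s))
  expect_equal(aucOverThresholds(lin, s), 0.5, tolerance = 1e-9)
  set.seed(10)
  v <- runif(length(s))
  expect_equal(aucOverThresholds(v, s),
               pracma::trapz(s, v) / (max(s) - min(s)), tolerance = 1e-9)
  expect_error(aucOverThresholds(1:3, 1:4), "length")
})

test_that("the sparsity sweep returns aligned curves and recomputable AUCs", {
  set.seed(30)
  sams <- setNames(lapply(1:8, function(i) rnorm(40, 1 + 0.05 * i, 0.1)), 1:8)
  net <- buildNetwork(makeROISet(sams))
  sw <- seq(0.1, 0.5, by = 0.1)
  mc <- metricCurves(net, sparsities = sw, nRand = 5, seed = 2)
  expect_equal(dim(mc$global), c(11L, length(sw)))
  expect_equal(mc$auc[["Eglobal"]],
               aucOverThresholds(mc$global["Eglobal", ], sw), tolerance = 1e-12)
  expect_equal(dim(mc$nodal$Dc), c(8L, length(sw)))
  expect_equal(mc$nodalAuc$Bc[["3"]],
               aucOverThresholds(mc$nodal$Bc["3", ], sw), tolerance = 1e-12)
})
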