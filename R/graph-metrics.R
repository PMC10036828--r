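#' Sparsity thresholding of a connectivity matrix
#'
#' Converts a dense KLS matrix into a weighted network by keeping the
#' `round(S * R(R-1)/2)` strongest off-diagonal connections (by absolute
#' strength) and zeroing the rest; surviving edges keep their weights.
#' Ties at the cutoff are broken deterministically by (strength descending,
#' row index, column index) so the retained edge set is reproducible.
#'
#' @param net a [KLSNetwork-class] (or plain symmetric matrix).
#' @param S target sparsity: fraction of possible edges retained, in (0, 1].
#' @return A [ThresholdedNetwork-class].
#' @export
applySparsityThreshold <- function(net, S) {
  w <- if (is(net, "KLSNetwork")) net@weights else net
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (S <= 0 || S > 1) stop("sparsity S must lie in (0, 1]")
  R <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  strength <- abs(w[ut])
  k <- round(S * R * (R - 1) / 2)
  if (k < 1) stop("sparsity S = ", S, " retains zero edges")
  ord <- order(-strength, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- matrix(0, R, R, dimnames = dimnames(w))
  ij <- ut[keep, , drop = FALSE]
  out[ij] <- abs(w[ij])
  out[ij[, c(2, 1), drop = FALSE]] <- abs(w[ij])
  new("ThresholdedNetwork", weights = out,
      sparsity = length(keep) / (R * (R - 1) / 2),
      gammaThreshold = min(strength[keep]))
}

asIgraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Onnela weighted clustering coefficient
#'
#' Per-node geometric-mean triangle intensity on weights rescaled by the
#' network maximum: \eqn{C_i = \frac{1}{k_i(k_i-1)}
#' \sum_{j,k}(\hat w_{ij}\hat w_{jk}\hat w_{ki})^{1/3}} with binary degree
#' \eqn{k_i}; nodes with \eqn{k_i < 2} have \eqn{C_i = 0}.
#'
#' @param W symmetric non-negative weight matrix, zero diagonal.
#' @return Numeric vector of nodal clustering coefficients in [0, 1].
#' @export
onnelaClustering <- function(W) {
  mx <- max(W)
  if (mx == 0) return(rep(0, nrow(W)))
  Wh <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  num <- diag(Wh %*% Wh %*% Wh)
  ifelse(k >= 2, num / (k * (k - 1)), 0)
}

nodalEfficiency <- function(W) {
  # mean inverse shortest-path length from each node (edge length = 1/w)
  if (nrow(W) < 2) return(0)
  D <- distanceMatrix(W)
  invD <- 1 / D
  diag(invD) <- NA
  mean(invD[!is.na(invD)])
}

distanceMatrix <- function(W) {
  g <- asIgraph(W)
  ew <- igraph::E(g)$weight
  igraph::distances(g, weights = if (length(ew)) 1 / ew else NULL)
}

#' Global weighted-network metrics
#'
#' Computes the full global metric panel on a thresholded weighted network:
#' assortativity `Ar`, modularity `Q`, hierarchy `Hr`, global and local
#' efficiency `Eglobal`/`Elocal`, clustering `Cp`, characteristic path
#' length `Lp`, synchronization `Sr`, and -- against `nRand`
#' degree-preserving rewired null networks -- the normalized quantities
#' `lambda = Lp/Lp_rand`, `gamma = Cp/Cp_rand` and small-worldness
#' `sigma = gamma/lambda`.
#'
#' Conventions: `Cp` is the mean Onnela weighted clustering; path lengths
#' use edge length `1/w` and `Lp` averages over connected (finite) pairs
#' only, since very sparse thresholds fragment the graph; `Eglobal` is the
#' mean of `1/d` over all pairs (disconnected pairs contribute 0); `Elocal`
#' averages the efficiency of each node's neighbour subgraph; `Q` is the
#' modularity of the partition found by greedy modularity optimization on
#' the weighted graph; `Ar` is the Pearson correlation of endpoint strengths
#' over edges; `Hr` is the exponent `beta` of the power-law regression
#' `log C_i ~ -beta log k_i` over nodes with `k > 1` and `C_i > 0`; `Sr` is
#' the Laplacian eigenratio `lambda_2 / lambda_max` of the binarized graph.
#'
#' @param net a [ThresholdedNetwork-class] (or non-negative symmetric matrix).
#' @param nRand number of degree-preserving random nulls for the normalized
#'   metrics (default 100). `0` skips nulls (`lambda`, `gamma`, `sigma` NA).
#' @param seed master seed for null generation; per-null seeds are derived
#'   by fixed offsets.
#' @param zscore additionally return `(metric - mean_null) / sd_null` for
#'   all metrics that have a null distribution.
#' @return Named list with the 11 global metrics, plus `null` (per-null
#'   `Cp`/`Lp` draws) and, if requested, `z` (z-scored metrics).
#' @export
computeGlobalMetrics <- function(net, nRand = 100L, seed = 1L,
                                 zscore = FALSE) {
  W <- if (is(net, "ThresholdedNetwork")) net@weights else net
  if (all(W == 0)) stop("empty network")
  m <- rawGlobalMetrics(W)
  nulls <- NULL
  if (nRand >= 1L) {
    nulls <- vapply(seq_len(nRand), function(b) {
      Wb <- rewireWeights(W, seed = seed + 1000L * b)
      if (zscore) unlist(rawGlobalMetrics(Wb))
      else c(Cp = mean(onnelaClustering(Wb)), Lp = finiteMeanPath(Wb))
    }, numeric(if (zscore) 8L else 2L))
    cpR <- mean(nulls["Cp", ])
    lpR <- mean(nulls["Lp", ])
    m$gamma <- m$Cp / cpR
    m$lambda <- m$Lp / lpR
    m$sigma <- m$gamma / m$lambda
  } else {
    m$gamma <- m$lambda <- m$sigma <- NA_real_
  }
  m$null <- nulls
  if (zscore && !is.null(nulls)) {
    base <- unlist(rawGlobalMetrics(W))
    mu <- rowMeans(nulls[names(base), , drop = FALSE])
    sdv <- apply(nulls[names(base), , drop = FALSE], 1, stats::sd)
    m$z <- (base - mu) / sdv
  }
  m
}

finiteMeanPath <- function(W) {
  D <- distanceMatrix(W)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

rawGlobalMetrics <- function(W) {
  g <- asIgraph(W)
  ew <- igraph::E(g)$weight
  D <- igraph::distances(g, weights = if (length(ew)) 1 / ew else NULL)
  du <- D[upper.tri(D)]
  Lp <- mean(du[is.finite(du)])
  Eglobal <- mean(ifelse(is.finite(du), 1 / du, 0))
  cpNodes <- onnelaClustering(W)
  Cp <- mean(cpNodes)
  Elocal <- mean(vapply(seq_len(nrow(W)), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    nodalEfficiency(W[nb, nb, drop = FALSE])
  }, 1.0))
  comm <- igraph::cluster_fast_greedy(g, weights = ew)
  Q <- igraph::modularity(g, igraph::membership(comm), weights = ew)
  s <- rowSums(W)
  eids <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  Ar <- if (nrow(eids) >= 2) {
    x <- c(s[eids[, 1]], s[eids[, 2]])
    y <- c(s[eids[, 2]], s[eids[, 1]])
    if (stats::sd(x) == 0) 0 else stats::cor(x, y)
  } else NA_real_
  k <- rowSums(W > 0)
  ok <- k > 1 & cpNodes > 0
  Hr <- if (sum(ok) >= 2 && stats::sd(log(k[ok])) > 0) {
    -unname(stats::lm.fit(cbind(1, log(k[ok])), log(cpNodes[ok]))$coefficients[2])
  } else NA_real_
  A <- (W > 0) + 0
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  Sr <- if (ev[length(ev)] > 1e-12) ev[2] / ev[length(ev)] else NA_real_
  list(Ar = Ar, Q = Q, Hr = Hr, Eglobal = Eglobal, Elocal = Elocal,
       Cp = Cp, Lp = Lp, Sr = Sr)
}

#' Nodal degree and betweenness
#'
#' Nodal degree `Dc` is the weighted degree (strength, row sum of weights);
#' nodal betweenness `Bc` is weighted betweenness centrality with edge
#' length `1/w`, so strong connections are short.
#'
#' @param net a [ThresholdedNetwork-class] (or non-negative symmetric matrix).
#' @return List with numeric vectors `Dc` and `Bc` (named by region).
#' @export
computeNodalMetrics <- function(net) {
  W <- if (is(net, "ThresholdedNetwork")) net@weights else net
  if (nrow(W) < 2) stop("need at least 2 nodes")
  g <- asIgraph(W)
  ew <- igraph::E(g)$weight
  Bc <- igraph::betweenness(g, weights = if (length(ew)) 1 / ew else NULL)
  list(Dc = rowSums(W), Bc = as.numeric(Bc))
}

#' Degree-preserving random rewiring
#'
#' Generates a matched null network by repeated double-edge swaps (at least
#' 10 attempted swaps per edge), preserving the number of nodes and edges
#' and the exact binary degree sequence; the original edge weights are then
#' reassigned to the rewired edges by a random permutation.
#'
#' @param net a [ThresholdedNetwork-class] (or non-negative symmetric matrix).
#' @param seed RNG seed for the rewiring and the weight permutation.
#' @return A weight matrix of the same dimension (for a
#'   [ThresholdedNetwork-class] input, an object of the same class).
#' @export
randomRewire <- function(net, seed = 1L) {
  isTN <- is(net, "ThresholdedNetwork")
  W <- if (isTN) net@weights else net
  Wb <- rewireWeights(W, seed)
  if (isTN)
    new("ThresholdedNetwork", weights = Wb, sparsity = net@sparsity,
        gammaThreshold = net@gammaThreshold)
  else Wb
}

rewireWeights <- function(W, seed) {
  nEdge <- sum(W[upper.tri(W)] > 0)
  if (nEdge < 2) return(W)
  # localized RNG so rewiring never disturbs the caller's random stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  g <- asIgraph(W)
  wts <- igraph::E(g)$weight
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10L * nEdge))
  A <- igraph::as_adjacency_matrix(gr, sparse = FALSE)
  ij <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  perm <- sample.int(length(wts))
  Wb <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  Wb[ij] <- wts[perm]
  Wb[ij[, c(2, 1), drop = FALSE]] <- wts[perm]
  Wb
}

#' Area under a metric curve over the sparsity sweep
#'
#' Trapezoidal integral of the metric values over the sparsity grid,
#' divided by the sweep range -- a mean-height summary so the AUC is on the
#' same scale as the metric itself.
#'
#' @param values metric values, one per sparsity.
#' @param sparsities sparsity grid (equal length, >= 2).
#' @return Scalar AUC.
#' @export
aucOverThresholds <- function(values, sparsities) {
  n <- length(values)
  if (n != length(sparsities)) stop("values and sparsities differ in length")
  if (n < 2) stop("need at least 2 sweep points")
  ds <- diff(sparsities)
  sum(ds * (values[-1] + values[-n]) / 2) / (sparsities[n] - sparsities[1])
}

#' Metric curves across the sparsity sweep
#'
#' Thresholds a subject network at every sparsity in the sweep (default
#' 0.02 to 0.50 in steps of 0.01, 49 points), computes the global and nodal
#' metric panel at each threshold, and summarizes every metric by its
#' area under the curve.
#'
#' @param net a [KLSNetwork-class].
#' @param sparsities sparsity sweep (default `seq(0.02, 0.50, by = 0.01)`).
#' @param nRand random nulls per threshold for normalized metrics
#'   (default 100).
#' @param seed master seed; per-threshold null seeds are derived offsets.
#' @return List with `sparsities`; `global`: matrix (metric x sparsity);
#'   `nodal`: list of `Dc`, `Bc` matrices (region x sparsity); `auc`: named
#'   vector of global-metric AUCs; `nodalAuc`: list of per-region AUC
#'   vectors.
#' @export
metricCurves <- function(net, sparsities = seq(0.02, 0.50, by = 0.01),
                         nRand = 100L, seed = 1L) {
  metricNames <- c("Ar", "Q", "Hr", "Eglobal", "Elocal", "Cp", "Lp", "Sr",
                   "lambda", "gamma", "sigma")
  R <- nrow(if (is(net, "KLSNetwork")) net@weights else net)
  glob <- matrix(NA_real_, length(metricNames), length(sparsities),
                 dimnames = list(metricNames, NULL))
  Dc <- Bc <- matrix(NA_real_, R, length(sparsities))
  for (t in seq_along(sparsities)) {
    tn <- applySparsityThreshold(net, sparsities[t])
    gm <- computeGlobalMetrics(tn, nRand = nRand, seed = seed + 97L * t)
    glob[, t] <- unlist(gm[metricNames])
    nm <- computeNodalMetrics(tn)
    Dc[, t] <- nm$Dc
    Bc[, t] <- nm$Bc
  }
  ids <- rownames(if (is(net, "KLSNetwork")) net@weights else net)
  rownames(Dc) <- rownames(Bc) <- ids
  list(sparsities = sparsities, global = glob,
       nodal = list(Dc = Dc, Bc = Bc),
       auc = apply(glob, 1L, aucOverThresholds, sparsities = sparsities),
       nodalAuc = list(Dc = apply(Dc, 1L, aucOverThresholds, sparsities = sparsities),
                       Bc = apply(Bc, 1L, aucOverThresholds, sparsities = sparsities)))
}
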