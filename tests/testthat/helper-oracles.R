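# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph) so they can certify the implementations.

# exact Gaussian KDE by direct summation over the sample
bruteKDE <- function(sample, grid, bw, floorEps = 1e-10) {
  dens <- vapply(grid, function(g) mean(dnorm(g, mean = sample, sd = bw)), 1.0)
  p <- pmax(dens * (grid[2] - grid[1]), floorEps)
  p / sum(p)
}

bruteSymKL <- function(p, q) {
  sum(p * log(p / q)) + sum(q * log(q / p))
}

# all-pairs shortest paths (Floyd-Warshall) on edge lengths 1/w
bruteDistances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bruteLp <- function(W) {
  D <- bruteDistances(W)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

bruteEglobal <- function(W) {
  D <- bruteDistances(W)
  d <- D[upper.tri(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

bruteOnnela <- function(W) {
  n <- nrow(W)
  Wh <- W / max(W)
  k <- rowSums(W > 0)
  cp <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) for (l in seq_len(n))
      if (j != i && l != i && j != l)
        acc <- acc + (Wh[i, j] * Wh[i, l] * Wh[j, l])^(1 / 3)
    cp[i] <- acc / (k[i] * (k[i] - 1))
  }
  cp
}

bruteElocal <- function(W) {
  n <- nrow(W)
  eff <- function(M) {
    if (nrow(M) < 2) return(0)
    D <- bruteDistances(M)
    iv <- 1 / D
    diag(iv) <- NA
    mean(iv[!is.na(iv)])
  }
  mean(vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) 0 else eff(W[nb, nb, drop = FALSE])
  }, 1.0))
}

# betweenness by exhaustive enumeration of simple paths (tiny graphs only)
bruteBetweenness <- function(W) {
  n <- nrow(W)
  bc <- numeric(n)
  pathsBetween <- function(s, t) {
    out <- list()
    walk <- function(v, visited, len) {
      if (v == t) {
        out[[length(out) + 1]] <<- list(path = visited, len = len)
        return()
      }
      for (u in which(W[v, ] > 0))
        if (!(u %in% visited)) walk(u, c(visited, u), len + 1 / W[v, u])
    }
    walk(s, s, 0)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- pathsBetween(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, 1.0, "len")
    best <- min(lens)
    sp <- ps[lens <= best + 1e-12]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(sp, function(p) v %in% p$path, TRUE))
      bc[v] <- bc[v] + through / length(sp)
    }
  }
  bc
}

# weighted Newman modularity of a given membership
bruteModularity <- function(W, memb) {
  m2 <- sum(W)
  k <- rowSums(W)
  same <- outer(memb, memb, "==")
  sum(((W - outer(k, k) / m2) * same)) / m2
}

# exhaustive best-partition modularity via restricted growth strings
bruteBestModularity <- function(W) {
  n <- nrow(W)
  best <- -Inf
  rec <- function(memb, maxLab) {
    i <- length(memb) + 1
    if (i > n) {
      q <- bruteModularity(W, memb)
      if (q > best) best <<- q
      return()
    }
    for (lab in seq_len(maxLab + 1))
      rec(c(memb, lab), max(maxLab, lab))
  }
  rec(integer(0), 0)
  best
}

bruteAssortativity <- function(W) {
  s <- rowSums(W)
  e <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  x <- c(s[e[, 1]], s[e[, 2]])
  y <- c(s[e[, 2]], s[e[, 1]])
  n <- length(x)
  (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
}

bruteHierarchy <- function(W) {
  cp <- bruteOnnela(W)
  k <- rowSums(W > 0)
  ok <- k > 1 & cp > 0
  x <- log(k[ok]); y <- log(cp[ok])
  # normal-equations slope
  -( (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2) )
}

bruteSynchronization <- function(W) {
  A <- (W > 0) + 0
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  ev[2] / ev[length(ev)]
}

# random connected-ish symmetric weighted matrix for property sweeps
randomWeightedGraph <- function(n, p = 0.6, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  on <- runif(nrow(ut)) < p
  w <- ifelse(on, runif(nrow(ut), 0.1, 1), 0)
  W[ut] <- w
  W[ut[, c(2, 1)]] <- w
  dimnames(W) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  W
}
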