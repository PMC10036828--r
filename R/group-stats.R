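#' Residualize values on covariates
#'
#' Ordinary least squares of the values on an intercept plus the covariate
#' columns; returns the residuals together with the fitted coefficients so
#' that weights estimated on a training fold can be applied unchanged to
#' held-out subjects.
#'
#' @param values numeric vector (or matrix, one column per feature).
#' @param covariates numeric matrix with one row per subject (e.g. age and
#'   a 0/1 sex code). An intercept column is added internally.
#' @return List with `residuals` (same shape as `values`) and
#'   `coefficients` ((1 + ncol(covariates)) x features matrix).
#' @export
residualizeCovariates <- function(values, covariates) {
  v <- as.matrix(values)
  Z <- as.matrix(covariates)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("cov", seq_len(ncol(Z)))
  if (nrow(Z) != nrow(v)) stop("covariate rows must match values")
  # constant covariate columns are absorbed by the intercept: drop them but
  # keep a zero coefficient so stored weights stay aligned with the input
  keep <- apply(Z, 2, function(col) stats::var(col) > 0)
  X <- cbind(Intercept = 1, Z[, keep, drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  fit <- stats::lm.fit(X, v)
  co <- matrix(0, 1 + ncol(Z), ncol(v),
               dimnames = list(c("Intercept", colnames(Z)), colnames(v)))
  co[c(TRUE, keep), ] <- as.matrix(fit$coefficients)
  list(residuals = if (is.matrix(values)) fit$residuals else drop(fit$residuals),
       coefficients = co)
}

#' Apply stored residualization coefficients to new data
#'
#' @param values new values (vector or matrix).
#' @param covariates new covariate rows.
#' @param coefficients coefficients from [residualizeCovariates()].
#' @return Residuals of the new data under the training-fold fit.
#' @export
applyResidualization <- function(values, covariates, coefficients) {
  v <- as.matrix(values)
  X <- cbind(1, as.matrix(covariates))
  r <- v - X %*% coefficients
  if (is.matrix(values)) r else drop(r)
}

#' Pooled-variance two-sample t test
#'
#' Classical equal-variance two-sample t statistic with two-sided p value.
#' When the compared values are residuals of a covariate regression with
#' `k` estimated covariate slopes, `dfLost = k` subtracts those degrees of
#' freedom.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param dfLost degrees of freedom already consumed by covariate
#'   adjustment (default 0).
#' @param welch use Welch's unequal-variance form instead (default FALSE).
#' @return List with `t`, `p` and `df`.
#' @export
twoSampleT <- function(a, b, dfLost = 0L, welch = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  if (welch) {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2 - dfLost
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p values (via [stats::p.adjust()]) and the significant
#' set at level `q`.
#'
#' @param pvals p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and logical `significant`.
#' @export
fdrCorrect <- function(pvals, q = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, significant = adj <= q)
}

groupTTests <- function(feat, group, covariates, q = 0.05, welch = FALSE) {
  # vectorized residualize-then-pooled-t across feature columns
  k <- ncol(as.matrix(covariates))
  res <- residualizeCovariates(feat, covariates)$residuals
  res <- as.matrix(res)
  isA <- group == levels(factor(group, levels = unique(group)))[1]
  a <- res[isA, , drop = FALSE]
  b <- res[!isA, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2 - k
  }
  t <- (colMeans(a) - colMeans(b)) / se
  p <- 2 * stats::pt(-abs(t), df)
  fdr <- fdrCorrect(p, q)
  data.frame(feature = colnames(feat), t = t, df = df, p = p,
             p_fdr = fdr$adjusted, significant = fdr$significant,
             direction = ifelse(t > 0, "first>second", "first<second"),
             row.names = NULL)
}

#' Edgewise (and general feature-wise) group comparison
#'
#' Covariate-adjusted two-sample comparison of every feature between two
#' groups: each feature is residualized on age and sex across the pooled
#' sample, compared with a pooled-variance t test (degrees of freedom
#' reduced by the number of covariates), and the family is corrected with
#' the Benjamini-Hochberg procedure. Edge, nodal and global metric families
#' should be corrected as separate calls.
#'
#' @param features numeric matrix, subjects x features, with column names
#'   (e.g. vectorized upper-triangle connections named "i_j").
#' @param group factor/character with two levels; the first level
#'   encountered is reported as the first group in `direction`.
#' @param covariates matrix of nuisance covariates (subjects x k).
#' @param q FDR level (default 0.05).
#' @param welch use Welch's t instead of the pooled form.
#' @return data.frame with feature, t, df, p, p_fdr, significant, direction.
#' @examples
#' cfg <- simulationConfig(nPatients = 30, nControls = 30, nRegions = 10,
#'   plantedEdges = data.frame(i = 1, j = 2, d = 2), seed = 42)
#' coh <- simulateConnectivityDirect(cfg)
#' res <- edgewiseComparison(connectivityFeatures(coh$networks),
#'                           coh$cohort$group,
#'                           cbind(age = coh$cohort$age, sex = coh$cohort$sex))
#' head(res[order(res$p), ])
#' @export
edgewiseComparison <- function(features, group, covariates, q = 0.05,
                               welch = FALSE) {
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  if (length(unique(group)) != 2L) stop("exactly two groups required")
  groupTTests(features, group, covariates, q = q, welch = welch)
}

#' Vectorize connectivity matrices into a feature table
#'
#' Stacks the upper triangles of a list of subject networks into a
#' subjects x edges matrix with columns named `"<i>_<j>"` by region id.
#'
#' @param nets list of [KLSNetwork-class] (or matrices with dimnames).
#' @return Numeric matrix, one row per subject, one column per region pair.
#' @export
connectivityFeatures <- function(nets) {
  getW <- function(n) if (is(n, "KLSNetwork")) n@weights else n
  W1 <- getW(nets[[1]])
  ids <- rownames(W1)
  ut <- which(upper.tri(W1), arr.ind = TRUE)
  cn <- paste(ids[ut[, 1]], ids[ut[, 2]], sep = "_")
  feat <- t(vapply(nets, function(n) getW(n)[ut], numeric(nrow(ut))))
  colnames(feat) <- cn
  rownames(feat) <- vapply(nets, function(n)
    if (is(n, "KLSNetwork")) n@subjectId else "", "")
  feat
}
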