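#' HC-anchored confounder adjustment
#'
#' Removes nuisance covariate effects (typically age and sex) from a
#' measure using weights estimated in the healthy-control group only, so
#' that disease-related variance is not regressed out: a linear model is
#' fit on HC, predictions are generated for the whole population,
#' corrected values are observed minus predicted, and individual z-scores
#' are (corrected value minus HC mean of corrected values) divided by the
#' HC standard deviation of corrected values.
#'
#' @param values numeric vector of the measure (one value per subject).
#' @param covariates data.frame of confounders (e.g. `age`, `sex`).
#' @param hcMask logical vector marking healthy controls.
#' @param minHC minimum number of HC required.
#' @return list of class `adjusted_scores`: `z` (per-subject standardized
#'   adjusted values), `corrected`, `coefficients` (HC-fit model),
#'   `hcMean`, `hcSD`.
#' @export
adjustConfounders <- function(values, covariates, hcMask, minHC = 10L) {
  values <- as.numeric(values)
  hcMask <- as.logical(hcMask)
  stopifnot(length(hcMask) == length(values))
  if (sum(hcMask) < minHC)
    stop(sprintf("need at least %d HC subjects (got %d)", minHC, sum(hcMask)))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrX <- qr(X[hcMask, , drop = FALSE])
  if (qrX$rank < ncol(X))
    stop("singular design: confounders are collinear or constant in the HC group")
  beta <- qr.coef(qrX, values[hcMask])
  corrected <- values - as.vector(X %*% beta)
  hcMean <- mean(corrected[hcMask])
  hcSD <- stats::sd(corrected[hcMask])
  if (!is.finite(hcSD) || hcSD <= 1e-10 * (1 + abs(hcMean)))
    stop("zero variance of corrected values in the HC group")
  structure(list(z = (corrected - hcMean) / hcSD, corrected = corrected,
                 coefficients = beta, hcMean = hcMean, hcSD = hcSD),
            class = "adjusted_scores")
}

# pooled-variance two-sample t statistics for group-1 index subsets,
# vectorized over subsets via sufficient statistics of the pooled sample
.pooledTFromSums <- function(S1, Q1, Tot, Q, n1, n2) {
  m1 <- S1 / n1
  m2 <- (Tot - S1) / n2
  ss <- (Q1 - n1 * m1^2) + ((Q - Q1) - n2 * m2^2)
  sp2 <- ss / (n1 + n2 - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  num <- m1 - m2
  t <- ifelse(denom > 0, num / denom, ifelse(num == 0, 0, sign(num) * Inf))
  t
}

#' Two-sided permutation t test
#'
#' Tests a two-sample difference with the pooled-variance t statistic
#' under the permutation null obtained by reshuffling group labels. When
#' the total number of group assignments is at most `exhaustiveLimit` (and
#' `exhaustiveIfSmall` is on), all assignments are enumerated and the
#' p-value is the exact proportion with `|t|` at least as extreme as
#' observed. Otherwise `nPerm` random reshuffles are drawn and
#' `p = (#{|t_perm| >= |t_obs|} + 1) / (nPerm + 1)`, which can never be 0.
#'
#' @param x,y numeric samples (each of size at least 2).
#' @param nPerm number of random permutations (at least 1000 when not
#'   exhaustive).
#' @param seed optional RNG seed.
#' @param exhaustiveIfSmall enumerate all assignments when feasible.
#' @param exhaustiveLimit maximum number of assignments to enumerate.
#' @return list with `statistic` (observed pooled t), `p`, `exhaustive`
#'   flag and the number of permutations used.
#' @export
permutationTtest <- function(x, y, nPerm = 10000L, seed = NULL,
                             exhaustiveIfSmall = TRUE,
                             exhaustiveLimit = 20000) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  z <- c(x, y)
  n <- n1 + n2
  Tot <- sum(z); Q <- sum(z^2)
  tObs <- .pooledTFromSums(sum(x), sum(x^2), Tot, Q, n1, n2)
  eps <- 1e-12
  nArrange <- choose(n, n1)
  if (exhaustiveIfSmall && nArrange <= exhaustiveLimit) {
    idx <- utils::combn(n, n1)
    zc <- z[idx]; dim(zc) <- dim(idx)
    S1 <- colSums(zc)
    Q1 <- colSums(zc^2)
    tp <- .pooledTFromSums(S1, Q1, Tot, Q, n1, n2)
    p <- mean(abs(tp) >= abs(tObs) - eps)
    return(list(statistic = tObs, p = p, exhaustive = TRUE,
                nPerm = as.integer(nArrange)))
  }
  if (nPerm < 1000L) stop("nPerm must be at least 1000 for the Monte Carlo test")
  if (!is.null(seed)) set.seed(seed)
  idx <- vapply(seq_len(nPerm), function(b) sample.int(n, n1),
                integer(n1))
  zc <- z[idx]; dim(zc) <- c(n1, nPerm)
  S1 <- colSums(zc)
  Q1 <- colSums(zc^2)
  tp <- .pooledTFromSums(S1, Q1, Tot, Q, n1, n2)
  p <- (sum(abs(tp) >= abs(tObs) - eps) + 1) / (nPerm + 1)
  list(statistic = tObs, p = p, exhaustive = FALSE, nPerm = as.integer(nPerm))
}

#' Nodal group comparison with FDR control
#'
#' Permutation t tests of per-node values (typically confounder-adjusted
#' coreness) between two groups, with a single label reshuffle shared
#' across nodes per permutation (preserving the cross-node dependence) and
#' Benjamini-Hochberg control of the false discovery rate across the node
#' family.
#'
#' @param values subjects x nodes numeric matrix.
#' @param groups two-level factor (or vector) of group labels; the first
#'   level is taken as group 1.
#' @param nPerm number of label permutations.
#' @param q FDR level for the Benjamini-Hochberg procedure.
#' @param seed optional RNG seed.
#' @return data.frame with one row per node: `node`, `statistic`, `g`
#'   (Hedges' g), `p` (permutation), `pBH` (BH-adjusted), `significant`.
#' @export
nodalComparison <- function(values, groups, nPerm = 10000L, q = 0.05,
                            seed = NULL) {
  Z <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly 2 levels")
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  n <- n1 + n2
  if (!is.null(seed)) set.seed(seed)
  Tot <- colSums(Z)
  Q <- colSums(Z^2)
  tObs <- .pooledTFromSums(colSums(Z[g1, , drop = FALSE]),
                           colSums(Z[g1, , drop = FALSE]^2), Tot, Q, n1, n2)
  # shared permutations as a sparse 0/1 selection matrix
  P <- matrix(0, nPerm, n)
  for (b in seq_len(nPerm)) P[b, sample.int(n, n1)] <- 1
  S1 <- P %*% Z
  Q1 <- P %*% (Z^2)
  eps <- 1e-12
  TotM <- matrix(Tot, nPerm, ncol(Z), byrow = TRUE)
  QM <- matrix(Q, nPerm, ncol(Z), byrow = TRUE)
  tp <- .pooledTFromSums(S1, Q1, TotM, QM, n1, n2)
  exceed <- colSums(abs(tp) >= matrix(abs(tObs) - eps, nPerm, ncol(Z),
                                      byrow = TRUE))
  p <- (exceed + 1) / (nPerm + 1)
  pBH <- stats::p.adjust(p, method = "BH")
  gEff <- vapply(seq_len(ncol(Z)), function(j)
    .hedgesGValue(Z[g1, j], Z[!g1, j]), numeric(1))
  nodes <- colnames(Z)
  if (is.null(nodes)) nodes <- defaultNodeLabels(ncol(Z))
  data.frame(node = nodes, statistic = tObs, g = gEff, p = p, pBH = pBH,
             significant = pBH <= q, row.names = NULL,
             stringsAsFactors = FALSE)
}

.hedgesGValue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (!is.finite(sp) || sp <= 0) return(NA_real_)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  (mean(x) - mean(y)) / sp * J
}

#' Hedges' g with bootstrap confidence interval
#'
#' Small-sample corrected standardized mean difference:
#' `g = d * J` with `d` the pooled-SD Cohen's d (denominator n1+n2-2) and
#' `J = 1 - 3 / (4(n1+n2) - 9)`. The confidence interval is a percentile
#' bootstrap with per-group resampling.
#'
#' @param x,y numeric samples (each of size at least 2).
#' @param nBoot number of bootstrap resamples (default 5000).
#' @param seed optional RNG seed.
#' @param conf confidence level.
#' @return list with `g`, `ciLow`, `ciHigh`, `n1`, `n2`, `nBoot`.
#' @export
hedgesG <- function(x, y, nBoot = 5000L, seed = NULL, conf = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  g <- .hedgesGValue(x, y)
  if (is.na(g)) stop("zero pooled standard deviation")
  if (!is.null(seed)) set.seed(seed)
  bg <- vapply(seq_len(nBoot), function(b)
    .hedgesGValue(x[sample.int(n1, n1, replace = TRUE)],
                  y[sample.int(n2, n2, replace = TRUE)]), numeric(1))
  bg <- bg[is.finite(bg)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(bg, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(g = g, ciLow = ci[1], ciHigh = ci[2], n1 = n1, n2 = n2,
       nBoot = as.integer(nBoot))
}

#' One-way ANOVA with Tukey post hoc tests
#'
#' Fixed-effects one-way analysis of variance across groups (e.g. clinical
#' phenotypes) followed by Tukey honest-significant-difference pairwise
#' comparisons via the studentized range distribution.
#'
#' @param values numeric response vector.
#' @param groups group labels; at least 2 groups with at least 2
#'   observations each.
#' @return list with `F`, `p`, `df` (between/within), `groupMeans` and
#'   `tukey` (data.frame of pairwise differences and adjusted p-values).
#' @export
anovaTukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    bad <- names(which(table(groups) < 2L))[1]
    stop(sprintf("group '%s' has fewer than 2 observations", bad))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      ciLow = tk[, "lwr"], ciHigh = tk[, "upr"],
                      pAdj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = c(between = tab[1, "Df"], within = tab[2, "Df"]),
       groupMeans = tapply(values, groups, mean), tukey = tukey)
}

#' Dichotomize clinical scores
#'
#' Splits patients by level of physical disability (`EDSS >= 4`, inclusive,
#' vs. `EDSS < 4`) or information processing speed (impaired: SDMT z-score
#' strictly below -1.5, vs. preserved). Subjects with a missing score get
#' `NA` and are counted as excluded.
#'
#' @param records cohort record data.frame (needs `edss` or `sdmt_z`).
#' @param task `"disability"` (EDSS) or `"ips"` (SDMT).
#' @return factor aligned with `records` rows; levels
#'   `c("EDSS<4", "EDSS>=4")` or `c("IPS-P", "IPS-I")`; attribute
#'   `nExcluded` counts missing scores.
#' @export
dichotomizeClinical <- function(records, task = c("disability", "ips")) {
  task <- match.arg(task)
  if (task == "disability") {
    v <- records$edss
    lab <- ifelse(v >= 4, "EDSS>=4", "EDSS<4")
    lev <- c("EDSS<4", "EDSS>=4")
  } else {
    v <- records$sdmt_z
    lab <- ifelse(v < -1.5, "IPS-I", "IPS-P")
    lev <- c("IPS-P", "IPS-I")
  }
  nExcl <- sum(is.na(v))
  if (nExcl > 0)
    message(sprintf("%d subject(s) excluded from the %s dichotomy (missing score)",
                    nExcl, task))
  structure(factor(lab, levels = lev), nExcluded = nExcl)
}
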