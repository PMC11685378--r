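#' Empirical-Bayes location/scale harmonization of multi-site features
#'
#' Removes additive and multiplicative site effects from a subjects x
#' features matrix while preserving the modeled biological covariates
#' (typically age, sex and disease group). Features are standardized by a
#' fitted grand model (site indicators plus covariates), per-site
#' location (gamma) and scale (delta^2) are estimated per feature and,
#' with `useEB = TRUE`, shrunk across features with parametric
#' empirical-Bayes priors (normal for gamma, inverse-gamma for delta^2,
#' method-of-moments hyperparameters, iterative conditional solution);
#' site location is subtracted, scale divided out, and the grand model
#' including covariate effects is restored.
#'
#' With a single site the input is returned unchanged. Features with zero
#' variance across subjects (or zero residual variance after the grand
#' model) are passed through untouched and counted in the returned model.
#'
#' @param features subjects x features numeric matrix (all finite).
#' @param site per-subject site labels; every site needs at least 2
#'   subjects when there is more than one site.
#' @param covariates data.frame of biological covariates to preserve
#'   (e.g. age, sex, group); `NULL` for none.
#' @param useEB apply parametric empirical-Bayes shrinkage of the site
#'   parameters (`FALSE` uses the raw per-site estimates).
#' @return list with `adjusted` (harmonized matrix, same dimensions) and
#'   `model` (class `harmonization_model`): grand coefficients, per-site
#'   location/scale estimates before and after shrinkage, EB
#'   hyperparameters, pooled feature variance, and indices of passthrough
#'   features.
#' @export
combatHarmonize <- function(features, site, covariates = NULL, useEB = TRUE) {
  Y <- as.matrix(features)
  if (any(!is.finite(Y))) stop("features must be finite")
  n <- nrow(Y)
  site <- factor(site)
  if (length(site) != n) stop("site must give one label per subject")
  ni <- table(site)
  nbatch <- length(ni)
  if (nbatch == 1L) {
    model <- structure(list(sites = levels(site), nPerSite = as.vector(ni),
                            singleSite = TRUE, passthrough = integer(0)),
                       class = "harmonization_model")
    return(list(adjusted = Y, model = model))
  }
  if (any(ni < 2L))
    stop(sprintf("site '%s' has fewer than 2 subjects",
                 names(ni)[which(ni < 2L)[1]]))

  batchmod <- stats::model.matrix(~ -1 + site)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mod <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  } else {
    mod <- matrix(0, n, 0)
  }
  design <- cbind(batchmod, mod)
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient design: a covariate is constant or confounded with site")

  # passthrough of degenerate features (zero variance across subjects)
  v0 <- apply(Y, 2, stats::var)
  passthrough <- unname(which(v0 < .Machine$double.eps))
  act <- setdiff(seq_len(ncol(Y)), passthrough)
  Ya <- Y[, act, drop = FALSE]

  Bhat <- solve(crossprod(design), crossprod(design, Ya))
  grand <- as.vector(ni / n) %*% Bhat[seq_len(nbatch), , drop = FALSE]
  fitted <- design %*% Bhat
  varPooled <- colSums((Ya - fitted)^2) / n
  degen <- varPooled < .Machine$double.eps
  if (any(degen)) {
    passthrough <- sort(c(passthrough, act[degen]))
    act <- act[!degen]
    Ya <- Y[, act, drop = FALSE]
    Bhat <- Bhat[, !degen, drop = FALSE]
    grand <- grand[, !degen, drop = FALSE]
    fitted <- fitted[, !degen, drop = FALSE]
    varPooled <- varPooled[!degen]
  }
  standMean <- matrix(grand, n, length(act), byrow = TRUE)
  if (ncol(mod) > 0)
    standMean <- standMean +
      mod %*% Bhat[-seq_len(nbatch), , drop = FALSE]
  Z <- sweep(Ya - standMean, 2, sqrt(varPooled), "/")

  gammaHat <- t(vapply(levels(site), function(b)
    colMeans(Z[site == b, , drop = FALSE]), numeric(length(act))))
  deltaHat <- t(vapply(levels(site), function(b)
    apply(Z[site == b, , drop = FALSE], 2, stats::var),
    numeric(length(act))))

  if (useEB) {
    gammaBar <- rowMeans(gammaHat)
    tau2 <- apply(gammaHat, 1, stats::var)
    m <- rowMeans(deltaHat)
    s2 <- apply(deltaHat, 1, stats::var)
    aPrior <- (2 * s2 + m^2) / s2
    bPrior <- (m * s2 + m^3) / s2
    gammaStar <- gammaHat
    deltaStar <- deltaHat
    for (b in seq_len(nbatch)) {
      nb <- as.integer(ni[b])
      Zb <- Z[site == levels(site)[b], , drop = FALSE]
      sol <- .ebSolve(Zb, gammaHat[b, ], deltaHat[b, ], gammaBar[b],
                      tau2[b], aPrior[b], bPrior[b], nb)
      gammaStar[b, ] <- sol$gamma
      deltaStar[b, ] <- sol$delta2
    }
    eb <- list(gammaBar = gammaBar, tau2 = tau2, aPrior = aPrior,
               bPrior = bPrior)
  } else {
    gammaStar <- gammaHat
    deltaStar <- deltaHat
    eb <- NULL
  }

  Zadj <- Z
  for (b in seq_len(nbatch)) {
    rows <- site == levels(site)[b]
    Zadj[rows, ] <- sweep(
      sweep(Z[rows, , drop = FALSE], 2, gammaStar[b, ], "-"),
      2, sqrt(deltaStar[b, ]), "/")
  }
  adjusted <- Y
  adjusted[, act] <- sweep(Zadj, 2, sqrt(varPooled), "*") + standMean

  model <- structure(list(
    sites = levels(site), nPerSite = as.vector(ni), singleSite = FALSE,
    grandCoefficients = Bhat, siteLocation = gammaHat, siteScale = deltaHat,
    siteLocationStar = gammaStar, siteScaleStar = deltaStar,
    ebHyperparameters = eb, pooledVariance = varPooled,
    passthrough = passthrough, useEB = useEB),
    class = "harmonization_model")
  list(adjusted = adjusted, model = model)
}

# iterative conditional solution for the EB posterior site parameters
.ebSolve <- function(Zb, gHat, dHat, gBar, tau2, a, b, nb,
                     conv = 1e-4, maxIter = 200L) {
  g <- gHat
  d <- dHat
  for (it in seq_len(maxIter)) {
    gNew <- (tau2 * nb * gHat + d * gBar) / (tau2 * nb + d)
    sum2 <- colSums(sweep(Zb, 2, gNew, "-")^2)
    dNew <- (0.5 * sum2 + b) / (nb / 2 + a - 1)
    change <- max(abs(gNew - g) / pmax(abs(g), 1e-12),
                  abs(dNew - d) / pmax(abs(d), 1e-12))
    g <- gNew
    d <- dNew
    if (change < conv) break
  }
  list(gamma = g, delta2 = d)
}

#' Clamp harmonized edge weights at zero
#'
#' Harmonization can push small edge weights slightly negative; negative
#' values are invalid layer weights and are set to zero. Idempotent.
#'
#' @param features numeric matrix or vector of edge weights.
#' @return clamped object of the same shape, with attribute `nClamped`.
#' @export
clampNonnegative <- function(features) {
  nneg <- sum(features < 0)
  if (nneg > 0)
    message(sprintf("clamped %d negative edge weight(s) to zero", nneg))
  out <- pmax(features, 0)
  attr(out, "nClamped") <- nneg
  out
}

#' @export
print.harmonization_model <- function(x, ...) {
  if (isTRUE(x$singleSite)) {
    cat("harmonization_model: single site, identity transform\n")
  } else {
    cat(sprintf("harmonization_model: %d sites (%s), EB %s, %d passthrough feature(s)\n",
                length(x$sites), paste(x$nPerSite, collapse = "/"),
                if (isTRUE(x$useEB)) "on" else "off", length(x$passthrough)))
  }
  invisible(x)
}
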