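#' Standardize regional volumes against the healthy-control norm
#'
#' For each region, regional volume is regressed on the supplied covariates
#' (ordinary least squares, fit on healthy controls only) and the residual
#' of every subject is divided by the standard deviation of the HC
#' residuals. The fitted HC model is returned so the same norm can be
#' applied to new subjects. With `covariates = NULL` the model is
#' intercept-only, i.e. plain z-scoring against the HC mean.
#'
#' @param volumes subjects x nodes numeric matrix of regional volumes (ml).
#' @param covariates data.frame (or matrix) of per-subject covariates,
#'   typically `age` (years), `sex` (coded 0/1) and `tiv` (ml); `NULL` for
#'   intercept-only standardization.
#' @param hcMask logical vector marking the healthy controls used to fit
#'   the norm. At least 10 HC are required when covariates are supplied.
#' @param minHC minimum number of HC subjects required when fitting a
#'   covariate model.
#' @return list of class `volume_zscores` with elements `z` (subjects x
#'   nodes matrix of standardized adjusted volumes), `coefficients`
#'   (covariates+1 x nodes), `hcSD` (per-node SD of HC residuals, sample
#'   convention) and `covariateNames`.
#' @details The SD uses the sample convention (denominator n-1), so that
#'   three HC volumes 10, 12, 14 with no covariates map to z = (-1, 0, +1).
#'   Over the HC subjects used for fitting, each node's z has mean 0 and
#'   SD 1 by construction.
#' @export
zscoreVolumes <- function(volumes, covariates = NULL, hcMask, minHC = 10L) {
  volumes <- as.matrix(volumes)
  hcMask <- as.logical(hcMask)
  stopifnot(length(hcMask) == nrow(volumes))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (sum(hcMask) < minHC)
      stop(sprintf("need at least %d HC subjects to fit the covariate model (got %d)",
                   minHC, sum(hcMask)))
    X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  } else {
    X <- matrix(1, nrow(volumes), 1, dimnames = list(NULL, "(Intercept)"))
  }
  storage.mode(X) <- "double"
  Xhc <- X[hcMask, , drop = FALSE]
  if (sum(hcMask) < ncol(X))
    stop("fewer HC subjects than model parameters")
  qrX <- qr(Xhc)
  if (qrX$rank < ncol(X))
    stop("singular design: covariates are collinear or constant in the HC group")
  beta <- qr.coef(qrX, volumes[hcMask, , drop = FALSE])
  pred <- X %*% beta
  resid <- volumes - pred
  hcSD <- apply(resid[hcMask, , drop = FALSE], 2, stats::sd)
  if (any(hcSD <= 0))
    stop(sprintf("zero residual variance in the HC group at node %d",
                 which(hcSD <= 0)[1]))
  z <- sweep(resid, 2, hcSD, "/")
  dimnames(z) <- dimnames(volumes)
  structure(list(z = z, coefficients = beta, hcSD = hcSD,
                 covariateNames = colnames(X)[-1]),
            class = "volume_zscores")
}

#' Build a morphological-covariance layer from one subject's z-scores
#'
#' Edge weight between regions i and j encodes their shared deviation from
#' the healthy norm: `w_ij = exp(-(z_i - z_j)^2)`, which lies in (0, 1] and
#' equals 1 exactly when the two regions deviate identically. The diagonal
#' is set to zero (self-edges carry no information for strength or
#' coreness).
#'
#' @param z numeric vector of per-node volume z-scores for one subject.
#' @param nodeLabels optional node labels; defaults to `names(z)`.
#' @return a [ConnectivityLayer-class] of kind `"MC"`.
#' @export
buildMCLayer <- function(z, nodeLabels = names(z)) {
  force(nodeLabels)
  z <- as.numeric(z)
  if (any(!is.finite(z)))
    stop(sprintf("non-finite z-score at node %d", which(!is.finite(z))[1]))
  if (is.null(nodeLabels)) nodeLabels <- defaultNodeLabels(length(z))
  d <- outer(z, z, "-")
  w <- exp(-d^2)
  ConnectivityLayer("MC", w, nodeLabels)
}

#' Transform raw structural connectivity weights
#'
#' Applies `log10(1 + w)` to compress streamline-weight magnitudes spanning
#' several orders of magnitude while preserving zeros, nonnegativity and
#' the rank order of edges.
#'
#' @param raw square symmetric nonnegative matrix of raw SC weights
#'   (e.g. SIFT2 streamline weight sums).
#' @param nodeLabels optional node labels.
#' @return a [ConnectivityLayer-class] of kind `"SC"`.
#' @export
transformSC <- function(raw, nodeLabels = rownames(raw)) {
  raw <- as.matrix(raw)
  if (min(raw) < 0)
    stop("raw SC weights must be nonnegative")
  ConnectivityLayer("SC", log10(1 + raw), nodeLabels)
}

#' Transform a functional correlation matrix
#'
#' Fisher z-transforms the Pearson correlations and takes absolute values
#' (`w = |atanh(r)|`), since anticorrelations may encode relevant coupling.
#' The diagonal is forced to zero.
#'
#' @param r square symmetric correlation matrix with off-diagonal entries
#'   strictly inside (-1, 1).
#' @param nodeLabels optional node labels.
#' @return a [ConnectivityLayer-class] of kind `"FC"`.
#' @export
transformFC <- function(r, nodeLabels = rownames(r)) {
  r <- as.matrix(r)
  off <- r[row(r) != col(r)]
  if (any(abs(off) >= 1))
    stop("off-diagonal correlations must lie strictly inside (-1, 1)")
  w <- abs(atanh(r))
  diag(w) <- 0
  ConnectivityLayer("FC", w, nodeLabels)
}

#' Normalize a layer by its largest singular value
#'
#' Divides all weights by the layer's largest singular value (the spectral
#' norm), so that every layer enters the multiplex with top singular value
#' exactly 1. This corrects for differences in average link weight across
#' modalities while preserving the rank order of edges within a layer.
#'
#' @param layer a [ConnectivityLayer-class] or a plain square symmetric
#'   matrix.
#' @return object of the same type with largest singular value 1.
#' @export
svdNormalize <- function(layer) {
  w <- if (is(layer, "ConnectivityLayer")) layer@weights else as.matrix(layer)
  if (all(w == 0))
    stop("cannot normalize an all-zero layer (degenerate subject)")
  # symmetric: spectral norm = largest |eigenvalue|; cheaper than full svd
  s1 <- max(abs(eigen(w, symmetric = TRUE, only.values = TRUE)$values))
  out <- w / s1
  if (is(layer, "ConnectivityLayer"))
    ConnectivityLayer(layer@kind, out, rownames(w))
  else out
}

#' Assemble a multimodal multiplex network
#'
#' Stacks the three normalized layers into a multiplex with one-to-one node
#' correspondence across layers. Layers must share the same node labels in
#' the same order and each must already be spectral-norm normalized.
#'
#' @param mc,sc,fc [ConnectivityLayer-class] objects of kinds MC, SC and FC.
#' @param checkNorm verify that each layer's largest singular value is 1
#'   (tolerance 1e-6).
#' @return a [MultiplexNetwork-class].
#' @export
assembleMultiplex <- function(mc, sc, fc, checkNorm = TRUE) {
  layers <- list(mc, sc, fc)
  kinds <- vapply(layers, layerKind, character(1))
  if (!identical(kinds, LAYER_KINDS))
    stop(sprintf("layers must be given in order MC, SC, FC (got %s)",
                 paste(kinds, collapse = ", ")))
  labs <- nodeLabels(mc)
  for (l in list(sc, fc)) {
    other <- nodeLabels(l)
    if (!identical(labs, other)) {
      d <- which(labs != other)[1]
      stop(sprintf("node label mismatch between layers: '%s' vs '%s' at position %d",
                   labs[d], other[d], d))
    }
  }
  if (checkNorm) {
    for (l in layers) {
      s1 <- max(abs(eigen(l@weights, symmetric = TRUE,
                          only.values = TRUE)$values))
      if (abs(s1 - 1) > 1e-6)
        stop(sprintf("%s layer is not normalized (largest singular value %.6g); run svdNormalize() first",
                     layerKind(l), s1))
    }
  }
  new("MultiplexNetwork", layers = layers)
}
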