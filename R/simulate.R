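#' Default parameters of the synthetic cohort generator
#'
#' Central constants of the generative model: planted block mean edge
#' weights (core-core > core-periphery > periphery-periphery), noise
#' scales, covariate slopes on regional volumes, per-phenotype mean attack
#' strengths (ordered CIS < RRMS < SPMS with PPMS intermediate), site
#' effect magnitudes and the attack-to-clinical links (EDSS increasing,
#' SDMT z decreasing, BPF decreasing and TLV increasing in the attack
#' strength delta).
#'
#' @return named list of generator parameters; any subset can be
#'   overridden through the `params` argument of [simulateCohort()].
#' @export
defaultSimParams <- function() {
  list(
    weightMeans = c(cc = 1, cp = 0.35, pp = 0.08),
    layerNoise = 0.1,          # SD of block-weight noise in the MC-like layer scale
    scScale = 50,              # raw SC block mean = weightMeans * scScale
    scShape = 4,               # gamma shape for raw SC weights
    fcFisherMeans = c(cc = 0.7, cp = 0.35, pp = 0.12),
    fcFisherSD = 0.12,         # noise of FC in Fisher-z space
    volumeBaseRange = c(4, 12),      # ml, per-node baseline volumes
    volumeNoiseSD = 0.4,             # ml
    covariateSlopes = c(age = -0.02, sex = 0.3, tiv = 0.004),
    deltaByPhenotype = c(CIS = 0.15, RRMS = 0.30, SPMS = 0.55, PPMS = 0.45),
    deltaSD = 0.08,
    affinityRange = c(0.8, 1),       # planted core attack affinity
    siteVolLocSD = 0.3,              # ml, per-site per-node volume offset
    siteVolScaleSD = 0.05,
    siteScScaleSD = 0.1,             # per-site multiplicative SC effect
    siteFcScaleSD = 0.05,            # per-site multiplicative Fisher-z FC effect
    edssNoiseSD = 0.7,
    sdmtNoiseSD = 0.8,
    bpfHCMean = 0.80, bpfSD = 0.02, bpfSlope = -0.07,
    tlvLogMean = 0.5, tlvLogSlope = 2.2, tlvLogSD = 0.5
  )
}

.mergeParams <- function(params) {
  p <- defaultSimParams()
  if (length(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad))
      stop(sprintf("unknown simulation parameter(s): %s. Valid: %s",
                   paste(bad, collapse = ", "),
                   paste(names(p), collapse = ", ")))
    p[names(params)] <- params
  }
  p
}

# block mean lookup: symmetric matrix of cc/cp/pp means for a core mask
.blockMeans <- function(isCore, means) {
  bl <- outer(isCore, isCore, function(a, b) a + b) # 2 cc, 1 cp, 0 pp
  m <- matrix(means["pp"], length(isCore), length(isCore))
  m[bl == 1] <- means["cp"]
  m[bl == 2] <- means["cc"]
  m
}

.symmetrizeUT <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

#' Planted core-periphery multiplex fixture
#'
#' Generates a three-layer multiplex with an identical planted core in all
#' layers: edge weights are drawn around block means `cc` (core-core),
#' `cp` (core-periphery) and `pp` (periphery-periphery) with additive
#' Gaussian noise truncated at zero, and every layer is spectral-norm
#' normalized. With `noise = 0` the construction is deterministic.
#'
#' @param nNodes number of nodes.
#' @param coreSet planted core, as node labels or indices; must be a
#'   nonempty proper subset of the nodes.
#' @param weightMeans named numeric `(cc, cp, pp)` with `cc > cp > pp > 0`.
#' @param noise SD of additive edge-weight noise.
#' @param seed optional RNG seed.
#' @param nodeLabels optional node labels.
#' @return list with elements `multiplex` ([MultiplexNetwork-class]) and
#'   `coreNodes` (character, the ground-truth core).
#' @export
plantedCoreMultiplex <- function(nNodes, coreSet,
                                 weightMeans = c(cc = 1, cp = 0.5, pp = 0.1),
                                 noise = 0.1, seed = NULL,
                                 nodeLabels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nodeLabels)) nodeLabels <- defaultNodeLabels(nNodes)
  if (is.numeric(coreSet)) coreSet <- nodeLabels[coreSet]
  if (length(coreSet) == 0L) stop("coreSet must be nonempty")
  if (!all(coreSet %in% nodeLabels)) stop("coreSet contains unknown node labels")
  if (length(coreSet) >= nNodes)
    stop("coreSet must be a proper subset of the nodes")
  isCore <- nodeLabels %in% coreSet
  mm <- .blockMeans(isCore, weightMeans)
  layers <- lapply(LAYER_KINDS, function(kind) {
    w <- mm
    if (noise > 0)
      w <- w + matrix(stats::rnorm(nNodes^2, 0, noise), nNodes)
    w <- pmax(.symmetrizeUT(w), 0)
    if (kind == "MC") w <- pmin(w, 1)  # MC weights live in [0, 1]
    svdNormalize(ConnectivityLayer(kind, w, nodeLabels))
  })
  list(multiplex = new("MultiplexNetwork", layers = layers),
       coreNodes = nodeLabels[isCore])
}

#' Apply a targeted hub attack to a multiplex
#'
#' Multiplies the weight of every edge `(i, j)` in every layer by
#' `1 - delta * max(affinity_i, affinity_j)`: edges touching high-affinity
#' (core) nodes are weakened proportionally to the attack strength, the
#' network-science analogue of centrality-targeted damage. `delta = 0`
#' leaves the network untouched; `delta = 1` with affinity 1 everywhere
#' annihilates all edges.
#'
#' @param multiplex a [MultiplexNetwork-class].
#' @param affinity per-node attack affinity in \[0, 1\].
#' @param delta attack strength in \[0, 1\].
#' @return the attacked [MultiplexNetwork-class] (layers are no longer
#'   spectral-norm normalized unless `delta = 0`).
#' @export
applyTargetedAttack <- function(multiplex, affinity, delta) {
  if (length(delta) != 1L || !is.finite(delta) || delta < 0 || delta > 1)
    stop("delta must be a single value in [0, 1]")
  n <- length(nodeLabels(multiplex))
  affinity <- as.numeric(affinity)
  if (length(affinity) != n || any(affinity < 0 | affinity > 1))
    stop("affinity must give one value in [0, 1] per node")
  fac <- 1 - delta * outer(affinity, affinity, pmax)
  diag(fac) <- 1
  layers <- lapply(multiplex@layers, function(l)
    ConnectivityLayer(l@kind, l@weights * fac, nodeLabels(multiplex)))
  new("MultiplexNetwork", layers = layers)
}

.makeParcellation <- function(nNodes) {
  systems <- c("visual", "somatomotor", "dorsal attention",
               "ventral attention", "limbic", "control", "default mode")
  nSub <- if (nNodes > 20) 14L else max(0L, nNodes - 7L)
  nCort <- nNodes - nSub
  data.frame(
    label = defaultNodeLabels(nNodes),
    system = c(rep_len(systems, nCort), rep("subcortical", nSub)),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-site cohort with planted disease structure
#'
#' Generates a cohort carrying the statistical structure the analysis
#' assumes: covariate-dependent regional volumes, raw SC (gamma block
#' weights) and FC (correlation-like block structure) matrices with a
#' shared planted core, a targeted hub attack whose strength delta is zero
#' for controls and increases with clinical phenotype severity
#' (CIS < RRMS < SPMS, PPMS intermediate), clinical scores generated as
#' monotone noisy functions of delta (EDSS up, SDMT z down, BPF down, TLV
#' up), and per-site location/scale effects applied last.
#'
#' @param nHC,nMS numbers of healthy controls and patients.
#' @param nNodes parcellation size (default 114: 100 cortical + 14
#'   subcortical).
#' @param nCore number of planted core nodes (must be < `nNodes`).
#' @param phenotypeMix named probabilities over CIS/RRMS/SPMS/PPMS summing
#'   to 1.
#' @param siteCount number of acquisition sites.
#' @param params named list overriding entries of [defaultSimParams()].
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @return list with elements `cohort` ([CohortData-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @export
simulateCohort <- function(nHC, nMS, nNodes = 114, nCore = 20,
                           phenotypeMix = c(CIS = 0.039, RRMS = 0.780,
                                            SPMS = 0.115, PPMS = 0.066),
                           siteCount = 2, params = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- .mergeParams(params)
  if (nCore >= nNodes) stop("nCore must be smaller than nNodes")
  if (!all(PHENOTYPE_LEVELS %in% names(phenotypeMix)) ||
      abs(sum(phenotypeMix) - 1) > 1e-6 || any(phenotypeMix < 0))
    stop("phenotypeMix must be nonnegative probabilities over CIS, RRMS, SPMS, PPMS summing to 1")

  n <- nHC + nMS
  ids <- sprintf("sub%04d", seq_len(n))
  group <- c(rep("HC", nHC), rep("MS", nMS))
  phenotype <- rep(NA_character_, n)
  if (nMS > 0)
    phenotype[group == "MS"] <- sample(PHENOTYPE_LEVELS, nMS, replace = TRUE,
                                       prob = phenotypeMix[PHENOTYPE_LEVELS])
  site <- sprintf("site%02d", sample.int(siteCount, n, replace = TRUE))
  age <- pmin(pmax(stats::rnorm(n, ifelse(group == "HC", 38.3, 43.3),
                                ifelse(group == "HC", 11.8, 11.4)), 18), 80)
  sex <- ifelse(stats::runif(n) < ifelse(group == "HC", 0.573, 0.663), "F", "M")
  tiv <- stats::rnorm(n, 1450, 120)

  # attack strength: zero for HC, phenotype-graded for MS
  delta <- numeric(n)
  ms <- group == "MS"
  if (any(ms))
    delta[ms] <- pmin(pmax(stats::rnorm(
      nMS, p$deltaByPhenotype[phenotype[ms]], p$deltaSD), 0), 1)
  names(delta) <- ids

  parc <- .makeParcellation(nNodes)
  labs <- parc$label
  coreNodes <- sort(sample.int(nNodes, nCore))
  isCore <- seq_len(nNodes) %in% coreNodes
  affinity <- stats::setNames(numeric(nNodes), labs)
  affinity[isCore] <- stats::runif(nCore, p$affinityRange[1], p$affinityRange[2])

  # regional volumes: node baseline + covariate effects + noise
  base <- stats::runif(nNodes, p$volumeBaseRange[1], p$volumeBaseRange[2])
  sexNum <- as.numeric(sex == "M")
  sl <- p$covariateSlopes
  volumes <- outer(rep(1, n), base) +
    sl["age"] * (age - 40) + sl["sex"] * sexNum + sl["tiv"] * (tiv - 1450) +
    matrix(stats::rnorm(n * nNodes, 0, p$volumeNoiseSD), n)
  dimnames(volumes) <- list(ids, labs)

  scMeans <- .blockMeans(isCore, p$weightMeans) * p$scScale
  fcMeans <- .blockMeans(isCore, p$fcFisherMeans)
  scList <- vector("list", n); names(scList) <- ids
  fcList <- vector("list", n); names(fcList) <- ids
  for (s in seq_len(n)) {
    fac <- 1 - delta[s] * outer(affinity, affinity, pmax)
    sc <- matrix(stats::rgamma(nNodes^2, shape = p$scShape,
                               scale = scMeans / p$scShape), nNodes)
    sc <- .symmetrizeUT(sc) * fac
    fz <- fcMeans + matrix(stats::rnorm(nNodes^2, 0, p$fcFisherSD), nNodes)
    fz <- .symmetrizeUT(fz) * fac
    fc <- tanh(fz)          # guarantees entries strictly inside (-1, 1)
    diag(fc) <- 0
    dimnames(sc) <- dimnames(fc) <- list(labs, labs)
    scList[[s]] <- sc
    fcList[[s]] <- fc
  }

  # clinical measures as monotone noisy functions of delta
  edss <- sdmt <- tlv <- rep(NA_real_, n)
  if (any(ms)) {
    e <- 2 + 5 * delta[ms] + stats::rnorm(nMS, 0, p$edssNoiseSD)
    edss[ms] <- round(pmin(pmax(e, 0), 10) * 2) / 2
    sdmt[ms] <- -2.5 * delta[ms] + stats::rnorm(nMS, 0, p$sdmtNoiseSD)
    tlv[ms] <- exp(p$tlvLogMean + p$tlvLogSlope * delta[ms] +
                     stats::rnorm(nMS, 0, p$tlvLogSD))
  }
  bpf <- pmin(pmax(p$bpfHCMean + p$bpfSlope * delta +
                     stats::rnorm(n, 0, p$bpfSD), 0.4), 0.95)

  # site effects, applied last: volumes get per-node location + scale,
  # SC/FC get a multiplicative per-site effect (FC in Fisher-z space)
  sites <- sort(unique(site))
  siteOffsets <- lapply(sites, function(st) list(
    volumeLocation = stats::rnorm(nNodes, 0, p$siteVolLocSD),
    volumeScale = exp(stats::rnorm(1, 0, p$siteVolScaleSD)),
    scScale = exp(stats::rnorm(1, 0, p$siteScScaleSD)),
    fcScale = exp(stats::rnorm(1, 0, p$siteFcScaleSD))))
  names(siteOffsets) <- sites
  for (s in seq_len(n)) {
    so <- siteOffsets[[site[s]]]
    volumes[s, ] <- volumes[s, ] * so$volumeScale + so$volumeLocation
    scList[[s]] <- scList[[s]] * so$scScale
    fz <- atanh(pmin(pmax(fcList[[s]], -1 + 1e-12), 1 - 1e-12)) * so$fcScale
    fc <- tanh(fz)
    diag(fc) <- 0
    fcList[[s]] <- fc
  }

  records <- data.frame(
    subject_id = ids, group = group, phenotype = phenotype, site = site,
    age = age, sex = sex, tiv = tiv, edss = edss, sdmt_z = sdmt,
    bpf = bpf, tlv = tlv, stringsAsFactors = FALSE)

  cohort <- new("CohortData", records = records, volumes = volumes,
                sc = scList, fc = fcList, parcellation = parc)
  truth <- new("SyntheticTruth", coreNodes = labs[isCore],
               attackStrength = delta, affinity = affinity,
               siteOffsets = siteOffsets, covariateSlopes = sl,
               weightMeans = p$weightMeans)
  list(cohort = cohort, truth = truth)
}
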