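#' Default pipeline configuration
#'
#' Nested list controlling every stage of [runPipeline()]; any subset of
#' keys can be overridden (unknown keys are a hard error). All stochastic
#' stages derive their seeds deterministically from the single top-level
#' `seed`, so re-running with the same configuration reproduces every
#' numeric output exactly.
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    input = list(cohortPath = NULL, volumesPath = NULL, matrixDir = NULL,
                 parcellationPath = NULL),
    simulate = list(nHC = 60L, nMS = 120L, nNodes = 114L, nCore = 20L,
                    phenotypeMix = c(CIS = 0.039, RRMS = 0.780,
                                     SPMS = 0.115, PPMS = 0.066),
                    siteCount = 2L, params = list()),
    grid = list(from = 0.01, to = 1, by = 0.01),
    coefficients = c(0.5, 0.5, 0.5),
    harmonize = list(enabled = TRUE, useEB = TRUE),
    subset = list(bpfZMin = NULL),
    stats = list(nPerm = 2000L, nBoot = 2000L, q = 0.05),
    predict = list(enabled = TRUE,
                   tasks = c("status", "disability", "ips"),
                   searchBudget = 8L, nRepeats = 5L),
    logLevel = "info")
}

.mergeConfig <- function(config, defaults = defaultConfig(),
                         path = character()) {
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) {
    where <- if (length(path)) paste0(paste(path, collapse = "$"), "$") else ""
    stop(sprintf("invalid config key(s): %s. Valid keys at %s: %s",
                 paste0(where, bad, collapse = ", "),
                 if (nzchar(where)) where else "top level",
                 paste(names(defaults), collapse = ", ")))
  }
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(config[[k]]) && !identical(k, "params")) {
      defaults[[k]] <- .mergeConfig(config[[k]], defaults[[k]], c(path, k))
    } else {
      defaults[[k]] <- config[[k]]
    }
  }
  defaults
}

.logStage <- function(cfg, fmt, ...) {
  if (!identical(cfg$logLevel, "quiet")) message(sprintf(fmt, ...))
}

#' Build per-subject multiplex networks from a cohort
#'
#' The construction stage: optional multi-site harmonization of raw
#' volumes (preserving age, sex and group), HC-anchored volume z-scoring
#' and morphological covariance, `log10(1 + w)` SC and `|atanh(r)|` FC
#' transforms, optional edgewise harmonization of the transformed SC/FC
#' (clamped at zero), spectral-norm normalization and multiplex assembly.
#'
#' @param cohort a [CohortData-class].
#' @param harmonize apply multi-site harmonization (skipped automatically
#'   with a single site).
#' @param useEB empirical-Bayes shrinkage in harmonization.
#' @param verbose report stage progress.
#' @return list with `multiplex` (named list of
#'   [MultiplexNetwork-class]), `volumeZ` (the `volume_zscores` fit) and
#'   `harmonizationModels`.
#' @export
buildMultiplexes <- function(cohort, harmonize = TRUE, useEB = TRUE,
                             verbose = FALSE) {
  rec <- cohort@records
  ids <- rec$subject_id
  labs <- nodeLabels(cohort)
  hc <- rec$group == "HC"
  multiSite <- length(unique(rec$site)) > 1L
  volumes <- cohort@volumes
  hmods <- list()
  bio <- data.frame(age = rec$age, sex = as.numeric(rec$sex == "M"),
                    group = as.numeric(rec$group == "MS"))
  if (harmonize && multiSite) {
    h <- combatHarmonize(volumes, rec$site, covariates = bio, useEB = useEB)
    volumes <- h$adjusted
    hmods$volumes <- h$model
  }
  vz <- zscoreVolumes(volumes,
                      covariates = data.frame(age = rec$age,
                                              sex = as.numeric(rec$sex == "M"),
                                              tiv = rec$tiv),
                      hcMask = hc)
  n <- length(labs)
  ut <- upper.tri(matrix(0, n, n))
  edgeMat <- function(lst, transform) {
    t(vapply(ids, function(id) transform(lst[[id]])[ut], numeric(sum(ut))))
  }
  scEdges <- edgeMat(cohort@sc, function(m) log10(1 + m))
  fcEdges <- edgeMat(cohort@fc, function(m) {
    w <- abs(atanh(m)); diag(w) <- 0; w
  })
  if (harmonize && multiSite) {
    hs <- combatHarmonize(scEdges, rec$site, covariates = bio, useEB = useEB)
    scEdges <- suppressMessages(clampNonnegative(hs$adjusted))
    hf <- combatHarmonize(fcEdges, rec$site, covariates = bio, useEB = useEB)
    fcEdges <- suppressMessages(clampNonnegative(hf$adjusted))
    hmods$sc <- hs$model
    hmods$fc <- hf$model
  }
  fromEdges <- function(v) {
    m <- matrix(0, n, n, dimnames = list(labs, labs))
    m[ut] <- v
    m + t(m)
  }
  multiplex <- stats::setNames(vector("list", length(ids)), ids)
  for (s in seq_along(ids)) {
    mc <- svdNormalize(buildMCLayer(vz$z[s, ], labs))
    sc <- svdNormalize(ConnectivityLayer("SC", fromEdges(scEdges[s, ]), labs))
    fc <- svdNormalize(ConnectivityLayer("FC", fromEdges(fcEdges[s, ]), labs))
    multiplex[[s]] <- assembleMultiplex(mc, sc, fc, checkNorm = FALSE)
  }
  if (verbose)
    message(sprintf("built %d multiplex networks (%d nodes, harmonization %s)",
                    length(ids), n,
                    if (harmonize && multiSite) "on" else "off"))
  list(multiplex = multiplex, volumeZ = vz, harmonizationModels = hmods)
}

#' Coreness profiles for a cohort in all domains
#'
#' Multiplex coreness plus single-layer coreness (MC, SC, FC with unit
#' coefficient) for every subject.
#'
#' @param multiplexList named list of per-subject
#'   [MultiplexNetwork-class] objects.
#' @param grid density grid.
#' @param coefficients multiplex layer coefficients.
#' @return named list of subjects x nodes coreness matrices, one per
#'   domain (`multiplex`, `MC`, `SC`, `FC`).
#' @export
cohortCoreness <- function(multiplexList, grid = densityGrid(),
                           coefficients = c(0.5, 0.5, 0.5)) {
  ids <- names(multiplexList)
  labs <- nodeLabels(multiplexList[[1]])
  domains <- c("multiplex", LAYER_KINDS)
  out <- lapply(domains, function(d)
    matrix(NA_real_, length(ids), length(labs),
           dimnames = list(ids, labs)))
  names(out) <- domains
  for (id in ids) {
    mx <- multiplexList[[id]]
    out$multiplex[id, ] <- coreness(mx, grid, coefficients)@coreness
    for (kind in LAYER_KINDS) {
      l <- mx@layers[[match(kind, LAYER_KINDS)]]
      out[[kind]][id, ] <- coreness(l, grid)@coreness
    }
  }
  out
}

#' Per-subject disruption indices in all domains
#'
#' kappa of each subject against the HC mean coreness of the matching
#' domain.
#'
#' @param corenessByDomain list of subjects x nodes coreness matrices from
#'   [cohortCoreness()].
#' @param hcMask logical marking the HC rows used for the reference.
#' @return list with `kappaTable` (data.frame `subject_id`, `multiplex`,
#'   `MC`, `SC`, `FC`) and `references` (per-domain HC mean coreness).
#' @export
cohortKappa <- function(corenessByDomain, hcMask) {
  ids <- rownames(corenessByDomain$multiplex)
  refs <- lapply(corenessByDomain, function(m)
    colMeans(m[hcMask, , drop = FALSE]))
  kt <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (d in names(corenessByDomain)) {
    kt[[d]] <- vapply(ids, function(id)
      disruptionIndex(corenessByDomain[[d]][id, ], refs[[d]])@kappa,
      numeric(1))
  }
  list(kappaTable = kt, references = refs)
}

# covariate-correct a subjects x nodes matrix against the HC-fitted model
# (no per-node standardization: nodes constant across HC, e.g. coreness 0
# everywhere, must pass through rather than error)
.correctMatrixHC <- function(values, covariates, hcMask) {
  X <- cbind(1, as.matrix(covariates))
  qrX <- qr(X[hcMask, , drop = FALSE])
  if (qrX$rank < ncol(X))
    stop("singular design: confounders are collinear or constant in the HC group")
  beta <- qr.coef(qrX, values[hcMask, , drop = FALSE])
  corrected <- values - X %*% beta
  dimnames(corrected) <- dimnames(values)
  corrected
}

.statsStage <- function(rec, corenessByDomain, kappaTable, cfg, seed) {
  hc <- rec$group == "HC"
  ms <- !hc
  conf <- data.frame(age = rec$age, sex = as.numeric(rec$sex == "M"))
  domains <- c("multiplex", "MC", "SC", "FC")
  adjKappa <- lapply(domains, function(d)
    adjustConfounders(kappaTable[[d]], conf, hc)$z)
  names(adjKappa) <- domains
  global <- lapply(domains, function(d) {
    z <- adjKappa[[d]]
    tt <- permutationTtest(z[ms], z[hc], nPerm = cfg$stats$nPerm,
                           seed = seed + 1L)
    gg <- hedgesG(z[hc], z[ms], nBoot = cfg$stats$nBoot, seed = seed + 2L)
    list(domain = d, statistic = tt$statistic, p = tt$p,
         groupKappa = mean(kappaTable[[d]][ms]),
         hedgesG = gg$g, ciLow = gg$ciLow, ciHigh = gg$ciHigh,
         n1 = sum(ms), n2 = sum(hc))
  })
  names(global) <- domains
  # group-level kappa from the MS group-mean coreness profile
  refMultiplex <- colMeans(corenessByDomain$multiplex[hc, , drop = FALSE])
  grpKappa <- groupDisruptionIndex(
    corenessByDomain$multiplex[ms, , drop = FALSE], refMultiplex)
  # nodal comparison on HC-anchored covariate-corrected multiplex coreness
  adjCore <- .correctMatrixHC(corenessByDomain$multiplex, conf, hc)
  nodal <- nodalComparison(adjCore, factor(rec$group,
                                           levels = c("MS", "HC")),
                           nPerm = cfg$stats$nPerm, q = cfg$stats$q,
                           seed = seed + 3L)
  # phenotype ANOVA on adjusted multiplex kappa (phenotypes with >= 2 pts)
  phen <- rec$phenotype[ms]
  zms <- adjKappa$multiplex[ms]
  keepPh <- phen %in% names(which(table(phen) >= 2))
  anova <- if (length(unique(phen[keepPh])) >= 2)
    anovaTukey(zms[keepPh], phen[keepPh]) else NULL
  # clinical dichotomies on adjusted multiplex kappa, patients only
  dich <- list()
  for (task in c("disability", "ips")) {
    lab <- suppressMessages(dichotomizeClinical(rec[ms, ], task))
    ok <- !is.na(lab)
    if (length(unique(lab[ok])) == 2 && all(table(lab[ok]) >= 2)) {
      z1 <- zms[ok][lab[ok] == levels(lab)[1]]
      z2 <- zms[ok][lab[ok] == levels(lab)[2]]
      tt <- permutationTtest(z1, z2, nPerm = cfg$stats$nPerm,
                             seed = seed + 4L)
      gg <- hedgesG(z1, z2, nBoot = cfg$stats$nBoot, seed = seed + 5L)
      dich[[task]] <- list(levels = levels(lab), statistic = tt$statistic,
                           p = tt$p, hedgesG = gg$g, ciLow = gg$ciLow,
                           ciHigh = gg$ciHigh,
                           n = as.vector(table(lab[ok])),
                           nExcluded = attr(lab, "nExcluded"))
    }
  }
  list(global = global, groupKappaMultiplex = grpKappa@kappa,
       nodal = nodal, anovaPhenotype = anova, dichotomies = dich,
       adjustedKappa = adjKappa)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) - build - harmonize - coreness - kappa -
#' statistics - prediction in order, each stochastic stage consuming a
#' seed derived from the configuration seed. See [defaultConfig()] for
#' the configuration schema; an invalid key is a hard error listing the
#' valid keys.
#'
#' @param config nested list overriding [defaultConfig()] entries.
#' @param outDir optional output directory; when given, the coreness and
#'   kappa tables and a JSON statistics/prediction report are written via
#'   [writeResults()].
#' @return list with the cohort (and simulation `truth` when simulated),
#'   per-domain coreness matrices, `kappaTable`, `stats`, `predictions`,
#'   the resolved `config` and, if written, output `paths`.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  cfg <- .mergeConfig(config)
  seed <- as.integer(cfg$seed)
  truth <- NULL
  if (!is.null(cfg$input$cohortPath)) {
    .logStage(cfg, "reading cohort from %s", cfg$input$cohortPath)
    cohort <- readCohort(cfg$input$cohortPath, cfg$input$volumesPath,
                         cfg$input$matrixDir, cfg$input$parcellationPath)
  } else {
    s <- cfg$simulate
    .logStage(cfg, "simulating cohort: %d HC + %d MS, %d nodes, %d core, %d site(s), seed %d",
              s$nHC, s$nMS, s$nNodes, s$nCore, s$siteCount, seed)
    sim <- simulateCohort(s$nHC, s$nMS, s$nNodes, s$nCore, s$phenotypeMix,
                          s$siteCount, s$params, seed = seed)
    cohort <- sim$cohort
    truth <- sim$truth
  }
  rec <- cohort@records
  built <- buildMultiplexes(cohort, harmonize = cfg$harmonize$enabled,
                            useEB = cfg$harmonize$useEB,
                            verbose = !identical(cfg$logLevel, "quiet"))
  grid <- densityGrid(cfg$grid$from, cfg$grid$to, cfg$grid$by)
  .logStage(cfg, "coreness sweep: %d densities, coefficients %s",
            length(grid), paste(cfg$coefficients, collapse = "/"))
  cores <- cohortCoreness(built$multiplex, grid, cfg$coefficients)
  hc <- rec$group == "HC"
  kap <- cohortKappa(cores, hc)

  keep <- rep(TRUE, nrow(rec))
  if (!is.null(cfg$subset$bpfZMin)) {
    bz <- adjustConfounders(rec$bpf,
                            data.frame(age = rec$age,
                                       sex = as.numeric(rec$sex == "M")),
                            hc)$z
    keep <- !is.na(rec$bpf) & bz > cfg$subset$bpfZMin
    .logStage(cfg, "subset filter bpf_z > %.2f: %d of %d subjects retained",
              cfg$subset$bpfZMin, sum(keep), length(keep))
  }
  recS <- rec[keep, , drop = FALSE]
  coresS <- lapply(cores, function(m) m[keep, , drop = FALSE])
  kapS <- kap$kappaTable[keep, , drop = FALSE]

  .logStage(cfg, "statistics: nPerm %d, nBoot %d, q %.3g",
            cfg$stats$nPerm, cfg$stats$nBoot, cfg$stats$q)
  stats <- .statsStage(recS, coresS, kapS, cfg, seed + 1000L)

  predictions <- list()
  if (isTRUE(cfg$predict$enabled)) {
    for (task in cfg$predict$tasks) {
      .logStage(cfg, "prediction task: %s", task)
      predictions[[task]] <- tryCatch(
        suppressMessages(runPredictionTask(
          kapS, recS, task, searchBudget = cfg$predict$searchBudget,
          nRepeats = cfg$predict$nRepeats, seed = seed + 2000L)),
        error = function(e) list(task = task, error = conditionMessage(e)))
    }
  }

  out <- list(cohort = cohort, truth = truth, coreness = cores,
              kappaTable = kap$kappaTable, references = kap$references,
              subsetKept = keep, stats = stats, predictions = predictions,
              volumeZ = built$volumeZ,
              harmonizationModels = built$harmonizationModels,
              config = cfg)
  if (!is.null(outDir)) {
    statsReport <- stats[c("global", "groupKappaMultiplex",
                           "anovaPhenotype", "dichotomies")]
    statsReport$nodal <- stats$nodal
    out$paths <- writeResults(outDir, cores$multiplex, kap$kappaTable,
                              statsReport, predictions)
    if (!is.null(truth)) {
      tj <- file.path(outDir, "truth.json")
      jsonlite::write_json(list(coreNodes = truth@coreNodes,
                                attackStrength = truth@attackStrength,
                                affinity = truth@affinity,
                                weightMeans = truth@weightMeans),
                           tj, auto_unbox = TRUE, digits = NA)
      out$paths$truth <- tj
    }
  }
  out
}
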