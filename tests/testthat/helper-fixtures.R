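# fixtures and independent oracles used across test files

starLayerMatrix <- function() {
  w <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  w["A", "B"] <- w["B", "A"] <- 3
  w["A", "C"] <- w["C", "A"] <- 2
  w["A", "D"] <- w["D", "A"] <- 1
  w
}

randomSymMatrix <- function(n, labels = NULL) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2)
  w <- w + t(w)
  if (is.null(labels)) labels <- sprintf("node%03d", seq_len(n))
  dimnames(w) <- list(labels, labels)
  w
}

# Independent rich-core oracle: plain double loops straight from the
# definition - richness, ranking (ties by ascending index), mu-plus at
# every rank, boundary at the first maximal mu-plus. Returns the mu-plus
# value at every rank position so tests can verify the boundary choice
# exhaustively.
oracleRichCore <- function(mats, coeffs) {
  n <- nrow(mats[[1]])
  mu <- numeric(n)
  for (i in seq_len(n))
    for (a in seq_along(mats))
      mu[i] <- mu[i] + coeffs[a] * sum(mats[[a]][i, ])
  ord <- order(-mu, seq_len(n))
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  muPlus <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (rank[j] < rank[i])
        for (a in seq_along(mats))
          muPlus[i] <- muPlus[i] + coeffs[a] * mats[[a]][i, j]
  muPlusByRank <- muPlus[ord]
  if (all(muPlusByRank == 0))
    return(list(core = integer(0), muPlusByRank = muPlusByRank))
  rstar <- which.max(muPlusByRank)
  list(core = ord[seq_len(rstar)], muPlusByRank = muPlusByRank)
}

# small deterministic cohort for I/O round trips
tinyCohort <- function(seed = 11) {
  simulateCohort(nHC = 3, nMS = 2, nNodes = 8, nCore = 3,
                 phenotypeMix = c(CIS = 0.25, RRMS = 0.25, SPMS = 0.25,
                                  PPMS = 0.25),
                 siteCount = 1, seed = seed)
}

# shared (memoized) synthetic cohort with planted multimodal disruption,
# processed through build/coreness/kappa once for the prediction tests
.fixtureCache <- new.env(parent = emptyenv())

disruptedCohortKappa <- function() {
  if (!is.null(.fixtureCache$kap)) return(.fixtureCache$kap)
  sim <- simulateCohort(nHC = 40, nMS = 80, nNodes = 60, nCore = 12,
                        siteCount = 1, seed = 202,
                        params = list(deltaByPhenotype = c(CIS = 0.25,
                                                           RRMS = 0.4,
                                                           SPMS = 0.6,
                                                           PPMS = 0.5)))
  built <- buildMultiplexes(sim$cohort, harmonize = FALSE)
  cores <- cohortCoreness(built$multiplex, densityGrid(0.02, 1, 0.02))
  hc <- sim$cohort@records$group == "HC"
  kap <- cohortKappa(cores, hc)
  out <- list(records = sim$cohort@records, kappaTable = kap$kappaTable,
              coreness = cores, truth = sim$truth)
  .fixtureCache$kap <- out
  out
}
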