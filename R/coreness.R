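#' Density grid for the threshold sweep
#'
#' @param from,to,by grid limits and step; densities must lie in (0, 1].
#' @return strictly increasing numeric vector of densities. The default
#'   covers the full density range, 0.01 to 1.00 in steps of 0.01
#'   (100 thresholds).
#' @export
densityGrid <- function(from = 0.01, to = 1, by = 0.01) {
  g <- round(seq(from, to, by = by), 10)
  .checkGrid(g)
  g
}

.checkGrid <- function(g) {
  if (length(g) == 0L) stop("density grid must be nonempty")
  if (any(g <= 0 | g > 1)) stop("densities must lie in (0, 1]")
  if (is.unsorted(g, strictly = TRUE)) stop("densities must be strictly increasing")
  invisible(g)
}

# upper-triangle edge list sorted for proportional thresholding:
# descending weight, ties broken by ascending (i, j) node-index order
.sortedEdges <- function(w) {
  N <- nrow(w)
  ut <- which(upper.tri(w))
  j <- ((ut - 1L) %/% N) + 1L
  i <- ut - (j - 1L) * N
  wv <- w[ut]
  o <- order(-wv, i, j)
  list(i = i[o], j = j[o], w = wv[o], N = N)
}

# grouped sum of w by integer index into a length-N vector
.accumN <- function(N, idx, w) {
  out <- numeric(N)
  if (length(idx)) {
    rs <- rowsum(w, idx)
    out[as.integer(rownames(rs))] <- rs[, 1L]
  }
  out
}

#' Proportionally threshold a layer
#'
#' Keeps the `m = round(density * N(N-1)/2)` largest-weight edges (weights
#' are retained, not binarized) and zeroes the rest. Ties at the cutoff are
#' broken deterministically by ascending `(i, j)` lexicographic node-index
#' order.
#'
#' @param layer a [ConnectivityLayer-class] or square symmetric matrix.
#' @param density edge density to retain, in (0, 1].
#' @return object of the same type as `layer` with only the retained edges.
#' @export
thresholdLayer <- function(layer, density) {
  if (length(density) != 1L || !is.finite(density) || density <= 0 || density > 1)
    stop("density must be a single value in (0, 1]")
  w <- if (is(layer, "ConnectivityLayer")) layer@weights else as.matrix(layer)
  e <- .sortedEdges(w)
  m <- as.integer(round(density * length(e$w)))
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  if (m > 0L) {
    keep <- seq_len(m)
    out[cbind(e$i[keep], e$j[keep])] <- e$w[keep]
    out[cbind(e$j[keep], e$i[keep])] <- e$w[keep]
  }
  if (is(layer, "ConnectivityLayer"))
    ConnectivityLayer(layer@kind, out, rownames(w))
  else out
}

# normalize the x argument of richness/core/coreness functions to a list of
# weight matrices plus default coefficients and a domain tag
.asLayerMats <- function(x) {
  if (is(x, "MultiplexNetwork"))
    list(mats = lapply(x@layers, function(l) l@weights),
         coeffs = c(0.5, 0.5, 0.5), domain = "multiplex")
  else if (is(x, "ConnectivityLayer"))
    list(mats = list(x@weights), coeffs = 1, domain = x@kind)
  else if (is.list(x))
    list(mats = lapply(x, as.matrix), coeffs = rep(1, length(x)),
         domain = "multiplex")
  else
    list(mats = list(as.matrix(x)), coeffs = 1, domain = "multiplex")
}

.checkCoeffs <- function(coeffs, nlayers) {
  if (length(coeffs) != nlayers)
    stop(sprintf("coefficient count (%d) must equal layer count (%d)",
                 length(coeffs), nlayers))
  if (any(coeffs < 0) || all(coeffs == 0))
    stop("coefficients must be nonnegative with at least one positive")
  invisible(coeffs)
}

#' Multiplex richness
#'
#' Node richness in the multiplex setting: `mu_i = sum_a c_a * s_i^a`,
#' where `s_i^a` is the strength of node i in (filtered) layer a and `c_a`
#' the per-layer coefficient. `muPlus_i` restricts each strength to the
#' neighbours ranked above i in the given ranking.
#'
#' @param x a [MultiplexNetwork-class], [ConnectivityLayer-class], or list
#'   of (filtered) weight matrices.
#' @param coefficients per-layer nonnegative coefficients; defaults to 0.5
#'   for each multiplex layer and 1 for a single layer.
#' @param ranking strict total order of the nodes as a permutation of node
#'   indices (richest first); defaults to descending `mu` with ties broken
#'   by ascending node index.
#' @return list with named numeric vectors `mu` and `muPlus`
#'   (`muPlus <= mu` elementwise) and the `ranking` used.
#' @export
multiplexRichness <- function(x, coefficients = NULL, ranking = NULL) {
  lx <- .asLayerMats(x)
  mats <- lx$mats
  if (is.null(coefficients)) coefficients <- lx$coeffs
  .checkCoeffs(coefficients, length(mats))
  N <- nrow(mats[[1]])
  labs <- rownames(mats[[1]])
  if (is.null(labs)) labs <- defaultNodeLabels(N)
  S <- vapply(mats, rowSums, numeric(N))
  mu <- as.vector(S %*% coefficients)
  if (is.null(ranking)) ranking <- order(-mu, seq_len(N))
  if (!identical(sort(as.integer(ranking)), seq_len(N)))
    stop("ranking must be a permutation of the node indices")
  r <- integer(N)
  r[ranking] <- seq_len(N)
  above <- outer(r, r, function(ri, rj) rj < ri) # above[i,j]: j ranked above i
  muPlus <- numeric(N)
  for (a in seq_along(mats))
    muPlus <- muPlus + coefficients[a] * rowSums(mats[[a]] * above)
  list(mu = stats::setNames(mu, labs),
       muPlus = stats::setNames(muPlus, labs),
       ranking = as.integer(ranking))
}

#' Rich-core decomposition
#'
#' Ranks nodes by multiplex richness `mu` (descending, ties by ascending
#' node index), computes the richer-neighbour strength `muPlus` under that
#' ranking, and places the core boundary at the rank position where
#' `muPlus` is maximal (ties resolved to the smallest rank, i.e. the
#' smallest core). The core is the set of nodes at ranks 1..r*. An empty
#' graph (all `muPlus` zero) yields an empty core.
#'
#' @inheritParams multiplexRichness
#' @return character vector of core node labels (possibly empty).
#' @export
richCore <- function(x, coefficients = NULL) {
  lx <- .asLayerMats(x)
  if (is.null(coefficients)) coefficients <- lx$coeffs
  rich <- multiplexRichness(lx$mats, coefficients)
  ordn <- rich$ranking
  mpr <- rich$muPlus[ordn]
  if (all(mpr == 0)) return(character(0))
  rstar <- which.max(mpr)
  names(rich$mu)[ordn[seq_len(rstar)]]
}

#' Coreness over a density-threshold sweep
#'
#' For every density in the grid, each layer is filtered independently by
#' proportional thresholding ([thresholdLayer()]), the rich core of the
#' filtered (multiplex) network is extracted, and core membership is
#' recorded. Coreness is the membership count divided by the number of
#' explored thresholds, so values are exact multiples of `1/length(grid)`.
#'
#' @param x a [MultiplexNetwork-class] (multiplex coreness) or a single
#'   [ConnectivityLayer-class] (single-layer coreness with unit
#'   coefficient).
#' @param grid density grid, see [densityGrid()].
#' @param coefficients per-layer richness coefficients; defaults to
#'   `c(0.5, 0.5, 0.5)` for a multiplex and 1 for a single layer.
#' @return a [CorenessProfile-class].
#' @export
coreness <- function(x, grid = densityGrid(), coefficients = NULL) {
  .checkGrid(grid)
  lx <- .asLayerMats(x)
  if (is.null(coefficients)) coefficients <- lx$coeffs
  .checkCoeffs(coefficients, length(lx$mats))
  labs <- rownames(lx$mats[[1]])
  if (is.null(labs)) labs <- defaultNodeLabels(nrow(lx$mats[[1]]))
  cv <- .corenessSweep(lx$mats, grid, coefficients)
  new("CorenessProfile", coreness = stats::setNames(cv, labs),
      grid = as.numeric(grid), coefficients = as.numeric(coefficients),
      domain = lx$domain)
}

# The sweep exploits that for an ascending density grid the retained edge
# sets are nested prefixes of each layer's sorted edge list, so strengths
# are updated incrementally; the ranking and boundary are recomputed per
# density because they are not monotone in the prefix.
.corenessSweep <- function(mats, grid, coeffs) {
  N <- nrow(mats[[1]])
  L <- length(mats)
  eds <- lapply(mats, .sortedEdges)
  E <- length(eds[[1]]$w)
  ms <- as.integer(round(grid * E))
  counts <- integer(N)
  S <- matrix(0, N, L)
  prevm <- 0L
  nodeIdx <- seq_len(N)
  for (d in seq_along(grid)) {
    m <- ms[d]
    if (m > prevm) {
      idx <- (prevm + 1L):m
      for (a in seq_len(L)) {
        e <- eds[[a]]
        S[, a] <- S[, a] +
          .accumN(N, c(e$i[idx], e$j[idx]), c(e$w[idx], e$w[idx]))
      }
      prevm <- m
    }
    mu <- as.vector(S %*% coeffs)
    ordn <- order(-mu, nodeIdx)
    r <- integer(N)
    r[ordn] <- nodeIdx
    mp <- numeric(N)
    if (m > 0L) {
      pre <- seq_len(m)
      for (a in seq_len(L)) {
        e <- eds[[a]]
        ii <- e$i[pre]; jj <- e$j[pre]; ww <- e$w[pre]
        lower <- jj
        swap <- r[ii] > r[jj]
        lower[swap] <- ii[swap]
        mp <- mp + coeffs[a] * .accumN(N, lower, ww)
      }
    }
    mpr <- mp[ordn]
    if (any(mpr > 0)) {
      rstar <- which.max(mpr)
      core <- ordn[seq_len(rstar)]
      counts[core] <- counts[core] + 1L
    }
  }
  counts / length(grid)
}

#' Coreness disruption index
#'
#' Ordinary-least-squares slope (with intercept) of the per-node coreness
#' difference `delta = subject - reference` regressed on the reference
#' coreness. A subject identical to the reference yields kappa = 0; a
#' subject with all-zero coreness yields kappa = -1. Negative kappa means
#' that nodes with high reference coreness lose disproportionately more
#' coreness - the targeted-attack signature.
#'
#' @param subject per-node coreness of the subject (numeric vector or
#'   [CorenessProfile-class]).
#' @param reference per-node reference coreness, typically the HC group
#'   mean (numeric vector or [CorenessProfile-class]); must not be
#'   constant.
#' @return a [KappaResult-class].
#' @export
disruptionIndex <- function(subject, reference) {
  s <- if (is(subject, "CorenessProfile")) subject@coreness else as.numeric(subject)
  r <- if (is(reference, "CorenessProfile")) reference@coreness else as.numeric(reference)
  if (length(s) != length(r))
    stop("subject and reference coreness must have equal length")
  rc <- r - mean(r)
  sxx <- sum(rc^2)
  if (sxx == 0)
    stop("reference coreness is constant: the disruption slope is undefined")
  d <- s - r
  slope <- sum(rc * d) / sxx
  intercept <- mean(d) - slope * mean(r)
  res <- d - (intercept + slope * r)
  sst <- sum((d - mean(d))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  new("KappaResult", kappa = slope, intercept = intercept, rSquared = r2,
      delta = stats::setNames(d, names(r)), reference = r)
}

#' Group-level coreness disruption index
#'
#' Applies [disruptionIndex()] to the column-wise mean of a group's
#' coreness profiles, mirroring the group-average construction of the
#' disruption scatterplot. A group that is the HC reference sample itself
#' yields kappa = 0 exactly.
#'
#' @param groupCoreness subjects x nodes matrix of coreness profiles (one
#'   row per subject).
#' @param reference per-node reference coreness.
#' @return a [KappaResult-class].
#' @export
groupDisruptionIndex <- function(groupCoreness, reference) {
  groupCoreness <- as.matrix(groupCoreness)
  if (nrow(groupCoreness) < 1L) stop("need at least one subject row")
  disruptionIndex(colMeans(groupCoreness), reference)
}
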