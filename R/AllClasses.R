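#' @import methods
NULL

LAYER_KINDS <- c("MC", "SC", "FC")
GROUP_LEVELS <- c("HC", "MS")
PHENOTYPE_LEVELS <- c("CIS", "RRMS", "SPMS", "PPMS")
SEX_LEVELS <- c("F", "M")

.checkSquareSym <- function(w, tol = 1e-8, what = "weights") {
  if (!is.matrix(w) || !is.numeric(w))
    return(sprintf("%s must be a numeric matrix", what))
  if (nrow(w) != ncol(w))
    return(sprintf("%s must be square (got %d x %d)", what, nrow(w), ncol(w)))
  if (any(!is.finite(w)))
    return(sprintf("%s contains non-finite values", what))
  if (max(abs(w - t(w))) > tol)
    return(sprintf("%s is not symmetric (max asymmetry %.3g)", what,
                   max(abs(w - t(w)))))
  if (any(abs(diag(w)) > 1e-12))
    return(sprintf("%s must have a zero diagonal", what))
  NULL
}

#' Single-modality connectivity layer
#'
#' A weighted, undirected brain network for one connectivity modality:
#' morphological covariance (`MC`), structural connectivity (`SC`) or
#' functional connectivity (`FC`). Weights are square, symmetric,
#' nonnegative, with a zero diagonal; node identity is carried by the
#' dimnames of the weight matrix.
#'
#' @slot kind one of `"MC"`, `"SC"`, `"FC"`.
#' @slot weights square symmetric numeric matrix with node labels as
#'   dimnames.
#'
#' @seealso [buildMCLayer()], [transformSC()], [transformFC()],
#'   [svdNormalize()]
#' @export
setClass("ConnectivityLayer",
         representation(kind = "character", weights = "matrix"))

setValidity("ConnectivityLayer", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% LAYER_KINDS)
    msgs <- c(msgs, sprintf("kind must be one of %s",
                            paste(LAYER_KINDS, collapse = ", ")))
  w <- object@weights
  m <- .checkSquareSym(w)
  if (!is.null(m)) msgs <- c(msgs, m)
  if (is.null(rownames(w)) || is.null(colnames(w)))
    msgs <- c(msgs, "weights must carry node labels as dimnames")
  else if (!identical(rownames(w), colnames(w)))
    msgs <- c(msgs, "row and column node labels differ")
  else if (anyDuplicated(rownames(w)))
    msgs <- c(msgs, "node labels must be unique")
  if (length(msgs) == 0L) {
    if (min(w) < -1e-12)
      msgs <- c(msgs, "weights must be nonnegative")
    if (identical(object@kind, "MC") && max(w) > 1 + 1e-9)
      msgs <- c(msgs, "MC weights must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConnectivityLayer
#'
#' @param kind layer modality, one of `"MC"`, `"SC"`, `"FC"`.
#' @param weights square symmetric nonnegative matrix; the diagonal is
#'   forced to zero.
#' @param nodeLabels optional node labels; defaults to the dimnames of
#'   `weights` or `node001`, `node002`, ...
#' @return a [ConnectivityLayer-class] object.
#' @export
ConnectivityLayer <- function(kind, weights, nodeLabels = NULL) {
  weights <- as.matrix(weights)
  if (is.null(nodeLabels)) {
    nodeLabels <- rownames(weights)
    if (is.null(nodeLabels))
      nodeLabels <- defaultNodeLabels(nrow(weights))
  }
  dimnames(weights) <- list(nodeLabels, nodeLabels)
  diag(weights) <- 0
  new("ConnectivityLayer", kind = kind, weights = weights)
}

#' Default node labels
#'
#' @param n number of nodes.
#' @return character vector `node001`, `node002`, ...
#' @keywords internal
defaultNodeLabels <- function(n) sprintf("node%03d", seq_len(n))

#' Multimodal multiplex network
#'
#' Three node-aligned connectivity layers (MC, SC, FC) sharing one node set
#' with a one-to-one correspondence between nodes at different layers and no
#' interlayer edges.
#'
#' @slot layers list of three [ConnectivityLayer-class] objects in the fixed
#'   order MC, SC, FC, with identical node labels.
#'
#' @seealso [assembleMultiplex()], [coreness()]
#' @export
setClass("MultiplexNetwork", representation(layers = "list"))

setValidity("MultiplexNetwork", function(object) {
  ls <- object@layers
  if (length(ls) != 3L)
    return("a multiplex must hold exactly three layers (MC, SC, FC)")
  if (!all(vapply(ls, is, logical(1), "ConnectivityLayer")))
    return("all layers must be ConnectivityLayer objects")
  kinds <- unname(vapply(ls, function(l) l@kind, character(1)))
  if (!identical(kinds, LAYER_KINDS))
    return(sprintf("layer order must be MC, SC, FC (got %s)",
                   paste(kinds, collapse = ", ")))
  labs <- rownames(ls[[1]]@weights)
  for (l in ls[-1]) {
    other <- rownames(l@weights)
    if (!identical(labs, other)) {
      d <- which(labs != other)[1]
      if (is.na(d)) d <- min(length(labs), length(other)) + 1L
      return(sprintf("node labels differ across layers (first mismatch at position %d)", d))
    }
  }
  TRUE
})

#' Per-node coreness over a density sweep
#'
#' Coreness of a node is the fraction of density thresholds at which the
#' node belongs to the detected rich core; values are exact multiples of
#' 1/(number of densities) and lie in \[0, 1\].
#'
#' @slot coreness named numeric vector of per-node coreness.
#' @slot grid the density grid used.
#' @slot coefficients the per-layer richness coefficients used.
#' @slot domain `"multiplex"` or one of `"MC"`, `"SC"`, `"FC"`.
#'
#' @seealso [coreness()], [disruptionIndex()]
#' @export
setClass("CorenessProfile",
         representation(coreness = "numeric", grid = "numeric",
                        coefficients = "numeric", domain = "character"))

setValidity("CorenessProfile", function(object) {
  v <- object@coreness
  if (is.null(names(v))) return("coreness must be named by node label")
  if (any(v < -1e-12 | v > 1 + 1e-12)) return("coreness must lie in [0, 1]")
  ng <- length(object@grid)
  if (ng < 1L) return("density grid must be nonempty")
  if (max(abs(v * ng - round(v * ng))) > 1e-9)
    return("coreness values must be exact multiples of 1/length(grid)")
  if (!object@domain %in% c("multiplex", LAYER_KINDS))
    return("domain must be 'multiplex', 'MC', 'SC' or 'FC'")
  TRUE
})

#' Coreness disruption index
#'
#' The coreness disruption index (kappa) is the ordinary-least-squares slope
#' of the per-node coreness difference (subject minus healthy-control
#' reference) regressed, with intercept, on the reference coreness.
#' Negative values indicate that high-coreness hubs lose coreness
#' disproportionately - the signature of a targeted attack.
#'
#' @slot kappa regression slope (the disruption index).
#' @slot intercept regression intercept.
#' @slot rSquared coefficient of determination of the fit.
#' @slot delta per-node coreness difference (subject - reference).
#' @slot reference per-node reference (HC mean) coreness.
#'
#' @seealso [disruptionIndex()], [groupDisruptionIndex()]
#' @export
setClass("KappaResult",
         representation(kappa = "numeric", intercept = "numeric",
                        rSquared = "numeric", delta = "numeric",
                        reference = "numeric"))

setValidity("KappaResult", function(object) {
  if (length(object@delta) != length(object@reference))
    return("delta and reference must have equal length")
  TRUE
})

#' Cohort container
#'
#' Holds the subject table, regional gray-matter volumes and the per-subject
#' raw structural and functional connectivity matrices over a shared
#' parcellation.
#'
#' @slot records data.frame with one row per subject: `subject_id`, `group`
#'   (HC/MS), `phenotype` (CIS/RRMS/SPMS/PPMS or NA), `site`, `age`, `sex`
#'   (F/M), `tiv`, `edss`, `sdmt_z`, `bpf`, `tlv`.
#' @slot volumes subjects x nodes matrix of regional volumes (ml).
#' @slot sc named list (by subject id) of raw structural connectivity
#'   matrices.
#' @slot fc named list of raw functional connectivity (correlation)
#'   matrices.
#' @slot parcellation data.frame with columns `label` and `system`.
#'
#' @seealso [readCohort()], [simulateCohort()]
#' @export
setClass("CohortData",
         representation(records = "data.frame", volumes = "matrix",
                        sc = "list", fc = "list",
                        parcellation = "data.frame"))

setValidity("CohortData", function(object) {
  rec <- object@records
  need <- c("subject_id", "group", "phenotype", "site", "age", "sex",
            "tiv", "edss", "sdmt_z", "bpf", "tlv")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(sprintf("records lacks columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$subject_id))
    return("subject_id must be unique within a cohort")
  if (!all(rec$group %in% GROUP_LEVELS))
    return(sprintf("unknown group value at row %d",
                   which(!rec$group %in% GROUP_LEVELS)[1]))
  bad <- !(is.na(rec$phenotype) | rec$phenotype %in% PHENOTYPE_LEVELS)
  if (any(bad))
    return(sprintf("unknown phenotype value at row %d", which(bad)[1]))
  if (!all(rec$sex %in% SEX_LEVELS))
    return(sprintf("unknown sex value at row %d",
                   which(!rec$sex %in% SEX_LEVELS)[1]))
  e <- rec$edss[!is.na(rec$edss)]
  if (length(e) && (any(e < 0 | e > 10) || any(abs(e * 2 - round(e * 2)) > 1e-9)))
    return("edss must lie in [0, 10] in steps of 0.5")
  b <- rec$bpf[!is.na(rec$bpf)]
  if (length(b) && any(b <= 0 | b >= 1)) return("bpf must lie in (0, 1)")
  tl <- rec$tlv[!is.na(rec$tlv)]
  if (length(tl) && any(tl < 0)) return("tlv must be nonnegative")
  hc <- rec$group == "HC"
  if (any(hc & !is.na(rec$phenotype)))
    return("HC records must have missing phenotype")
  n <- nrow(object@parcellation)
  if (!all(c("label", "system") %in% names(object@parcellation)))
    return("parcellation needs columns 'label' and 'system'")
  if (anyDuplicated(object@parcellation$label))
    return("parcellation labels must be unique")
  if (ncol(object@volumes) != n)
    return("volumes column count must equal the parcellation size")
  if (nrow(object@volumes) != nrow(rec))
    return("volumes row count must equal the number of subjects")
  for (nm in c("sc", "fc")) {
    ml <- slot(object, nm)
    if (!identical(sort(names(ml)), sort(rec$subject_id)))
      return(sprintf("%s matrices must be named by the cohort's subject ids", nm))
    for (id in names(ml)) {
      m <- .checkSquareSym(ml[[id]], what = sprintf("%s matrix of %s", nm, id))
      if (!is.null(m)) return(m)
      if (nrow(ml[[id]]) != n)
        return(sprintf("%s matrix of %s has side %d, expected %d",
                       nm, id, nrow(ml[[id]]), n))
    }
  }
  TRUE
})

#' Ground truth of a simulated cohort
#'
#' Records everything the generator planted so that recovery can be tested:
#' the core node set, per-subject attack strengths, per-node attack
#' affinities, site effects, covariate slopes and block mean edge weights.
#'
#' @slot coreNodes labels of the planted core nodes.
#' @slot attackStrength named per-subject attack strength delta in \[0, 1\]
#'   (0 for every HC).
#' @slot affinity named per-node attack affinity in \[0, 1\] (0 off-core).
#' @slot siteOffsets list of per-site location/scale effects.
#' @slot covariateSlopes named numeric: age/sex/TIV effects on volumes.
#' @slot weightMeans named numeric `(cc, cp, pp)` block mean edge weights.
#'
#' @seealso [simulateCohort()]
#' @export
setClass("SyntheticTruth",
         representation(coreNodes = "character", attackStrength = "numeric",
                        affinity = "numeric", siteOffsets = "list",
                        covariateSlopes = "numeric", weightMeans = "numeric"))

setValidity("SyntheticTruth", function(object) {
  w <- object@weightMeans
  if (!all(c("cc", "cp", "pp") %in% names(w)))
    return("weightMeans must be named cc, cp, pp")
  if (!(w["cc"] > w["cp"] && w["cp"] > w["pp"] && w["pp"] > 0))
    return("weightMeans must satisfy cc > cp > pp > 0")
  d <- object@attackStrength
  if (length(d) && (min(d) < 0 || max(d) > 1))
    return("attackStrength must lie in [0, 1]")
  a <- object@affinity
  if (length(a) && (min(a) < 0 || max(a) > 1))
    return("affinity must lie in [0, 1]")
  TRUE
})
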