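#' Node labels of a network object
#'
#' @param x a [ConnectivityLayer-class], [MultiplexNetwork-class],
#'   [CorenessProfile-class] or [CohortData-class] object.
#' @return character vector of node labels in the fixed shared order.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "ConnectivityLayer", function(x) rownames(x@weights))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "MultiplexNetwork",
          function(x) rownames(x@layers[[1]]@weights))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "CorenessProfile", function(x) names(x@coreness))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "CohortData", function(x) x@parcellation$label)

#' Weight matrix of a layer
#'
#' @param x a [ConnectivityLayer-class] or [MultiplexNetwork-class].
#' @param kind for a multiplex, which layer to extract (`"MC"`, `"SC"`,
#'   `"FC"`).
#' @return numeric weight matrix with node labels as dimnames.
#' @export
setGeneric("layerWeights", function(x, kind) standardGeneric("layerWeights"))

#' @rdname layerWeights
#' @export
setMethod("layerWeights", "ConnectivityLayer",
          function(x, kind) x@weights)

#' @rdname layerWeights
#' @export
setMethod("layerWeights", "MultiplexNetwork", function(x, kind) {
  kind <- match.arg(kind, LAYER_KINDS)
  x@layers[[match(kind, LAYER_KINDS)]]@weights
})

#' Modality of a layer
#' @param x a [ConnectivityLayer-class].
#' @return `"MC"`, `"SC"` or `"FC"`.
#' @export
setGeneric("layerKind", function(x) standardGeneric("layerKind"))

#' @rdname layerKind
#' @export
setMethod("layerKind", "ConnectivityLayer", function(x) x@kind)

#' Layers of a multiplex
#' @param x a [MultiplexNetwork-class].
#' @return named list of [ConnectivityLayer-class] objects (MC, SC, FC).
#' @export
setGeneric("multiplexLayers", function(x) standardGeneric("multiplexLayers"))

#' @rdname multiplexLayers
#' @export
setMethod("multiplexLayers", "MultiplexNetwork",
          function(x) stats::setNames(x@layers, LAYER_KINDS))

#' Coreness values
#' @param x a [CorenessProfile-class].
#' @return named numeric vector of per-node coreness in \[0, 1\].
#' @export
setGeneric("corenessValues", function(x) standardGeneric("corenessValues"))

#' @rdname corenessValues
#' @export
setMethod("corenessValues", "CorenessProfile", function(x) x@coreness)

#' Coreness disruption index value
#' @param x a [KappaResult-class].
#' @return the regression slope kappa.
#' @export
setGeneric("kappaValue", function(x) standardGeneric("kappaValue"))

#' @rdname kappaValue
#' @export
setMethod("kappaValue", "KappaResult", function(x) x@kappa)

#' Subject table of a cohort
#' @param x a [CohortData-class].
#' @return data.frame with one row per subject.
#' @export
setGeneric("subjectRecords", function(x) standardGeneric("subjectRecords"))

#' @rdname subjectRecords
#' @export
setMethod("subjectRecords", "CohortData", function(x) x@records)

setMethod("show", "ConnectivityLayer", function(object) {
  w <- object@weights
  cat(sprintf("ConnectivityLayer [%s]: %d nodes, %d nonzero edges, weight range [%.4g, %.4g]\n",
              object@kind, nrow(w), sum(w[upper.tri(w)] > 0),
              min(w[upper.tri(w)]), max(w)))
})

setMethod("show", "MultiplexNetwork", function(object) {
  cat(sprintf("MultiplexNetwork: %d nodes x 3 layers (MC, SC, FC)\n",
              length(nodeLabels(object))))
})

setMethod("show", "CorenessProfile", function(object) {
  cat(sprintf("CorenessProfile [%s]: %d nodes, %d densities, mean coreness %.3f\n",
              object@domain, length(object@coreness), length(object@grid),
              mean(object@coreness)))
})

setMethod("show", "KappaResult", function(object) {
  cat(sprintf("KappaResult: kappa = %.4f (intercept %.4f, R^2 %.3f, %d nodes)\n",
              object@kappa, object@intercept, object@rSquared,
              length(object@reference)))
})

setMethod("show", "CohortData", function(object) {
  rec <- object@records
  cat(sprintf("CohortData: %d subjects (%d HC, %d MS), %d nodes, %d site(s)\n",
              nrow(rec), sum(rec$group == "HC"), sum(rec$group == "MS"),
              nrow(object@parcellation), length(unique(rec$site))))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d core nodes, %d subjects, mean attack %.3f\n",
              length(object@coreNodes), length(object@attackStrength),
              mean(object@attackStrength)))
})
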