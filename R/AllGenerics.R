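#' @rdname ConnectivityMatrix-class
#' @param object,x a package object.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname FusedMatrix-class
#' @export
setGeneric("gammaValue", function(x) standardGeneric("gammaValue"))

#' @rdname MergeTree-class
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' @rdname MergeTree-class
#' @export
setGeneric("leafIds", function(x) standardGeneric("leafIds"))

#' @rdname NodeLabeling-class
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname Partition-class
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @rdname CrossModularityGrid-class
#' @export
setGeneric("optimum", function(x) standardGeneric("optimum"))

#' @rdname DisorderGeneSets-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname DisorderGeneSets-class
#' @export
setGeneric("setGroups", function(x) standardGeneric("setGroups"))

setMethod("nodeIds", "ConnectivityMatrix", function(x) x@nodeIds)
setMethod("nodeIds", "NodeLabeling", function(x) x@nodeIds)
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)
setMethod("modality", "ConnectivityMatrix", function(x) x@modality)
setMethod("gammaValue", "FusedMatrix", function(x) x@gamma)
setMethod("nLeaves", "MergeTree", function(x) x@nLeaves)
setMethod("leafIds", "MergeTree", function(x) x@leafIds)
setMethod("nodeLabels", "NodeLabeling", function(x) x@labels)
setMethod("nModules", "Partition", function(x) x@nModules)
setMethod("optimum", "CrossModularityGrid", function(x) x@optimum)
setMethod("geneSets", "DisorderGeneSets", function(x) x@sets)
setMethod("setGroups", "DisorderGeneSets", function(x) x@groups)

setMethod("show", "ConnectivityMatrix", function(object) {
  v <- object@values
  nl <- if (length(object@nodeIds)) sum(v[upper.tri(v)] != 0) else 0L
  cat(sprintf("%s connectivity matrix: %d nodes, %d links, %s\n",
              object@modality, length(object@nodeIds), nl,
              if (object@weighted) "weighted" else "binary"))
})

setMethod("show", "FusedMatrix", function(object) {
  cat(sprintf("gamma-fused structure-function matrix: %d nodes, gamma = %g\n",
              length(object@nodeIds), object@gamma))
})

setMethod("show", "PopulationPair", function(object) {
  cat(sprintf(paste0("population SC/FC pair: %d nodes, %d links ",
                     "(density %.4f, %d threshold ties kept)\n"),
              length(object@scBin@nodeIds), object@nLinks,
              object@density, object@tieCount))
})

setMethod("show", "MergeTree", function(object) {
  cat(sprintf("WPGMA merge tree: %d leaves, %d merges, heights [%.4g, %.4g]\n",
              object@nLeaves, nrow(object@merge),
              min(object@height), max(object@height)))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("partition: %d nodes in %d modules\n",
              length(object@nodeIds), object@nModules))
})

setMethod("show", "NodeLabeling", function(object) {
  cat(sprintf("node labeling: %d nodes, %d distinct labels\n",
              length(object@nodeIds), length(unique(object@labels))))
})

setMethod("show", "CrossModularityGrid", function(object) {
  o <- object@optimum
  cat(sprintf(paste0("cross-modularity grid: %d gammas x %d module counts; ",
                     "optimum chi = %.4f at gamma = %g, M = %d ",
                     "(%d modules with >= %d nodes)\n"),
              length(object@gammas), length(object@moduleCounts),
              o$chi, o$gamma, o$m, o$nValidModules, object@minModuleSize))
})

setMethod("show", "ModuleExpression", function(object) {
  cat(sprintf("module-level expression: %d modules x %d genes\n",
              length(object@modules), length(object@genes)))
})

setMethod("show", "DisorderGeneSets", function(object) {
  cat(sprintf("disorder gene sets: %d sets (%d grouped), %d symbols total\n",
              length(object@sets), length(object@groups),
              sum(lengths(object@sets))))
})
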