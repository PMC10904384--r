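#' @import methods
NULL

#' Square connectivity matrix over an ordered node list
#'
#' Container for a symmetric region-by-region connectivity matrix, tagged by
#' modality. Structural matrices hold nonnegative streamline counts (or their
#' binarization), functional matrices hold Pearson correlations in [-1, 1],
#' and fused matrices hold convex combinations of binarized pairs. The
#' diagonal is always zero: self-connections are undefined for both
#' modalities.
#'
#' @slot nodeIds ordered character vector of unique node identifiers.
#' @slot values numeric N x N symmetric matrix with zero diagonal.
#' @slot modality one of \code{"structural"}, \code{"functional"},
#'   \code{"fused"}.
#' @slot weighted logical; \code{FALSE} once a matrix has been binarized.
#' @export
setClass("ConnectivityMatrix",
  representation(
    nodeIds  = "character",
    values   = "matrix",
    modality = "character",
    weighted = "logical"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  n <- length(object@nodeIds)
  if (anyDuplicated(object@nodeIds)) return("node ids must be unique")
  if (nrow(v) != n || ncol(v) != n) return("matrix dimension must equal the number of node ids")
  if (!object@modality %in% c("structural", "functional", "fused"))
    return("modality must be structural, functional or fused")
  if (n > 0) {
    if (max(abs(v - t(v))) > 1e-8) return("matrix is not symmetric within 1e-8")
    if (any(diag(v) != 0)) return("diagonal must be zero")
    if (object@modality == "structural" && any(v < 0))
      return("structural values must be nonnegative")
    if (object@modality == "functional" && (any(v < -1) || any(v > 1)))
      return("functional values must lie in [-1, 1]")
  }
  TRUE
})

#' Gamma-fused structure-function matrix
#'
#' A \linkS4class{ConnectivityMatrix} whose entries are
#' \code{gamma * FC + (1 - gamma) * SC} over a binarized, density-matched
#' population pair, so every off-diagonal entry is one of
#' \code{0, gamma, 1 - gamma, 1}.
#'
#' @slot gamma fusion parameter in [0, 1]; 0 is pure structure, 1 pure
#'   function.
#' @export
setClass("FusedMatrix",
  contains = "ConnectivityMatrix",
  representation(gamma = "numeric")
)

setValidity("FusedMatrix", function(object) {
  g <- object@gamma
  if (length(g) != 1 || is.na(g) || g < 0 || g > 1)
    return("gamma must be a single value in [0, 1]")
  TRUE
})

#' Binarized, density-matched population connectivity pair
#'
#' Holds the population structural and functional matrices (link-wise medians
#' across subjects), their binarizations, and bookkeeping about the density
#' matching: the structural matrix is binarized at > 0 and the functional
#' matrix keeps its K strongest positive links, K being the structural link
#' count (ties at the threshold are all kept).
#'
#' @slot scBin,fcBin binary \linkS4class{ConnectivityMatrix} objects sharing
#'   node ids.
#' @slot scRaw,fcRaw the population matrices the binarization came from.
#' @slot density fraction of possible links present in \code{scBin}.
#' @slot nLinks structural link count K.
#' @slot tieCount number of functional links kept beyond K because they tied
#'   with the K-th strongest value.
#' @export
setClass("PopulationPair",
  representation(
    scBin = "ConnectivityMatrix",
    fcBin = "ConnectivityMatrix",
    scRaw = "ConnectivityMatrix",
    fcRaw = "ConnectivityMatrix",
    density = "numeric",
    nLinks = "integer",
    tieCount = "integer"
  )
)

setValidity("PopulationPair", function(object) {
  if (!identical(object@scBin@nodeIds, object@fcBin@nodeIds))
    return("scBin and fcBin must share node ids")
  for (slotName in c("scBin", "fcBin")) {
    v <- slot(object, slotName)@values
    if (!all(v %in% c(0, 1))) return(sprintf("%s must be binary", slotName))
  }
  TRUE
})

#' Agglomerative merge tree over network nodes
#'
#' Dendrogram produced by weighted-average (WPGMA) agglomeration of a fused
#' connectivity matrix under correlation distance. Stored in the standard
#' merge-matrix convention: row k of \code{merge} lists the two clusters
#' joined at step k, negative entries denoting leaves and positive entries
#' earlier merge steps. Merge heights are non-decreasing, so cutting the tree
#' at successive module counts yields nested partitions.
#'
#' @slot nLeaves number of leaves (network nodes).
#' @slot merge integer (nLeaves - 1) x 2 merge matrix.
#' @slot height numeric merge distances, non-decreasing.
#' @slot order leaf ordering for plotting.
#' @slot leafIds node identifiers, in input order.
#' @slot method linkage used (always \code{"mcquitty"}, i.e. WPGMA).
#' @export
setClass("MergeTree",
  representation(
    nLeaves = "integer",
    merge   = "matrix",
    height  = "numeric",
    order   = "integer",
    leafIds = "character",
    method  = "character"
  )
)

setValidity("MergeTree", function(object) {
  n <- object@nLeaves
  if (length(object@leafIds) != n) return("leafIds length must equal nLeaves")
  if (nrow(object@merge) != n - 1) return("merge must have nLeaves - 1 rows")
  if (length(object@height) != n - 1) return("height must have nLeaves - 1 entries")
  if (is.unsorted(object@height + 1e-12)) return("merge heights must be non-decreasing")
  TRUE
})

#' Node labeling (atlas, macro-region or module assignment)
#'
#' One categorical label per node, used for macro-region grouping, atlas
#' overlap and module membership.
#'
#' @slot nodeIds ordered character node identifiers.
#' @slot labels one label per node.
#' @export
setClass("NodeLabeling",
  representation(nodeIds = "character", labels = "character")
)

setValidity("NodeLabeling", function(object) {
  if (length(object@labels) != length(object@nodeIds))
    return("labels and nodeIds must have equal length")
  if (anyDuplicated(object@nodeIds)) return("node ids must be unique")
  if (length(object@labels) > 0 && any(is.na(object@labels)))
    return("every node must carry a label")
  TRUE
})

#' Partition of nodes into modules at a tree cut
#'
#' A \linkS4class{NodeLabeling} whose labels are module assignments at a
#' given cut cardinality.
#'
#' @slot nModules number of distinct modules.
#' @export
setClass("Partition",
  contains = "NodeLabeling",
  representation(nModules = "integer")
)

setValidity("Partition", function(object) {
  m <- length(unique(object@labels))
  if (m != object@nModules)
    return(sprintf("label set has %d values but nModules is %d", m, object@nModules))
  TRUE
})

#' Cross-modularity surface over the (gamma, M) plane
#'
#' Tabulates functional modularity Q_F, structural modularity Q_S, module
#' similarity T_FS and their geometric mean chi for every fusion parameter
#' gamma and cut cardinality M searched, together with the located optimum.
#'
#' @slot gammas gamma grid searched.
#' @slot moduleCounts cut cardinalities searched.
#' @slot qf,qs,tfs,chi numeric matrices indexed (gamma, M).
#' @slot validModules integer matrix: modules with at least
#'   \code{minModuleSize} members at each (gamma, M).
#' @slot minModuleSize threshold below which a module is too small to carry
#'   community structure.
#' @slot optimum list with elements \code{gamma}, \code{m}, \code{chi},
#'   \code{nValidModules} and the optimal \code{partition}.
#' @export
setClass("CrossModularityGrid",
  representation(
    gammas = "numeric",
    moduleCounts = "integer",
    qf = "matrix", qs = "matrix", tfs = "matrix", chi = "matrix",
    validModules = "matrix",
    minModuleSize = "integer",
    optimum = "list"
  )
)

#' Module-level gene expression matrix
#'
#' Mean expression per (module, gene), aggregated from sample-level
#' measurements assigned to modules.
#'
#' @slot modules ordered module labels.
#' @slot genes ordered gene symbols.
#' @slot values modules x genes numeric matrix.
#' @slot nSamples samples contributing to each module row.
#' @export
setClass("ModuleExpression",
  representation(
    modules = "character",
    genes = "character",
    values = "matrix",
    nSamples = "integer"
  )
)

setValidity("ModuleExpression", function(object) {
  if (nrow(object@values) != length(object@modules)) return("row count must match modules")
  if (ncol(object@values) != length(object@genes)) return("column count must match genes")
  if (anyDuplicated(object@genes)) return("gene symbols must be unique")
  if (length(object@modules) > 0 && any(apply(object@values, 1, function(r) all(is.na(r)))))
    return("no module row may be entirely missing")
  TRUE
})

#' Collection of disorder gene sets
#'
#' Named gene sets (one per brain disorder) with an optional mapping of sets
#' to disease groups, as read from GMT files.
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot groups named character vector mapping set names to group names
#'   (may be empty).
#' @export
setClass("DisorderGeneSets",
  representation(sets = "list", groups = "character")
)

setValidity("DisorderGeneSets", function(object) {
  if (length(object@sets) > 0) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      return("sets must be uniquely named")
    sizes <- lengths(object@sets)
    if (any(sizes == 0)) return("no gene set may be empty")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0))
      return("gene symbols must be unique within a set")
  }
  if (length(object@groups) > 0 &&
      !all(names(object@groups) %in% names(object@sets)))
    return("groups must map existing set names")
  TRUE
})
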