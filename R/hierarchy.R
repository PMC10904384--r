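#' Build the WPGMA merge tree of a connectivity matrix
#'
#' Each node's connectivity profile is its full matrix row (diagonal fixed at
#' zero); pairwise dissimilarity is the correlation distance
#' \eqn{d(i,j) = 1 - r(row_i, row_j)} and agglomeration uses weighted-average
#' (WPGMA) linkage, under which merge heights are monotone so every cut
#' cardinality yields a well-defined nested partition. With
#' \code{excludeSelf = TRUE} the correlation for a pair (i, j) is computed
#' with columns i and j removed from both rows.
#'
#' @param x a \linkS4class{FusedMatrix}, \linkS4class{ConnectivityMatrix} or
#'   plain symmetric matrix.
#' @param excludeSelf drop the mutual columns from each pair's profiles.
#' @return a \linkS4class{MergeTree}.
#' @export
buildMergeTree <- function(x, excludeSelf = FALSE) {
  if (is(x, "ConnectivityMatrix")) {
    v <- x@values
    ids <- x@nodeIds
  } else {
    v <- as.matrix(x)
    ids <- rownames(v)
    if (is.null(ids)) ids <- paste0("n", seq_len(nrow(v)))
  }
  n <- nrow(v)
  if (n < 2) parameterError("need at least 2 nodes to build a tree")
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    degenerateNodeError(sprintf(
      "constant connectivity row(s): %s (correlation distance undefined)",
      paste(utils::head(ids[sds == 0], 5), collapse = ", ")))
  if (excludeSelf) {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      keep <- -c(i, j)
      d[i, j] <- d[j, i] <- 1 - stats::cor(v[i, keep], v[j, keep])
    }
  } else {
    d <- 1 - stats::cor(t(v))
  }
  dimnames(d) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(d), method = "mcquitty")
  mergeTreeFromHclust(hc)
}

#' Cut a merge tree into m modules
#'
#' Cuts at cardinality m, i.e. after applying the first N - m merges; with
#' monotone linkage successive cuts are nested refinements. Modules are
#' labeled \code{M1..Mm} in order of first appearance along the leaf list.
#'
#' @param tree a \linkS4class{MergeTree}.
#' @param m number of modules, 1 <= m <= number of leaves.
#' @return a \linkS4class{Partition}.
#' @export
cutTree <- function(tree, m) {
  stopifnot(is(tree, "MergeTree"))
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m > tree@nLeaves || m != round(m))
    parameterError(sprintf("m must be an integer in [1, %d]", tree@nLeaves))
  g <- cutMembership(tree, as.integer(m))
  new("Partition", nodeIds = tree@leafIds, labels = paste0("M", g),
      nModules = as.integer(m))
}

# integer module membership at cut cardinality m, numbered by first
# appearance in leaf-input order; derived directly from the merge table so
# the cut is by merge count, not height (robust to tied heights)
cutMembership <- function(tree, m) {
  n <- tree@nLeaves
  memb <- -seq_len(n)  # cluster id per leaf: negative = still a singleton
  nApply <- n - m
  if (nApply > 0) {
    for (k in seq_len(nApply)) {
      memb[memb == tree@merge[k, 1] | memb == tree@merge[k, 2]] <- k
    }
  }
  as.integer(factor(memb, levels = unique(memb)))
}

#' Multi-scale tree metrics at a reference cut
#'
#' For the partition at cut cardinality \code{referenceM}:
#' \describe{
#'   \item{MS}{module size, the number of leaves in the module.}
#'   \item{H}{per leaf, the cut cardinality (counted from the top, M = 1) at
#'     which the leaf first stands alone as a singleton.}
#'   \item{MH}{module height, the mean H over the module's leaves.}
#'   \item{MSI}{multi-scale index: the number of consecutive cut
#'     cardinalities across which the module's leaf set stays intact,
#'     counted from the level at which the module is merged into its parent
#'     down to the level at which it first appears as its own cluster.}
#' }
#'
#' @param tree a \linkS4class{MergeTree}.
#' @param referenceM reference cut cardinality.
#' @return list with \code{modules} (data.frame: module, MS, MSI, MH) and
#'   \code{leaves} (data.frame: node_id, module, H).
#' @export
treeMetrics <- function(tree, referenceM) {
  stopifnot(is(tree, "MergeTree"))
  p <- cutTree(tree, referenceM)
  n <- tree@nLeaves
  nm <- n - 1L

  # first merge step involving each leaf -> H
  sFirst <- integer(n)
  for (k in seq_len(nm)) {
    for (j in tree@merge[k, ]) if (j < 0 && sFirst[-j] == 0L) sFirst[-j] <- k
  }
  H <- n - sFirst + 1L

  # leaf set of the cluster created at each merge step
  leafSets <- vector("list", nm)
  for (k in seq_len(nm)) {
    lv <- function(j) if (j < 0) -j else leafSets[[j]]
    leafSets[[k]] <- sort(c(lv(tree@merge[k, 1]), lv(tree@merge[k, 2])))
  }
  # step at which the cluster created at step k is absorbed (root: n)
  absorbed <- rep(n, nm)
  for (k in seq_len(nm)) {
    for (j in tree@merge[k, ]) if (j > 0) absorbed[j] <- k
  }

  memb <- split(seq_len(n), factor(p@labels, levels = unique(p@labels)))
  moduleNames <- names(memb)
  MS <- lengths(memb)
  MSI <- integer(length(memb))
  MH <- numeric(length(memb))
  for (i in seq_along(memb)) {
    leaves <- sort(memb[[i]])
    if (length(leaves) == 1) {
      sBirth <- 0L
      sAbs <- sFirst[leaves]
    } else {
      sBirth <- which(vapply(leafSets, identical, NA, y = leaves))[1]
      sAbs <- absorbed[sBirth]
    }
    MSI[i] <- sAbs - sBirth + 1L
    MH[i] <- mean(H[leaves])
  }
  list(
    modules = data.frame(module = moduleNames, MS = as.integer(MS),
                         MSI = MSI, MH = MH, row.names = NULL),
    leaves = data.frame(node_id = tree@leafIds, module = p@labels, H = H,
                        row.names = NULL)
  )
}
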