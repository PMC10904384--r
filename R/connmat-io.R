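#' Construct a ConnectivityMatrix
#'
#' Validates, symmetrizes (averaging asymmetries up to \code{tol}) and zeroes
#' the diagonal. Larger asymmetries are an error rather than silently
#' averaged, since they usually indicate misaligned node orders.
#'
#' @param values square numeric matrix.
#' @param nodeIds node identifiers; defaults to the matrix dimnames.
#' @param modality \code{"structural"}, \code{"functional"} or \code{"fused"}.
#' @param weighted logical; set \code{FALSE} for binarized matrices.
#' @param tol symmetrization tolerance (default 1e-8).
#' @return a \linkS4class{ConnectivityMatrix}.
#' @export
connectivityMatrix <- function(values, nodeIds = rownames(values),
                               modality = c("structural", "functional", "fused"),
                               weighted = TRUE, tol = 1e-8) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    formatError(sprintf("matrix is not square: %d x %d", nrow(values), ncol(values)))
  if (is.null(nodeIds)) nodeIds <- paste0("n", seq_len(nrow(values)))
  nodeIds <- as.character(nodeIds)
  if (length(nodeIds) != nrow(values))
    validationError("node id count does not match matrix dimension")
  storage.mode(values) <- "double"
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    validationError(sprintf("matrix asymmetry %.3g exceeds tolerance %.1g", asym, tol))
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(nodeIds, nodeIds)
  if (modality == "functional" && (any(values < -1 - 1e-12) || any(values > 1 + 1e-12)))
    validationError("functional values outside [-1, 1]")
  if (modality == "structural" && any(values < 0))
    validationError("structural values must be nonnegative")
  new("ConnectivityMatrix", nodeIds = nodeIds, values = values,
      modality = modality, weighted = weighted)
}

#' Read a connectivity matrix from TSV
#'
#' Canonical dialect: tab-separated, node ids in the header row and first
#' column. The matrix must be square and symmetric within 1e-8; the diagonal
#' is forced to zero.
#'
#' @param path file path.
#' @param modality matrix modality tag.
#' @param weighted logical weighted flag.
#' @return a \linkS4class{ConnectivityMatrix}.
#' @export
readConnectivityMatrix <- function(path,
                                   modality = c("structural", "functional", "fused"),
                                   weighted = TRUE) {
  modality <- match.arg(modality)
  if (!file.exists(path)) formatError(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    formatError(sprintf("matrix in %s is not square: %d x %d", path, nrow(m), ncol(m)))
  if (!identical(rownames(m), colnames(m)))
    validationError(sprintf("row and column node ids disagree in %s", path))
  connectivityMatrix(m, rownames(m), modality, weighted = weighted)
}

#' Write a connectivity matrix as TSV
#'
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeConnectivityMatrix <- function(x, path) {
  stopifnot(is(x, "ConnectivityMatrix"))
  df <- data.frame(node_id = x@nodeIds, x@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read disorder gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, fields \code{name}, description,
#' then gene symbols, all tab-separated. Duplicate symbols within a line are
#' removed with a warning; an empty gene list or a duplicated set name is an
#' error.
#'
#' @param path GMT file path.
#' @param groups optional named character vector mapping set names to disease
#'   groups.
#' @return a \linkS4class{DisorderGeneSets}.
#' @export
readGeneSets <- function(path, groups = character()) {
  if (!file.exists(path)) formatError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) formatError(sprintf("empty GMT file: %s", path))
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(fields) < 3 || length(genes) == 0)
      formatError(sprintf("GMT line for set '%s' has no genes", fields[1]))
    if (fields[1] %in% names(sets))
      formatError(sprintf("duplicate set name '%s'", fields[1]))
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene symbols in set '%s' de-duplicated", fields[1]))
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
  }
  new("DisorderGeneSets", sets = sets, groups = groups)
}

#' Write gene sets as GMT
#'
#' @param x a \linkS4class{DisorderGeneSets}.
#' @param path output path.
#' @param descriptions optional per-set description field.
#' @return the path, invisibly.
#' @export
writeGeneSets <- function(x, path, descriptions = NULL) {
  stopifnot(is(x, "DisorderGeneSets"))
  nm <- names(x@sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(nm))
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], descriptions[i], x@sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write node partitions and labelings
#'
#' Two-column TSV with header \code{node_id<TAB>label}; write-then-read is
#' the identity. When \code{nodeIds} is supplied, nodes outside that universe
#' are rejected.
#'
#' @param path file path.
#' @param nodeIds optional universe of admissible node ids.
#' @return \code{readPartition} returns a \linkS4class{Partition};
#'   \code{readNodeLabeling} a \linkS4class{NodeLabeling}.
#' @export
readPartition <- function(path, nodeIds = NULL) {
  lab <- readNodeLabeling(path, nodeIds)
  new("Partition", nodeIds = lab@nodeIds, labels = lab@labels,
      nModules = length(unique(lab@labels)))
}

#' @rdname readPartition
#' @export
readNodeLabeling <- function(path, nodeIds = NULL) {
  if (!file.exists(path)) formatError(sprintf("file not found: %s", path))
  if (file.size(path) == 0) formatError(sprintf("empty labeling file: %s", path))
  df <- utils::read.delim(path, colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2)
    formatError(sprintf("labeling file %s must have two columns and >= 1 row", path))
  ids <- df[[1]]
  if (!is.null(nodeIds) && !all(ids %in% nodeIds))
    validationError(sprintf("unknown node ids in %s: %s", path,
                            paste(utils::head(setdiff(ids, nodeIds), 5), collapse = ", ")))
  new("NodeLabeling", nodeIds = ids, labels = df[[2]])
}

#' @rdname readPartition
#' @param x a \linkS4class{Partition} or \linkS4class{NodeLabeling}.
#' @export
writePartition <- function(x, path) {
  stopifnot(is(x, "NodeLabeling"))
  df <- data.frame(node_id = x@nodeIds, module_label = x@labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge-table and Newick export of merge trees
#'
#' The merge table is a 4-column TSV (\code{left_id}, \code{right_id},
#' \code{distance}, \code{new_cluster_size}), one row per merge: leaves are
#' denoted by their node ids and internal clusters by \code{C<k>}, k being
#' the (1-based) merge row that created them. \code{treeToNewick} writes the
#' dendrogram as a Newick string with branch lengths derived from merge
#' distances.
#'
#' @param tree a \linkS4class{MergeTree}.
#' @param path output (or input) path.
#' @return the path invisibly; \code{readMergeTable} a
#'   \linkS4class{MergeTree}.
#' @export
writeMergeTable <- function(tree, path) {
  stopifnot(is(tree, "MergeTree"))
  idOf <- function(j) if (j < 0) tree@leafIds[-j] else paste0("C", j)
  sizes <- clusterSizes(tree)
  df <- data.frame(
    left_id  = vapply(tree@merge[, 1], idOf, ""),
    right_id = vapply(tree@merge[, 2], idOf, ""),
    distance = tree@height,
    new_cluster_size = sizes
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMergeTable
#' @export
readMergeTable <- function(path) {
  if (!file.exists(path)) formatError(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, colClasses = c("character", "character", "numeric", "integer"))
  if (ncol(df) < 4) formatError(sprintf("merge table %s must have 4 columns", path))
  isClust <- function(s) grepl("^C[0-9]+$", s)
  leafNames <- c(rbind(df$left_id, df$right_id))
  leafNames <- leafNames[!isClust(leafNames)]
  n <- nrow(df) + 1L
  if (length(leafNames) != n)
    formatError(sprintf("merge table %s: %d leaves for %d merges", path, length(leafNames), nrow(df)))
  leafIds <- sort(leafNames)
  code <- function(s) {
    out <- -match(s, leafIds)
    cl <- isClust(s)
    out[cl] <- as.integer(sub("^C", "", s[cl]))
    out
  }
  merge <- cbind(code(df$left_id), code(df$right_id))
  storage.mode(merge) <- "integer"
  hc <- structure(list(merge = merge, height = df$distance,
                       order = seq_len(n), labels = leafIds,
                       method = "mcquitty"),
                  class = "hclust")
  hc$order <- stats::order.dendrogram(stats::as.dendrogram(hc))
  mergeTreeFromHclust(hc)
}

#' @rdname writeMergeTable
#' @export
treeToNewick <- function(tree, path = NULL) {
  stopifnot(is(tree, "MergeTree"))
  phy <- ape::as.phylo(asHclust(tree))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

# hclust <-> MergeTree bridges (internal)
asHclust <- function(tree) {
  structure(list(merge = tree@merge, height = tree@height,
                 order = tree@order, labels = tree@leafIds,
                 method = tree@method),
            class = "hclust")
}

mergeTreeFromHclust <- function(hc) {
  new("MergeTree",
      nLeaves = length(hc$labels),
      merge = hc$merge, height = as.numeric(hc$height),
      order = as.integer(hc$order), leafIds = as.character(hc$labels),
      method = if (is.null(hc$method)) "mcquitty" else hc$method)
}

# size of the cluster created at each merge row
clusterSizes <- function(tree) {
  sizes <- integer(nrow(tree@merge))
  for (k in seq_along(sizes)) {
    sz <- function(j) if (j < 0) 1L else sizes[j]
    sizes[k] <- sz(tree@merge[k, 1]) + sz(tree@merge[k, 2])
  }
  sizes
}
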