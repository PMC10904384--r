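#' Aggregate sample-level expression to module level
#'
#' Averages expression over the samples assigned to each module (arithmetic
#' mean per gene). Modules in the labeling without any sample are dropped
#' with a warning.
#'
#' @param sampleExpression samples x genes numeric matrix with sample ids as
#'   row names and gene symbols as column names.
#' @param sampleModules a \linkS4class{NodeLabeling} assigning each sample to
#'   a module.
#' @return a \linkS4class{ModuleExpression}.
#' @export
aggregateSamples <- function(sampleExpression, sampleModules) {
  stopifnot(is(sampleModules, "NodeLabeling"))
  m <- as.matrix(sampleExpression)
  if (nrow(m) == 0) validationError("no samples in expression matrix")
  ids <- rownames(m)
  if (is.null(ids)) {
    if (nrow(m) != length(sampleModules@nodeIds))
      validationError("unnamed expression rows do not match the labeling")
    ids <- sampleModules@nodeIds
  }
  pos <- match(ids, sampleModules@nodeIds)
  if (anyNA(pos))
    validationError(sprintf("unlabeled samples: %s",
      paste(utils::head(ids[is.na(pos)], 5), collapse = ", ")))
  modLevels <- unique(sampleModules@labels)
  labels <- factor(sampleModules@labels[pos], levels = modLevels)
  present <- modLevels %in% labels
  if (!all(present)) {
    warning(sprintf("dropping module(s) without samples: %s",
                    paste(modLevels[!present], collapse = ", ")))
    modLevels <- modLevels[present]
    labels <- factor(as.character(labels), levels = modLevels)
  }
  groups <- split(seq_len(nrow(m)), labels)
  vals <- t(vapply(groups, function(idx) colMeans(m[idx, , drop = FALSE]),
                   numeric(ncol(m))))
  genes <- colnames(m)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m)))
  new("ModuleExpression", modules = modLevels, genes = genes,
      values = matrix(vals, nrow = length(modLevels),
                      dimnames = list(modLevels, genes)),
      nSamples = lengths(groups))
}

#' Score modules against disorder gene sets
#'
#' For each disorder, summarizes the expression of its matched genes per
#' module (\code{stat = "mean"} by default, \code{"median"} available) and
#' z-scores that summary across modules using the sample standard deviation.
#' Modules with z > 2 are flagged \code{"high"}, z < -2 \code{"low"}. Gene
#' matching is case-insensitive exact symbol match; a set matching no gene
#' is an error, and unmatched symbols are reported via a message.
#'
#' @param expr a \linkS4class{ModuleExpression}.
#' @param sets a \linkS4class{DisorderGeneSets}.
#' @param stat per-module summary over the set's genes: \code{"mean"}
#'   (default) or \code{"median"}.
#' @param zThreshold flag threshold on |z| (default 2).
#' @return data.frame with columns module, disorder, mean_expression, z,
#'   flag, n_genes_matched.
#' @export
disorderScores <- function(expr, sets, stat = c("mean", "median"), zThreshold = 2) {
  stat <- match.arg(stat)
  stopifnot(is(expr, "ModuleExpression"), is(sets, "DisorderGeneSets"))
  if (length(expr@modules) < 2)
    validationError("z-scores across modules need at least 2 modules")
  geneKey <- toupper(expr@genes)
  summarize <- if (stat == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  out <- lapply(names(sets@sets), function(d) {
    hit <- match(toupper(sets@sets[[d]]), geneKey)
    matched <- which(!is.na(hit))
    if (length(matched) == 0)
      geneMatchError(sprintf("gene set '%s' matches no gene in the expression matrix", d))
    if (length(matched) < length(hit))
      message(sprintf("set '%s': %d/%d symbols unmatched", d,
                      length(hit) - length(matched), length(hit)))
    x <- summarize(expr@values[, hit[matched], drop = FALSE])
    sdx <- stats::sd(x)
    z <- if (sdx == 0) rep(NA_real_, length(x)) else (x - mean(x)) / sdx
    flag <- rep("none", length(x))
    flag[!is.na(z) & z > zThreshold] <- "high"
    flag[!is.na(z) & z < -zThreshold] <- "low"
    data.frame(module = expr@modules, disorder = d, mean_expression = unname(x),
               z = unname(z), flag = flag,
               n_genes_matched = length(matched), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Score modules against disease groups
#'
#' Pools, per disease group, the union of its member disorders' gene symbols
#' (a gene appearing in two member disorders counts once) and applies the
#' same summary-and-z-score analysis as \code{\link{disorderScores}}.
#'
#' @inheritParams disorderScores
#' @return data.frame as in \code{\link{disorderScores}}, with the group
#'   name in the \code{disorder} column.
#' @export
groupScores <- function(expr, sets, stat = c("mean", "median"), zThreshold = 2) {
  stopifnot(is(sets, "DisorderGeneSets"))
  if (length(sets@groups) == 0)
    validationError("gene set collection carries no group mapping")
  groupNames <- unique(unname(sets@groups))
  pooled <- lapply(groupNames, function(g) {
    members <- names(sets@groups)[sets@groups == g]
    genes <- unique(unlist(sets@sets[members], use.names = FALSE))
    if (length(genes) == 0) geneMatchError(sprintf("disease group '%s' is empty", g))
    genes
  })
  names(pooled) <- groupNames
  disorderScores(expr, new("DisorderGeneSets", sets = pooled,
                           groups = character()),
                 stat = stat, zThreshold = zThreshold)
}
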