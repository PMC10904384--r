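#' Node strength of a fused matrix
#'
#' Strength is the row sum of fused weights; normalized strength divides by
#' the maximum (brain-map convention) or, with \code{normalize = "n-1"}, by
#' the number of possible neighbors.
#'
#' @param fused a \linkS4class{FusedMatrix} or
#'   \linkS4class{ConnectivityMatrix}.
#' @param normalize \code{"max"} (default) or \code{"n-1"}.
#' @return data.frame with columns node_id, strength, normalized_strength;
#'   the gamma used is attached as attribute \code{"gamma"} when available.
#' @export
nodeStrength <- function(fused, normalize = c("max", "n-1")) {
  normalize <- match.arg(normalize)
  stopifnot(is(fused, "ConnectivityMatrix"))
  s <- rowSums(fused@values)
  if (all(s == 0)) degenerateGraphError("all-zero matrix has no strengths")
  denom <- if (normalize == "max") max(s) else length(s) - 1
  out <- data.frame(node_id = fused@nodeIds, strength = s,
                    normalized_strength = s / denom, row.names = NULL)
  if (is(fused, "FusedMatrix")) attr(out, "gamma") <- fused@gamma
  out
}

#' Group a per-node table by a labeling
#'
#' Splits a per-node value column (default \code{strength}) by label, e.g.
#' to compare strength distributions across macro-regions.
#'
#' @param table data.frame with a \code{node_id} column.
#' @param labeling a \linkS4class{NodeLabeling} covering the table's nodes.
#' @param column which column to group (default \code{"strength"}).
#' @return named list of numeric vectors, one per label.
#' @export
groupByLabels <- function(table, labeling, column = "strength") {
  stopifnot(is(labeling, "NodeLabeling"))
  pos <- match(table$node_id, labeling@nodeIds)
  if (anyNA(pos))
    validationError(sprintf("labeling is missing nodes: %s",
      paste(utils::head(table$node_id[is.na(pos)], 5), collapse = ", ")))
  split(table[[column]], labeling@labels[pos])
}

#' Intra-module mean weight (segregation)
#'
#' For each module m, the mean weight over ordered intra-module node pairs,
#' \eqn{\sum_{i \ne j \in m} w_{ij} / (|m| (|m| - 1))}: a proxy for how
#' self-contained the module is. Singleton modules have no internal pairs
#' and are reported as \code{NA}.
#'
#' @param fused a \linkS4class{FusedMatrix} or
#'   \linkS4class{ConnectivityMatrix}.
#' @param p a \linkS4class{Partition} covering the nodes.
#' @return data.frame with columns module, size, segregation.
#' @export
moduleSegregation <- function(fused, p) {
  stopifnot(is(fused, "ConnectivityMatrix"))
  v <- fused@values
  labels <- alignLabels(p, rownames(v), nrow(v))
  groups <- split(seq_len(nrow(v)), factor(labels, levels = unique(labels)))
  seg <- vapply(groups, function(idx) {
    k <- length(idx)
    if (k < 2) return(NA_real_)
    sum(v[idx, idx]) / (k * (k - 1))
  }, 0)
  data.frame(module = names(groups), size = lengths(groups),
             segregation = unname(seg), row.names = NULL)
}

#' Pairwise Pearson correlations among module-level metrics
#'
#' Computes Pearson r and two-sided p-values for every pair of metric
#' columns over modules, dropping rows with missing values pairwise.
#'
#' @param metrics data.frame of module-level metrics (e.g. MS, MSI, MH,
#'   segregation); non-numeric columns are ignored.
#' @return list with matrices \code{r} and \code{p}.
#' @export
metricCorrelations <- function(metrics) {
  num <- metrics[vapply(metrics, is.numeric, NA)]
  k <- ncol(num)
  if (k < 2) insufficientDataError("need at least two numeric metric columns")
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(num), names(num)))
  diag(r) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(num[[i]], num[[j]])
    if (sum(ok) < 3)
      insufficientDataError(sprintf(
        "fewer than 3 modules with defined %s and %s", names(num)[i], names(num)[j]))
    ct <- stats::cor.test(num[[i]][ok], num[[j]][ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}
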