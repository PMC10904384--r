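#' Newman-Girvan modularity of a partition on a binary graph
#'
#' \deqn{Q = \sum_c \left[ \frac{L_c}{L} - \left(\frac{d_c}{2L}\right)^2 \right]}
#' with L the total link count, \eqn{L_c} the intra-module link count and
#' \eqn{d_c} the summed degree of module c.
#'
#' @param adj binary \linkS4class{ConnectivityMatrix} or 0/1 matrix.
#' @param p \linkS4class{Partition} covering the graph's nodes.
#' @return modularity Q in [-0.5, 1].
#' @export
newmanModularity <- function(adj, p) {
  a <- if (is(adj, "ConnectivityMatrix")) adj@values else as.matrix(adj)
  labels <- alignLabels(p, rownames(a), nrow(a))
  L <- sum(a) / 2
  if (L == 0) emptyGraphError("graph has no links")
  deg <- rowSums(a)
  q <- 0
  for (idx in split(seq_len(nrow(a)), labels)) {
    lc <- sum(a[idx, idx, drop = FALSE]) / 2
    dc <- sum(deg[idx])
    q <- q + lc / L - (dc / (2 * L))^2
  }
  q
}

# match a Partition's labels to a matrix's row order
alignLabels <- function(p, ids, n) {
  stopifnot(is(p, "NodeLabeling"))
  if (is.null(ids)) {
    if (length(p@nodeIds) != n)
      validationError("partition does not cover the graph's nodes")
    return(p@labels)
  }
  pos <- match(ids, p@nodeIds)
  if (anyNA(pos))
    validationError(sprintf("partition is missing nodes: %s",
                            paste(utils::head(ids[is.na(pos)], 5), collapse = ", ")))
  p@labels[pos]
}

#' DICE similarity of two sets
#'
#' \eqn{2 |a \cap b| / (|a| + |b|)}; defined as long as at least one set is
#' non-empty.
#'
#' @param a,b vectors treated as sets.
#' @return DICE coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0)
    undefinedDiceError("DICE of two empty sets is undefined")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Structure-function module similarity T_FS
#'
#' With the default \code{"link-dice"} strategy the two binary matrices are
#' compared under the shared partition: for each module, the DICE overlap
#' between its intra-module link sets in FC and in SC; modules with no intra
#' links in either matrix are excluded from the average (0 if all are).
#' The legacy \code{"node-dice"} strategy clusters FC and SC separately,
#' cuts both trees at the partition's module count and averages, over
#' functional modules, the best node-set DICE against any structural module;
#' it does not depend on gamma.
#'
#' @param pair a \linkS4class{PopulationPair}.
#' @param p \linkS4class{Partition} over the pair's nodes.
#' @param strategy \code{"link-dice"} (default) or \code{"node-dice"}.
#' @return similarity in [0, 1].
#' @export
moduleSimilarity <- function(pair, p, strategy = c("link-dice", "node-dice")) {
  strategy <- tryCatch(match.arg(strategy),
                       error = function(e) parameterError(
                         sprintf("unknown T_FS strategy '%s'", strategy[1])))
  stopifnot(is(pair, "PopulationPair"))
  if (strategy == "link-dice") {
    fc <- pair@fcBin@values
    sc <- pair@scBin@values
    labels <- alignLabels(p, rownames(fc), nrow(fc))
    vals <- c()
    for (idx in split(seq_len(nrow(fc)), labels)) {
      if (length(idx) < 2) next
      ut <- upper.tri(matrix(0, length(idx), length(idx)))
      f <- fc[idx, idx, drop = FALSE][ut] > 0
      s <- sc[idx, idx, drop = FALSE][ut] > 0
      if (!any(f) && !any(s)) next
      vals <- c(vals, 2 * sum(f & s) / (sum(f) + sum(s)))
    }
    if (length(vals) == 0) return(0)
    mean(vals)
  } else {
    m <- nModules(p)
    fTree <- buildMergeTree(pair@fcBin)
    sTree <- buildMergeTree(pair@scBin)
    fMods <- split(leafIds(fTree), cutTree(fTree, m)@labels)
    sMods <- split(leafIds(sTree), cutTree(sTree, m)@labels)
    mean(vapply(fMods, function(fm) {
      max(vapply(sMods, function(sm) diceCoefficient(fm, sm), 0))
    }, 0))
  }
}

#' Cross-modularity chi
#'
#' \deqn{\chi = (Q_F \times Q_S \times T_{FS})^{1/3}}
#' If any factor is negative the configuration carries no meaningful
#' community structure and chi is recorded as \code{NA} (excluded from
#' maximization).
#'
#' @param qf,qs functional and structural modularity.
#' @param t module similarity T_FS.
#' @return chi, or \code{NA} when a factor is negative.
#' @export
chiStat <- function(qf, qs, t) {
  if (anyNA(c(qf, qs, t))) return(NA_real_)
  if (qf < 0 || qs < 0 || t < 0) return(NA_real_)
  (qf * qs * t)^(1 / 3)
}

#' Search the (gamma, M) plane for the cross-modularity optimum
#'
#' For every gamma: fuse the pair, build the WPGMA tree of the fused matrix,
#' and for every cut cardinality M compute Q_F and Q_S (the same fused-tree
#' partition applied to the binary FC and SC matrices respectively), T_FS
#' and chi. The optimum is the chi-maximizing cell, ties broken toward
#' smaller M then smaller gamma. Modules with fewer than
#' \code{minModuleSize} members are counted separately as invalid, mirroring
#' the exclusion of one- and two-node modules whose internal community
#' structure cannot be analyzed.
#'
#' @param pair a \linkS4class{PopulationPair}.
#' @param gammas gamma grid (default \code{defaultGammaGrid()}).
#' @param mRange cut cardinalities to search (default \code{2:120}, clipped
#'   to the node count).
#' @param minModuleSize minimum leaves for a module to count as valid
#'   (default 3).
#' @param tfsStrategy T_FS strategy, see \code{\link{moduleSimilarity}}.
#' @param excludeSelf passed to \code{\link{buildMergeTree}}.
#' @return a \linkS4class{CrossModularityGrid}.
#' @export
optimizeCrossModularity <- function(pair, gammas = defaultGammaGrid(),
                                    mRange = 2:120, minModuleSize = 3,
                                    tfsStrategy = c("link-dice", "node-dice"),
                                    excludeSelf = FALSE) {
  tfsStrategy <- match.arg(tfsStrategy)
  stopifnot(is(pair, "PopulationPair"))
  if (length(gammas) == 0) parameterError("gamma grid must be non-empty")
  if (any(gammas < 0 | gammas > 1)) parameterError("gammas must lie in [0, 1]")
  n <- length(pair@scBin@nodeIds)
  mRange <- sort(unique(as.integer(mRange)))
  mRange <- mRange[mRange >= 2 & mRange <= n]
  if (length(mRange) == 0) parameterError("mRange must intersect [2, N]")

  ng <- length(gammas); nm <- length(mRange)
  dn <- list(paste0("gamma_", gammas), paste0("M_", mRange))
  qf <- qs <- tfs <- chi <- matrix(NA_real_, ng, nm, dimnames = dn)
  nValid <- matrix(NA_integer_, ng, nm, dimnames = dn)

  nodeDiceCache <- new.env(parent = emptyenv())
  trees <- vector("list", ng)
  for (i in seq_len(ng)) {
    fused <- fuseConnectivity(pair, gammas[i])
    tree <- buildMergeTree(fused, excludeSelf = excludeSelf)
    trees[[i]] <- tree
    for (j in seq_len(nm)) {
      p <- cutTree(tree, mRange[j])
      qf[i, j] <- newmanModularity(pair@fcBin, p)
      qs[i, j] <- newmanModularity(pair@scBin, p)
      tfs[i, j] <- if (tfsStrategy == "node-dice") {
        key <- as.character(mRange[j])
        if (is.null(nodeDiceCache[[key]]))
          nodeDiceCache[[key]] <- moduleSimilarity(pair, p, "node-dice")
        nodeDiceCache[[key]]
      } else {
        moduleSimilarity(pair, p, "link-dice")
      }
      chi[i, j] <- chiStat(qf[i, j], qs[i, j], tfs[i, j])
      nValid[i, j] <- sum(table(p@labels) >= minModuleSize)
    }
  }
  if (all(is.na(chi)))
    validationError("chi is undefined over the whole grid (a factor is negative everywhere)")
  # argmax chi; ties toward smaller M, then smaller gamma
  best <- which(chi == max(chi, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(mRange[best[, 2]], gammas[best[, 1]]), , drop = FALSE]
  bi <- best[1, 1]; bj <- best[1, 2]
  optPartition <- cutTree(trees[[bi]], mRange[bj])
  new("CrossModularityGrid",
      gammas = gammas, moduleCounts = mRange,
      qf = qf, qs = qs, tfs = tfs, chi = chi,
      validModules = nValid, minModuleSize = as.integer(minModuleSize),
      optimum = list(gamma = gammas[bi], m = mRange[bj], chi = chi[bi, bj],
                     qf = qf[bi, bj], qs = qs[bi, bj], tfs = tfs[bi, bj],
                     nValidModules = nValid[bi, bj], partition = optPartition))
}

#' Long-format data.frame view of a cross-modularity grid
#'
#' @param grid a \linkS4class{CrossModularityGrid}.
#' @return data.frame with columns gamma, m, q_f, q_s, t_fs, chi,
#'   n_valid_modules.
#' @export
gridAsDataFrame <- function(grid) {
  stopifnot(is(grid, "CrossModularityGrid"))
  expand <- expand.grid(gi = seq_along(grid@gammas),
                        mj = seq_along(grid@moduleCounts))
  data.frame(
    gamma = grid@gammas[expand$gi],
    m = grid@moduleCounts[expand$mj],
    q_f = grid@qf[cbind(expand$gi, expand$mj)],
    q_s = grid@qs[cbind(expand$gi, expand$mj)],
    t_fs = grid@tfs[cbind(expand$gi, expand$mj)],
    chi = grid@chi[cbind(expand$gi, expand$mj)],
    n_valid_modules = grid@validModules[cbind(expand$gi, expand$mj)]
  )
}
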