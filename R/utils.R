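#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same nodes,
#' computed from the contingency table in closed form. 1 means identical up
#' to relabeling, 0 is chance-level agreement.
#'
#' @param p1,p2 \linkS4class{Partition} (or \linkS4class{NodeLabeling})
#'   objects over the same nodes.
#' @return adjusted Rand index.
#' @export
partitionAgreement <- function(p1, p2) {
  stopifnot(is(p1, "NodeLabeling"), is(p2, "NodeLabeling"))
  pos <- match(p1@nodeIds, p2@nodeIds)
  if (anyNA(pos)) validationError("partitions do not cover the same nodes")
  tab <- table(p1@labels, p2@labels[pos])
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1)
  (sumij - expected) / (maxIdx - expected)
}
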