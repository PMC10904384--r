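#' Module-by-atlas overlap matrix
#'
#' Cross-tabulates a partition against a reference atlas labeling over the
#' same elements. Mode \code{"fraction"} gives, per module row, the fraction
#' of its elements falling in each atlas label (rows sum to 1); mode
#' \code{"dice"} gives the DICE coefficient between the module's element set
#' and the label's. Optional per-element weights (e.g. voxel counts per
#' micro-region) recover voxel-level proportions from region-level input.
#'
#' @param p a \linkS4class{Partition}.
#' @param atlas a \linkS4class{NodeLabeling} over the same elements.
#' @param mode \code{"fraction"} (default) or \code{"dice"}.
#' @param weights optional named element weights (default 1 per element).
#' @return numeric modules x atlas-labels matrix.
#' @export
overlapMatrix <- function(p, atlas, mode = c("fraction", "dice"), weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(p, "NodeLabeling"), is(atlas, "NodeLabeling"))
  if (!setequal(p@nodeIds, atlas@nodeIds))
    validationError("partition and atlas must cover the same elements")
  pos <- match(p@nodeIds, atlas@nodeIds)
  w <- if (is.null(weights)) rep(1, length(p@nodeIds)) else {
    if (is.null(names(weights))) weights else unname(weights[p@nodeIds])
  }
  mods <- factor(p@labels, levels = unique(p@labels))
  labs <- factor(atlas@labels[pos], levels = sort(unique(atlas@labels)))
  cross <- tapply(w, list(mods, labs), sum, default = 0)
  cross <- matrix(cross, nrow = nlevels(mods),
                  dimnames = list(levels(mods), levels(labs)))
  if (mode == "fraction") {
    sweep(cross, 1, rowSums(cross), "/")
  } else {
    modTot <- rowSums(cross)
    labTot <- colSums(cross)
    2 * cross / outer(modTot, labTot, "+")
  }
}

#' Top-k atlas labels per module
#'
#' Ranks each module's overlap row in decreasing order (ties broken
#' alphabetically by label name) and returns the k best labels.
#'
#' @param overlaps matrix from \code{\link{overlapMatrix}}.
#' @param k number of labels to keep per module.
#' @return named list of character vectors (one per module, length <= k).
#' @export
topLabels <- function(overlaps, k = 3) {
  if (k < 1) parameterError("k must be >= 1")
  labs <- colnames(overlaps)
  out <- lapply(seq_len(nrow(overlaps)), function(i) {
    ord <- order(-overlaps[i, ], labs)
    labs[ord][seq_len(min(k, length(labs)))]
  })
  names(out) <- rownames(overlaps)
  out
}
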