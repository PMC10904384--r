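#' Fuse a binarized population pair at a given gamma
#'
#' Computes the gamma-fused structure-function matrix
#' \deqn{\gamma SFC = \gamma \, FC_p + (1 - \gamma) \, SC_p}
#' elementwise over the binarized pair, so a link present in both modalities
#' has weight 1, an SC-only link weight \eqn{1 - \gamma}, an FC-only link
#' weight \eqn{\gamma}, and an absent link 0. gamma = 0 recovers the
#' structural matrix exactly and gamma = 1 the functional one.
#'
#' @param pair a \linkS4class{PopulationPair}.
#' @param gamma fusion parameter in [0, 1].
#' @return a \linkS4class{FusedMatrix}.
#' @export
fuseConnectivity <- function(pair, gamma) {
  stopifnot(is(pair, "PopulationPair"))
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    parameterError(sprintf("gamma must be a single value in [0, 1], got %s",
                           paste(gamma, collapse = ",")))
  v <- gamma * pair@fcBin@values + (1 - gamma) * pair@scBin@values
  new("FusedMatrix", nodeIds = pair@scBin@nodeIds, values = v,
      modality = "fused", weighted = TRUE, gamma = gamma)
}

#' Fuse a pair over a grid of gamma values
#'
#' @param pair a \linkS4class{PopulationPair}.
#' @param gammas gamma values, all in [0, 1]; default
#'   \code{defaultGammaGrid()}.
#' @return list of \linkS4class{FusedMatrix} objects, in input order.
#' @export
gammaGridFuse <- function(pair, gammas = defaultGammaGrid()) {
  if (length(gammas) == 0) parameterError("gamma grid must be non-empty")
  lapply(gammas, function(g) fuseConnectivity(pair, g))
}

#' Default gamma grid
#'
#' Eleven values 0.0 to 1.0 in steps of 0.1: the coarsest grid that resolves
#' a one-decimal optimum.
#'
#' @return numeric vector of gammas.
#' @export
defaultGammaGrid <- function() seq(0, 1, by = 0.1)
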