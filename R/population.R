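#' Link-wise median population matrix
#'
#' Aggregates per-subject connectivity matrices into a population matrix by
#' taking, for each link, the median value across subjects. Absent links
#' (zeros) enter the median like any other value, so a link present in fewer
#' than half the subjects has population value 0 for count data.
#'
#' @param subjectMatrices list of \linkS4class{ConnectivityMatrix} objects
#'   sharing node ids (same order) and modality.
#' @return a \linkS4class{ConnectivityMatrix} of the same modality.
#' @export
populationMedian <- function(subjectMatrices) {
  if (length(subjectMatrices) < 1)
    validationError("need at least one subject matrix")
  ref <- subjectMatrices[[1]]
  for (m in subjectMatrices) {
    if (!identical(m@nodeIds, ref@nodeIds))
      validationError("subject matrices do not share node ids")
    if (!identical(m@modality, ref@modality))
      validationError("subject matrices do not share modality")
  }
  arr <- vapply(subjectMatrices, function(m) m@values,
                matrix(0, length(ref@nodeIds), length(ref@nodeIds)))
  med <- apply(arr, c(1, 2), stats::median)
  connectivityMatrix(med, ref@nodeIds, ref@modality, weighted = TRUE)
}

#' Density-match and binarize a population SC/FC pair
#'
#' The structural matrix is binarized at > 0. To match its sparse density,
#' the functional matrix keeps only its K strongest links (K = structural
#' link count) and is then binarized. By default only positive correlations
#' are ranked, by value; \code{fcRule = "absolute"} ranks by magnitude
#' instead. All links tied with the K-th value are kept, so the functional
#' density can exceed the structural one by the tie-group size (reported in
#' the returned pair).
#'
#' @param scPop,fcPop population \linkS4class{ConnectivityMatrix} objects
#'   sharing node ids.
#' @param fcRule \code{"positive"} (default) or \code{"absolute"}.
#' @return a \linkS4class{PopulationPair}.
#' @export
matchDensityAndBinarize <- function(scPop, fcPop, fcRule = c("positive", "absolute")) {
  fcRule <- match.arg(fcRule)
  if (!identical(scPop@nodeIds, fcPop@nodeIds))
    validationError("SC and FC population matrices do not share node ids")
  n <- length(scPop@nodeIds)
  ut <- upper.tri(scPop@values)
  scLinks <- scPop@values[ut] > 0
  k <- sum(scLinks)
  if (k == 0) densityError("structural population matrix has no links")
  fcVals <- fcPop@values[ut]
  rankVals <- if (fcRule == "absolute") abs(fcVals) else fcVals
  eligible <- if (fcRule == "absolute") rankVals > 0 else fcVals > 0
  if (sum(eligible) < k)
    densityError(sprintf(
      "only %d eligible FC links for %d SC links (achievable density %.4f, required %.4f)",
      sum(eligible), k, sum(eligible) / sum(ut), k / sum(ut)))
  thr <- sort(rankVals[eligible], decreasing = TRUE)[k]
  keep <- eligible & rankVals >= thr
  ties <- sum(keep) - k
  if (ties > 0)
    message(sprintf("density matching kept %d extra FC links tied at the threshold", ties))

  binarize <- function(linkKeep, template, modality) {
    v <- matrix(0, n, n)
    v[ut] <- as.numeric(linkKeep)
    v <- v + t(v)
    connectivityMatrix(v, template@nodeIds, modality, weighted = FALSE)
  }
  new("PopulationPair",
      scBin = binarize(scLinks, scPop, "structural"),
      fcBin = binarize(keep, fcPop, "functional"),
      scRaw = scPop, fcRaw = fcPop,
      density = k / sum(ut), nLinks = as.integer(k), tieCount = as.integer(ties))
}
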