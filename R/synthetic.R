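#' Specification for a synthetic SC/FC cohort with planted modules
#'
#' Defines a cohort of paired structural and functional connectivity
#' matrices sharing a planted modular skeleton, plus a module-tagged
#' expression matrix with planted disorder gene sets. Structural subjects
#' are planted-partition Bernoulli graphs (within-module link probability
#' \code{pIn}, between \code{pOut}) derived from a common population graph
#' by per-subject link flips; functional subjects are noisy block
#' correlation matrices (\code{fcMuIn} within, \code{fcMuOut} between) with
#' subject-level Gaussian noise, clipped to [-1, 1]. Optional nested
#' sub-modules tighten connectivity within sub-blocks
#' (\code{pInSub}, \code{fcMuInSub}, defaulting to midway between the
#' level-1 value and 1).
#'
#' @param nNodes number of network nodes.
#' @param moduleSizes level-1 planted module sizes, summing to
#'   \code{nNodes}.
#' @param subSizes optional list (one entry per module) of nested sub-module
#'   sizes.
#' @param pIn,pOut SC link probabilities within / between modules.
#' @param pInSub SC link probability within nested sub-modules.
#' @param fcMuIn,fcMuOut FC block correlation means within / between
#'   modules.
#' @param fcMuInSub FC correlation mean within nested sub-modules.
#' @param fcNoiseSd population-level sd of FC block noise.
#' @param nSubjects cohort size.
#' @param subjectFlipProb per-subject probability of flipping each SC link
#'   indicator.
#' @param subjectNoiseSd per-subject sd of FC noise.
#' @param seed mandatory RNG seed; the cohort is a pure function of the
#'   spec.
#' @param nGenes,nSets,genesPerSet expression panel dimensions (disjoint
#'   gene sets).
#' @param samplesPerModule expression samples per module (>= 2).
#' @param planted list of \code{list(module =, set =, effect =)} triples:
#'   the named gene set is shifted by \code{effect} in the named module.
#' @param nGroups if > 0, assign sets round-robin to this many disease
#'   groups.
#' @return a validated spec (classed list).
#' @export
syntheticSpec <- function(nNodes = 60, moduleSizes = rep(15L, 4),
                          subSizes = NULL,
                          pIn = 0.8, pOut = 0.05, pInSub = NULL,
                          fcMuIn = 0.6, fcMuOut = 0.05, fcMuInSub = NULL,
                          fcNoiseSd = 0.1,
                          nSubjects = 20, subjectFlipProb = 0.05,
                          subjectNoiseSd = 0.1,
                          seed,
                          nGenes = 200, nSets = 10, genesPerSet = 8,
                          samplesPerModule = 3,
                          planted = list(), nGroups = 0) {
  if (missing(seed) || is.null(seed)) parameterError("seed is mandatory")
  if (sum(moduleSizes) != nNodes)
    parameterError("module sizes must sum to the node count")
  probs <- c(pIn, pOut, subjectFlipProb)
  if (any(probs < 0 | probs > 1)) parameterError("probabilities must lie in [0, 1]")
  if (any(moduleSizes < 1)) parameterError("every module needs at least one node")
  if (!is.null(subSizes)) {
    if (length(subSizes) != length(moduleSizes))
      parameterError("subSizes must have one entry per module")
    ok <- mapply(function(ss, ms) sum(ss) == ms, subSizes, moduleSizes)
    if (!all(ok)) parameterError("sub-module sizes must sum to their module's size")
  }
  if (nSets * genesPerSet > nGenes)
    parameterError("disjoint gene sets require nSets * genesPerSet <= nGenes")
  if (samplesPerModule < 2)
    parameterError("need >= 2 expression samples per module")
  spec <- list(
    nNodes = as.integer(nNodes), moduleSizes = as.integer(moduleSizes),
    subSizes = subSizes,
    pIn = pIn, pOut = pOut,
    pInSub = if (is.null(pInSub)) pIn + (1 - pIn) / 2 else pInSub,
    fcMuIn = fcMuIn, fcMuOut = fcMuOut,
    fcMuInSub = if (is.null(fcMuInSub)) fcMuIn + (1 - fcMuIn) / 2 else fcMuInSub,
    fcNoiseSd = fcNoiseSd,
    nSubjects = as.integer(nSubjects),
    subjectFlipProb = subjectFlipProb, subjectNoiseSd = subjectNoiseSd,
    seed = as.integer(seed),
    nGenes = as.integer(nGenes), nSets = as.integer(nSets),
    genesPerSet = as.integer(genesPerSet),
    samplesPerModule = as.integer(samplesPerModule),
    planted = planted, nGroups = as.integer(nGroups)
  )
  class(spec) <- "gsfcSyntheticSpec"
  spec
}

#' Generate a synthetic subject cohort
#'
#' Draws the cohort defined by a \code{\link{syntheticSpec}}: a list of
#' per-subject (SC, FC) \linkS4class{ConnectivityMatrix} pairs plus the
#' planted ground-truth partition (and the nested fine partition when
#' sub-modules are specified). Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with elements \code{subjects} (list of
#'   \code{list(sc =, fc =)}), \code{truth} and \code{truthFine}
#'   (\linkS4class{Partition} or \code{NULL}).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "gsfcSyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$nNodes
  ids <- sprintf("r%04d", seq_len(n))
  modLab <- rep(paste0("B", seq_along(spec$moduleSizes)), spec$moduleSizes)
  truth <- new("Partition", nodeIds = ids, labels = modLab,
               nModules = length(spec$moduleSizes))
  truthFine <- NULL
  subLab <- NULL
  if (!is.null(spec$subSizes)) {
    subLab <- unlist(lapply(seq_along(spec$subSizes), function(i) {
      rep(paste0("B", i, ".", seq_along(spec$subSizes[[i]])), spec$subSizes[[i]])
    }))
    truthFine <- new("Partition", nodeIds = ids, labels = subLab,
                     nModules = length(unique(subLab)))
  }

  same <- outer(modLab, modLab, "==")
  pMat <- ifelse(same, spec$pIn, spec$pOut)
  muMat <- ifelse(same, spec$fcMuIn, spec$fcMuOut)
  if (!is.null(subLab)) {
    sameSub <- outer(subLab, subLab, "==")
    pMat[sameSub] <- spec$pInSub
    muMat[sameSub] <- spec$fcMuInSub
  }
  ut <- upper.tri(pMat)
  baseSC <- stats::rbinom(sum(ut), 1, pMat[ut])
  baseFC <- muMat[ut] + stats::rnorm(sum(ut), 0, spec$fcNoiseSd)

  symmetrize <- function(linkVals) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[ut] <- linkVals
    m + t(m)
  }
  subjects <- lapply(seq_len(spec$nSubjects), function(s) {
    flips <- stats::rbinom(sum(ut), 1, spec$subjectFlipProb)
    scLinks <- as.numeric(xor(baseSC == 1, flips == 1))
    fcLinks <- pmin(1, pmax(-1, baseFC + stats::rnorm(sum(ut), 0, spec$subjectNoiseSd)))
    list(
      sc = connectivityMatrix(symmetrize(scLinks), ids, "structural", weighted = TRUE),
      fc = connectivityMatrix(symmetrize(fcLinks), ids, "functional", weighted = TRUE)
    )
  })
  list(subjects = subjects, truth = truth, truthFine = truthFine)
}

#' Generate a module-tagged expression matrix with planted gene sets
#'
#' Baseline expression is iid Normal(0, 1) over samples x genes;
#' \code{samplesPerModule} samples are assigned to each module of the given
#' partition, and each planted (module, set, effect) triple shifts that
#' set's genes by \code{effect} in that module's samples. The disorder panel
#' consists of \code{nSets} disjoint random gene sets.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param p \linkS4class{Partition} whose module labels the samples are
#'   tagged with; defaults to the spec's planted level-1 modules.
#' @return list with \code{expression} (samples x genes matrix),
#'   \code{sampleModules} (\linkS4class{NodeLabeling}), \code{geneSets}
#'   (\linkS4class{DisorderGeneSets}) and \code{planted} (the spec's
#'   triples).
#' @export
generateExpression <- function(spec, p = NULL) {
  stopifnot(inherits(spec, "gsfcSyntheticSpec"))
  set.seed(spec$seed + 1L)
  modules <- if (is.null(p)) paste0("B", seq_along(spec$moduleSizes))
             else unique(p@labels)
  nSamp <- length(modules) * spec$samplesPerModule
  genes <- sprintf("G%04d", seq_len(spec$nGenes))
  sampleIds <- sprintf("s%04d", seq_len(nSamp))
  sampleMod <- rep(modules, each = spec$samplesPerModule)
  expr <- matrix(stats::rnorm(nSamp * spec$nGenes), nSamp, spec$nGenes,
                 dimnames = list(sampleIds, genes))
  perm <- sample(spec$nGenes)
  sets <- lapply(seq_len(spec$nSets), function(i) {
    genes[perm[((i - 1) * spec$genesPerSet + 1):(i * spec$genesPerSet)]]
  })
  names(sets) <- paste0("D", seq_len(spec$nSets))
  groups <- character()
  if (spec$nGroups > 0) {
    groups <- paste0("Grp", rep(seq_len(spec$nGroups), length.out = spec$nSets))
    names(groups) <- names(sets)
  }
  for (tr in spec$planted) {
    if (!tr$module %in% modules)
      parameterError(sprintf("planted module '%s' does not exist", tr$module))
    if (!tr$set %in% names(sets))
      parameterError(sprintf("planted set '%s' does not exist", tr$set))
    rows <- which(sampleMod == tr$module)
    cols <- match(sets[[tr$set]], genes)
    expr[rows, cols] <- expr[rows, cols] + tr$effect
  }
  list(
    expression = expr,
    sampleModules = new("NodeLabeling", nodeIds = sampleIds, labels = sampleMod),
    geneSets = new("DisorderGeneSets", sets = sets, groups = groups),
    planted = spec$planted
  )
}
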