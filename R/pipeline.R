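#' Run the full fusion pipeline from a configuration
#'
#' Chains the stages build-population -> fuse-grid -> tree -> optimize ->
#' metrics -> annotate -> genetics, writing every stage's output as files in
#' \code{outDir} so any stage can be rerun in isolation, plus a JSON
#' provenance record (input hashes, parameters, seed, package version). A
#' stage failure aborts with the failing stage named; outputs already
#' written are retained.
#'
#' Configuration (JSON file or list): either \code{synthetic} (arguments to
#' \code{\link{syntheticSpec}}) or \code{scDir}/\code{fcDir} with
#' per-subject TSV matrices paired by sorted filename; optional
#' \code{gammas}, \code{mRange} (two integers), \code{minModuleSize},
#' \code{tfsStrategy}, \code{fcRule}, \code{atlas} (labeling TSV),
#' \code{expression} (list with \code{path}, \code{labels}, \code{gmt}),
#' \code{seed}.
#'
#' @param config list or path to a JSON file.
#' @param outDir output directory (created if absent).
#' @return invisibly, a list with the \linkS4class{PopulationPair}, the
#'   \linkS4class{CrossModularityGrid} and the output paths.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) formatError(sprintf("config not found: %s", config))
    configPath <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else configPath <- NULL
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(outDir, ...)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  prov <- list(package = "gammaSFC",
               version = as.character(utils::packageVersion("gammaSFC")),
               seed = config$seed, parameters = config, inputs = list())

  truth <- NULL
  cohort <- stage("load-subjects", function() {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- config$seed
      if (!is.null(args$moduleSizes)) args$moduleSizes <- as.integer(args$moduleSizes)
      co <- generateCohort(do.call(syntheticSpec, args))
      writePartition(co$truth, out("ground_truth_partition.tsv"))
      co$subjects
    } else {
      if (is.null(config$scDir) || is.null(config$fcDir))
        formatError("config needs either 'synthetic' or 'scDir'/'fcDir'")
      for (d in c(config$scDir, config$fcDir))
        if (!dir.exists(d)) formatError(sprintf("input directory not found: %s", d))
      scFiles <- sort(list.files(config$scDir, full.names = TRUE))
      fcFiles <- sort(list.files(config$fcDir, full.names = TRUE))
      if (length(scFiles) != length(fcFiles) || length(scFiles) == 0)
        validationError("scDir and fcDir must hold equal, nonzero subject counts")
      prov$inputs$sc <<- as.list(tools::md5sum(scFiles))
      prov$inputs$fc <<- as.list(tools::md5sum(fcFiles))
      mapply(function(s, f) list(
        sc = readConnectivityMatrix(s, "structural"),
        fc = readConnectivityMatrix(f, "functional")
      ), scFiles, fcFiles, SIMPLIFY = FALSE)
    }
  })
  if (!is.null(config$synthetic) && file.exists(out("ground_truth_partition.tsv")))
    truth <- readPartition(out("ground_truth_partition.tsv"))

  pair <- stage("build-population", function() {
    scPop <- populationMedian(lapply(cohort, `[[`, "sc"))
    fcPop <- populationMedian(lapply(cohort, `[[`, "fc"))
    fcRule <- if (is.null(config$fcRule)) "positive" else config$fcRule
    pr <- matchDensityAndBinarize(scPop, fcPop, fcRule = fcRule)
    writeConnectivityMatrix(pr@scRaw, out("sc_population.tsv"))
    writeConnectivityMatrix(pr@fcRaw, out("fc_population.tsv"))
    writeConnectivityMatrix(pr@scBin, out("sc_population_bin.tsv"))
    writeConnectivityMatrix(pr@fcBin, out("fc_population_bin.tsv"))
    pr
  })

  gammas <- if (is.null(config$gammas)) defaultGammaGrid() else as.numeric(config$gammas)
  mRange <- if (is.null(config$mRange)) 2:120 else
    seq(config$mRange[1], config$mRange[2])
  minModuleSize <- if (is.null(config$minModuleSize)) 3 else config$minModuleSize
  tfsStrategy <- if (is.null(config$tfsStrategy)) "link-dice" else config$tfsStrategy

  grid <- stage("optimize", function() {
    g <- optimizeCrossModularity(pair, gammas = gammas, mRange = mRange,
                                 minModuleSize = minModuleSize,
                                 tfsStrategy = tfsStrategy)
    utils::write.table(gridAsDataFrame(g), out("cross_modularity_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writePartition(g@optimum$partition, out("optimal_partition.tsv"))
    g
  })

  stage("tree", function() {
    fusedOpt <- fuseConnectivity(pair, grid@optimum$gamma)
    tree <- buildMergeTree(fusedOpt)
    writeMergeTable(tree, out("optimal_tree_merges.tsv"))
    treeToNewick(tree, out("optimal_tree.nwk"))
    tm <- treeMetrics(tree, grid@optimum$m)
    utils::write.table(tm$modules, out("tree_metrics_modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tm$leaves, out("tree_metrics_leaves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("metrics", function() {
    fusedOpt <- fuseConnectivity(pair, grid@optimum$gamma)
    st <- nodeStrength(fusedOpt)
    utils::write.table(st, out("node_strength.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    seg <- moduleSegregation(fusedOpt, grid@optimum$partition)
    utils::write.table(seg, out("module_segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (!is.null(config$atlas)) stage("annotate", function() {
    atlas <- readNodeLabeling(config$atlas)
    prov$inputs$atlas <<- as.list(tools::md5sum(config$atlas))
    ov <- overlapMatrix(grid@optimum$partition, atlas, mode = "fraction")
    utils::write.table(data.frame(module = rownames(ov), ov, check.names = FALSE),
                       out("atlas_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (!is.null(config$expression) || !is.null(config$synthetic)) {
    stage("genetics", function() {
      if (!is.null(config$expression)) {
        exprTab <- utils::read.delim(config$expression$path, row.names = 1,
                                     check.names = FALSE)
        labeling <- readNodeLabeling(config$expression$labels)
        sets <- readGeneSets(config$expression$gmt)
        prov$inputs$expression <<- as.list(tools::md5sum(config$expression$path))
        expr <- aggregateSamples(as.matrix(exprTab), labeling)
      } else {
        args <- config$synthetic
        if (is.null(args$seed)) args$seed <- config$seed
        if (!is.null(args$moduleSizes)) args$moduleSizes <- as.integer(args$moduleSizes)
        gx <- generateExpression(do.call(syntheticSpec, args), truth)
        writeGeneSets(gx$geneSets, out("gene_sets.gmt"))
        sets <- gx$geneSets
        expr <- aggregateSamples(gx$expression, gx$sampleModules)
      }
      sc <- disorderScores(expr, sets)
      utils::write.table(sc, out("disorder_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(sets@groups) > 0) {
        gsc <- groupScores(expr, sets)
        utils::write.table(gsc, out("group_scores.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  prov$outputs <- as.list(tools::md5sum(sort(list.files(outDir, full.names = TRUE,
                                                        pattern = "\\.(tsv|nwk|gmt)$"))))
  if (!is.null(configPath)) prov$inputs$config <- as.list(tools::md5sum(configPath))
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(pair = pair, grid = grid, outDir = outDir))
}
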