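moduleExpr <- function(values, modules = rownames(values), genes = colnames(values)) {
  new("ModuleExpression", modules = modules, genes = genes,
      values = values, nSamples = rep(1L, nrow(values)))
}

test_that("sample aggregation averages within modules", {
  m <- matrix(c(1, 3, 5, 7), 2, 2, dimnames = list(c("s1", "s2"), c("g1", "g2")))
  lab <- makeLabeling(c("s1", "s2"), c("M1", "M2"))
  expr <- aggregateSamples(m, lab)
  expect_identical(unname(expr@values), unname(m))  # one sample per module: identity
  expect_identical(expr@modules, c("M1", "M2"))

  lab2 <- makeLabeling(c("s1", "s2"), c("M1", "M1"))
  expr2 <- aggregateSamples(m, lab2)
  expect_equal(unname(expr2@values[1, ]), c(2, 6))

  withr::local_seed(81)
  big <- matrix(rnorm(60), 12, 5,
                dimnames = list(sprintf("s%02d", 1:12), paste0("g", 1:5)))
  labels <- sample(c("A", "B", "C"), 12, replace = TRUE)
  labR <- makeLabeling(rownames(big), labels)
  ex <- aggregateSamples(big, labR)
  for (mod in unique(labels)) {
    expect_equal(unname(ex@values[mod, ]),
                 unname(colMeans(big[labels == mod, , drop = FALSE])),
                 tolerance = 1e-12)
  }

  lab3 <- new("NodeLabeling", nodeIds = c(rownames(big), "s99"),
              labels = c(labels, "GHOST"))
  expect_warning(aggregateSamples(big, lab3), "GHOST")
  expect_error(aggregateSamples(big[0, , drop = FALSE], labR),
               class = "gsfc_validation_error")
})

test_that("disorder z-scores match hand computation and flag thresholds", {
  vals <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("M", 1:3), "GENEA"))
  expr <- moduleExpr(vals)
  sets <- new("DisorderGeneSets", sets = list(D1 = "genea"), groups = character())
  sc <- disorderScores(expr, sets)  # matching is case-insensitive
  expect_equal(sc$z, c(-1, 0, 1))
  expect_identical(sc$flag, rep("none", 3))
  expect_identical(sc$n_genes_matched, rep(1L, 3))

  flat <- moduleExpr(matrix(2, 3, 1, dimnames = list(paste0("M", 1:3), "GENEA")))
  scFlat <- disorderScores(flat, sets)
  expect_true(all(is.na(scFlat$z)))
  expect_identical(scFlat$flag, rep("none", 3))

  miss <- new("DisorderGeneSets", sets = list(DX = "NOPE"), groups = character())
  expect_error(disorderScores(expr, miss), class = "gsfc_gene_match_error")
})

test_that("z-scores across modules have zero mean and unit sample sd", {
  withr::local_seed(82)
  vals <- matrix(rnorm(26 * 30), 26, 30,
                 dimnames = list(paste0("M", 1:26), paste0("G", 1:30)))
  expr <- moduleExpr(vals)
  sets <- new("DisorderGeneSets",
              sets = list(D1 = paste0("G", 1:10), D2 = paste0("G", 11:30)),
              groups = character())
  sc <- disorderScores(expr, sets)
  for (d in c("D1", "D2")) {
    z <- sc$z[sc$disorder == d]
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
  }
})

test_that("z-scores are invariant under affine rescaling of expression", {
  withr::local_seed(83)
  vals <- matrix(rnorm(8 * 12), 8, 12,
                 dimnames = list(paste0("M", 1:8), paste0("G", 1:12)))
  sets <- new("DisorderGeneSets", sets = list(D = paste0("G", 1:5)),
              groups = character())
  z1 <- disorderScores(moduleExpr(vals), sets)$z
  z2 <- disorderScores(moduleExpr(3.7 * vals + 11), sets)$z
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("a strongly over-expressed planted module is flagged high", {
  withr::local_seed(84)
  vals <- matrix(rnorm(10 * 20), 10, 20,
                 dimnames = list(paste0("M", 1:10), paste0("G", 1:20)))
  vals["M4", 1:6] <- vals["M4", 1:6] + 4  # + 4 noise-sd shift
  sets <- new("DisorderGeneSets", sets = list(D = paste0("G", 1:6)),
              groups = character())
  sc <- disorderScores(moduleExpr(vals), sets)
  expect_identical(sc$flag[sc$module == "M4"], "high")
  expect_identical(sum(sc$flag == "high"), 1L)
})

test_that("median summary is available as an alternative to the mean", {
  vals <- matrix(c(1, 2, 100,   2, 3, 100,  0, 1, 100), 3, 3, byrow = TRUE,
                 dimnames = list(paste0("M", 1:3), paste0("G", 1:3)))
  sets <- new("DisorderGeneSets", sets = list(D = paste0("G", 1:3)),
              groups = character())
  scMean <- disorderScores(moduleExpr(vals), sets, stat = "mean")
  scMed <- disorderScores(moduleExpr(vals), sets, stat = "median")
  expect_equal(scMed$mean_expression, apply(vals, 1, median), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(scMean$mean_expression, scMed$mean_expression)))
})

test_that("group scores pool the union of member-disorder genes", {
  withr::local_seed(85)
  vals <- matrix(rnorm(6 * 10), 6, 10,
                 dimnames = list(paste0("M", 1:6), paste0("G", 1:10)))
  expr <- moduleExpr(vals)

  solo <- new("DisorderGeneSets", sets = list(D1 = paste0("G", 1:4)),
              groups = c(D1 = "GrpA"))
  expect_equal(groupScores(expr, solo)$z,
               disorderScores(expr, new("DisorderGeneSets",
                                        sets = list(D1 = paste0("G", 1:4)),
                                        groups = character()))$z)

  two <- new("DisorderGeneSets",
             sets = list(D1 = paste0("G", 1:4), D2 = paste0("G", 5:7),
                         D3 = paste0("G", 8:10)),
             groups = c(D1 = "GrpA", D2 = "GrpA", D3 = "GrpB"))
  gsc <- groupScores(expr, two)
  pooled <- rowMeans(vals[, 1:7])
  expect_equal(gsc$mean_expression[gsc$disorder == "GrpA"], unname(pooled),
               tolerance = 1e-12)

  noGroups <- new("DisorderGeneSets", sets = list(D1 = "G1"), groups = character())
  expect_error(groupScores(expr, noGroups), class = "gsfc_validation_error")

  # a gene shared by two member disorders counts once in the pooled set
  shared <- new("DisorderGeneSets",
                sets = list(D1 = c("G1", "G2"), D2 = c("G2", "G3")),
                groups = c(D1 = "Grp", D2 = "Grp"))
  gshared <- groupScores(expr, shared)
  expect_equal(gshared$mean_expression, unname(rowMeans(vals[, 1:3])),
               tolerance = 1e-12)
})
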