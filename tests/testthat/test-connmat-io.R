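test_that("TSV matrix reading validates shape, symmetry and range", {
  tmp <- withr::local_tempfile(fileext = ".tsv")

  zeros <- matrix(0, 3, 3)
  writeTsvMatrix(zeros, c("a", "b", "c"), tmp)
  m <- readConnectivityMatrix(tmp, "structural")
  expect_identical(nodeIds(m), c("a", "b", "c"))
  expect_true(all(connValues(m) == 0))

  asym <- zeros; asym[1, 2] <- 5; asym[2, 1] <- 4
  writeTsvMatrix(asym, c("a", "b", "c"), tmp)
  expect_error(readConnectivityMatrix(tmp, "structural"),
               class = "gsfc_validation_error")

  writeLines(c("node_id\ta\tb\tc", "a\t0\t1\t2", "b\t1\t0\t3"), tmp)
  expect_error(readConnectivityMatrix(tmp, "structural"),
               class = "gsfc_format_error")

  fun <- matrix(c(0, 0.9, 0.2, 0.9, 0, -0.3, 0.2, -0.3, 0), 3, 3)
  diag(fun) <- 7  # diagonal must be discarded on load
  writeTsvMatrix(fun, c("a", "b", "c"), tmp)
  f <- readConnectivityMatrix(tmp, "functional")
  expect_identical(diag(connValues(f)), c(a = 0, b = 0, c = 0))
  expect_equal(connValues(f)["a", "b"], 0.9)
  expect_equal(connValues(f)["b", "c"], -0.3)
  expect_identical(connValues(f), t(connValues(f)))

  bad <- fun; bad[1, 2] <- bad[2, 1] <- 1.5
  writeTsvMatrix(bad, c("a", "b", "c"), tmp)
  expect_error(readConnectivityMatrix(tmp, "functional"),
               class = "gsfc_validation_error")
})

test_that("matrix write/read round-trip is the identity within 1e-12", {
  withr::local_seed(11)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  v <- randomSymWeighted(7)
  m <- makeConn(v, sprintf("r%02d", 1:7), "structural")
  writeConnectivityMatrix(m, tmp)
  m2 <- readConnectivityMatrix(tmp, "structural")
  expect_identical(nodeIds(m2), nodeIds(m))
  expect_lt(max(abs(connValues(m2) - connValues(m))), 1e-12)
})

test_that("GMT parsing handles the standard dialect and its edge cases", {
  tmp <- withr::local_tempfile(fileext = ".gmt")

  writeLines("D1\tdesc\tGENEA\tGENEB", tmp)
  gs <- readGeneSets(tmp)
  expect_identical(geneSets(gs), list(D1 = c("GENEA", "GENEB")))

  writeLines("D1\tdesc\tGENEA\tGENEA", tmp)
  expect_warning(gs <- readGeneSets(tmp), "de-duplicated")
  expect_identical(geneSets(gs)$D1, "GENEA")

  writeLines("D1\tdesc", tmp)
  expect_error(readGeneSets(tmp), class = "gsfc_format_error")

  writeLines(c("D1\tdesc\tA", "D1\tdesc\tB"), tmp)
  expect_error(readGeneSets(tmp), class = "gsfc_format_error")

  # 40-disorder collection round-trips through write + read
  sets <- new("DisorderGeneSets",
              sets = setNames(lapply(1:40, function(i) paste0("G", i, "_", 1:5)),
                              paste0("DIS", 1:40)),
              groups = character())
  writeGeneSets(sets, tmp)
  back <- readGeneSets(tmp)
  expect_length(geneSets(back), 40)
  expect_identical(geneSets(back), geneSets(sets))
})

test_that("partition TSV round-trips and validates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")

  p <- makePartition(paste0("n", 1:5), c("A", "A", "B", "C", "B"))
  writePartition(p, tmp)
  p2 <- readPartition(tmp)
  expect_identical(nodeIds(p2), nodeIds(p))
  expect_identical(nodeLabels(p2), nodeLabels(p))
  expect_identical(nModules(p2), 3L)

  file.create(tmp)
  expect_error(readPartition(tmp), class = "gsfc_format_error")

  writePartition(p, tmp)
  expect_error(readPartition(tmp, nodeIds = paste0("x", 1:5)),
               class = "gsfc_validation_error")

  # a partition at the scale of the largest parcellation round-trips
  withr::local_seed(7)
  big <- makePartition(sprintf("r%04d", 1:2165),
                       sample(paste0("M", 1:26), 2165, replace = TRUE))
  writePartition(big, tmp)
  big2 <- readPartition(tmp)
  expect_identical(nodeLabels(big2), nodeLabels(big))
})

test_that("merge-table and Newick exports preserve the dendrogram", {
  withr::local_seed(3)
  v <- randomSymWeighted(9)
  tree <- buildMergeTree(makeConn(v, letters[1:9], "fused"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeMergeTable(tree, tmp)
  back <- readMergeTable(tmp)
  expect_equal(back@height, tree@height, tolerance = 1e-12)
  for (m in c(2, 4, 7)) {
    expect_equal(partitionAgreement(cutTree(back, m), cutTree(tree, m)), 1)
  }
  nwk <- withr::local_tempfile(fileext = ".nwk")
  treeToNewick(tree, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, letters[1:9])
})
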