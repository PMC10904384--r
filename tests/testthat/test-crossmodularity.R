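test_that("modularity reproduces hand-computed and degenerate cases", {
  # two disjoint 2-cliques: edges ab and cd
  v <- matrix(0, 4, 4); v[1, 2] <- 1; v[3, 4] <- 1; v <- v + t(v)
  adj <- makeConn(v, letters[1:4], weighted = FALSE)
  p <- makePartition(letters[1:4], c("A", "A", "B", "B"))
  expect_equal(newmanModularity(adj, p), 0.5)

  one <- makePartition(letters[1:4], rep("A", 4))
  expect_equal(newmanModularity(adj, one), 0)

  empty <- makeConn(matrix(0, 3, 3), letters[1:3], weighted = FALSE)
  expect_error(newmanModularity(empty, makePartition(letters[1:3], 1:3)),
               class = "gsfc_empty_graph_error")
})

test_that("modularity matches the counting oracle on random graphs", {
  withr::local_seed(51)
  for (trial in 1:50) {
    n <- sample(4:8, 1)
    v <- randomSymBinary(n, runif(1, 0.3, 0.8))
    if (sum(v) == 0) next
    labels <- sample(paste0("M", 1:sample(2:4, 1)), n, replace = TRUE)
    adj <- makeConn(v, paste0("n", 1:n), weighted = FALSE)
    p <- makePartition(paste0("n", 1:n), labels)
    expect_equal(newmanModularity(adj, p), oracleModularity(v, labels),
                 tolerance = 1e-10)
  }
})

test_that("modularity agrees with igraph on random partitions", {
  skip_if_not_installed("igraph")
  withr::local_seed(52)
  for (trial in 1:10) {
    v <- randomSymBinary(8, 0.5)
    if (sum(v) == 0) next
    labels <- sample(1:3, 8, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(v, mode = "undirected")
    expect_equal(
      newmanModularity(makeConn(v, paste0("n", 1:8), weighted = FALSE),
                       makePartition(paste0("n", 1:8), labels)),
      igraph::modularity(g, membership = labels),
      tolerance = 1e-10)
  }
})

test_that("DICE similarity covers identity, disjoint and partial overlap", {
  expect_equal(diceCoefficient(c("a", "b"), c("a", "b")), 1)
  expect_equal(diceCoefficient(c("a", "b"), c("c", "d")), 0)
  expect_equal(diceCoefficient(c("a", "b"), c("b", "c")), 0.5)
  expect_error(diceCoefficient(character(0), character(0)),
               class = "gsfc_undefined_dice_error")
})

test_that("link-overlap T_FS behaves at its boundary cases", {
  withr::local_seed(53)
  sc <- randomSymBinary(8, 0.5)
  ids <- paste0("n", 1:8)
  p <- makePartition(ids, rep(c("A", "B"), each = 4))

  expect_equal(moduleSimilarity(binPair(sc, sc), p), 1)

  # intra-module links disjoint between FC and SC in every module
  scd <- matrix(0, 4, 4); scd[1, 2] <- 1; scd <- scd + t(scd)
  fcd <- matrix(0, 4, 4); fcd[3, 4] <- 1; fcd <- fcd + t(fcd)
  pd <- makePartition(paste0("n", 1:4), rep("A", 4))
  expect_equal(moduleSimilarity(binPair(scd, fcd), pd), 0)

  expect_error(moduleSimilarity(binPair(sc, sc), p, strategy = "bogus"),
               class = "gsfc_parameter_error")
})

test_that("link-overlap T_FS matches pair enumeration and is symmetric", {
  withr::local_seed(54)
  for (trial in 1:20) {
    n <- sample(5:10, 1)
    sc <- randomSymBinary(n, 0.5)
    fc <- randomSymBinary(n, 0.5)
    labels <- sample(paste0("M", 1:3), n, replace = TRUE)
    p <- makePartition(paste0("n", 1:n), labels)
    t1 <- moduleSimilarity(binPair(sc, fc), p)
    expect_equal(t1, oracleLinkDice(fc, sc, labels), tolerance = 1e-10)
    expect_equal(t1, moduleSimilarity(binPair(fc, sc), p), tolerance = 1e-12)
  }
})

test_that("node-set T_FS equals one for identical modality trees", {
  withr::local_seed(55)
  v <- cliqueUnion(2, 4) + randomSymBinary(8, 0.1)
  v[v > 1] <- 1
  p <- makePartition(paste0("n", 1:8), rep(c("A", "B"), each = 4))
  expect_equal(moduleSimilarity(binPair(v, v), p, strategy = "node-dice"), 1)
})

test_that("chi is the signed cube root of the factor product", {
  expect_equal(chiStat(0.5, 0.5, 0.5), 0.5)
  expect_equal(chiStat(1, 1, 1), 1)
  expect_equal(chiStat(0.4, 0.9, 0.6), 0.6)
  expect_true(is.na(chiStat(-0.1, 0.5, 0.5)))
  expect_true(is.na(chiStat(0.5, 0.5, NA)))
})

test_that("chi is monotone increasing in each nonnegative factor", {
  withr::local_seed(56)
  for (trial in 1:50) {
    x <- runif(3); eps <- runif(1, 0.01, 0.3)
    expect_gt(chiStat(x[1] + eps, x[2], x[3]), chiStat(x[1], x[2], x[3]))
    expect_gt(chiStat(x[1], x[2] + eps, x[3]), chiStat(x[1], x[2], x[3]))
    expect_gt(chiStat(x[1], x[2], x[3] + eps), chiStat(x[1], x[2], x[3]))
  }
})

test_that("the (gamma, M) search maximizes chi at the planted scale", {
  v <- cliqueUnion(4, 5)
  pair <- binPair(v, v)
  grid <- optimizeCrossModularity(pair, gammas = c(0, 0.5, 1), mRange = 2:10)
  o <- optimum(grid)
  expect_identical(o$m, 4L)
  # Q of the planted 4-clique partition in closed form: 4 * (1/4 - 1/16)
  expect_equal(o$chi, (0.75 * 0.75 * 1)^(1 / 3), tolerance = 1e-10)
  expect_equal(o$qf, 0.75, tolerance = 1e-10)
  # per-gamma maxima all sit at M = 4
  expect_true(all(apply(grid@chi, 1, which.max) == which(grid@moduleCounts == 4)))
  # identical modalities make the surface gamma-invariant
  expect_true(all(abs(sweep(grid@chi, 2, grid@chi[1, ])) < 1e-12))
})

test_that("small modules are counted as invalid at the optimum", {
  v <- cliqueUnion(4, 5)
  # append a detached 2-node dyad that forms its own tiny module
  n <- nrow(v) + 2
  w <- matrix(0, n, n)
  w[1:nrow(v), 1:nrow(v)] <- v
  w[21, 22] <- w[22, 21] <- 1
  pair <- binPair(w, w)
  grid <- optimizeCrossModularity(pair, gammas = 0.5, mRange = 2:10,
                                  minModuleSize = 3)
  o <- optimum(grid)
  tabSizes <- table(nodeLabels(o$partition))
  expect_identical(o$nValidModules, sum(tabSizes >= 3))
  expect_lt(o$nValidModules, o$m)
})

test_that("grid search validates its parameters", {
  pair <- binPair(cliqueUnion(2, 3), cliqueUnion(2, 3))
  expect_error(optimizeCrossModularity(pair, gammas = numeric(0)),
               class = "gsfc_parameter_error")
  expect_error(optimizeCrossModularity(pair, gammas = c(0.5, 1.4)),
               class = "gsfc_parameter_error")
  expect_error(optimizeCrossModularity(pair, mRange = 200:300),
               class = "gsfc_parameter_error")
})
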