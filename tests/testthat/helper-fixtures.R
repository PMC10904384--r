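# Fixtures built in code; no files on disk beyond tempfiles created per test.

makeConn <- function(values, ids = NULL, modality = "structural",
                     weighted = TRUE) {
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(values)))
  connectivityMatrix(values, ids, modality, weighted = weighted)
}

randomSymBinary <- function(n, p = 0.4) {
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- rbinom(n * (n - 1) / 2, 1, p)
  v + t(v)
}

randomSymWeighted <- function(n, max = 10) {
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0, max)
  v + t(v)
}

# PopulationPair assembled directly from two binary symmetric matrices
binPair <- function(scMat, fcMat, ids = NULL) {
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(scMat)))
  new("PopulationPair",
      scBin = makeConn(scMat, ids, "structural", weighted = FALSE),
      fcBin = makeConn(fcMat, ids, "functional", weighted = FALSE),
      scRaw = makeConn(scMat, ids, "structural"),
      fcRaw = makeConn(fcMat, ids, "functional"),
      density = sum(scMat[upper.tri(scMat)] > 0) / (nrow(scMat) * (nrow(scMat) - 1) / 2),
      nLinks = as.integer(sum(scMat[upper.tri(scMat)] > 0)),
      tieCount = 0L)
}

# block-diagonal union of k cliques of equal size
cliqueUnion <- function(k, size) {
  n <- k * size
  v <- matrix(0, n, n)
  for (b in seq_len(k)) {
    idx <- ((b - 1) * size + 1):(b * size)
    v[idx, idx] <- 1
  }
  diag(v) <- 0
  v
}

# chain dendrogram over leaves a,b,c,d: merge ab, then abc, then abcd
chainTree <- function() {
  new("MergeTree", nLeaves = 4L,
      merge = matrix(c(-1L, -2L, 1L, -3L, 2L, -4L), ncol = 2, byrow = TRUE),
      height = c(0.2, 0.5, 0.9), order = 1:4,
      leafIds = c("a", "b", "c", "d"), method = "mcquitty")
}

makePartition <- function(ids, labels) {
  new("Partition", nodeIds = ids, labels = as.character(labels),
      nModules = length(unique(labels)))
}

makeLabeling <- function(ids, labels) {
  new("NodeLabeling", nodeIds = ids, labels = as.character(labels))
}

writeTsvMatrix <- function(values, ids, path) {
  df <- data.frame(node_id = ids, values, check.names = FALSE)
  colnames(df) <- c("node_id", ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
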