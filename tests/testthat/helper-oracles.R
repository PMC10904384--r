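# Independent brute-force oracles. These deliberately use naive loops and
# set enumeration, never the package's own code paths.

oracleMedian <- function(vals) {
  s <- sort(vals)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Newman-Girvan Q by explicit link and degree counting
oracleModularity <- function(adj, labels) {
  n <- nrow(adj)
  L <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) L <- L + adj[i, j]
  q <- 0
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    lc <- 0
    for (i in idx) for (j in idx) if (i < j) lc <- lc + adj[i, j]
    dc <- 0
    for (i in idx) dc <- dc + sum(adj[i, ])
    q <- q + lc / L - (dc / (2 * L))^2
  }
  q
}

oracleDice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0
  for (x in a) if (x %in% b) inter <- inter + 1
  2 * inter / (length(a) + length(b))
}

# link-overlap T_FS by enumerating every node pair
oracleLinkDice <- function(fc, sc, labels) {
  n <- nrow(fc)
  vals <- c()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    nf <- ns <- nb <- 0
    for (i in idx) for (j in idx) if (i < j) {
      if (fc[i, j] > 0) nf <- nf + 1
      if (sc[i, j] > 0) ns <- ns + 1
      if (fc[i, j] > 0 && sc[i, j] > 0) nb <- nb + 1
    }
    if (nf + ns > 0) vals <- c(vals, 2 * nb / (nf + ns))
  }
  if (length(vals) == 0) 0 else mean(vals)
}

oracleSegregation <- function(w, labels) {
  out <- c()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    k <- length(idx)
    if (k < 2) { out <- c(out, NA); next }
    s <- 0
    for (i in idx) for (j in idx) if (i != j) s <- s + w[i, j]
    out <- c(out, s / (k * (k - 1)))
  }
  out
}

oracleOverlapFraction <- function(modLabels, atlasLabels) {
  mods <- unique(modLabels)
  labs <- sort(unique(atlasLabels))
  m <- matrix(0, length(mods), length(labs), dimnames = list(mods, labs))
  for (i in seq_along(mods)) for (j in seq_along(labs)) {
    inMod <- which(modLabels == mods[i])
    inLab <- which(atlasLabels == labs[j])
    m[i, j] <- length(intersect(inMod, inLab)) / length(inMod)
  }
  m
}

oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# O(N^3) WPGMA agglomerator over a dissimilarity matrix. Returns one row per
# merge: the two leaf sets joined (sorted leaf indices) and the distance.
oracleWPGMA <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dist <- d
  diag(dist) <- Inf
  merges <- list()
  cur <- dist
  members <- active
  alive <- rep(TRUE, n)
  idx <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    ids <- which(alive)
    for (a in ids) for (b in ids) if (a < b && cur[a, b] < best) {
      best <- cur[a, b]; bi <- a; bj <- b
    }
    merges[[step]] <- list(left = sort(members[[bi]]),
                           right = sort(members[[bj]]),
                           height = best)
    # WPGMA update: simple average of the two children's distances
    for (x in ids) if (x != bi && x != bj)
      cur[bi, x] <- cur[x, bi] <- (cur[bi, x] + cur[bj, x]) / 2
    members[[bi]] <- c(members[[bi]], members[[bj]])
    alive[bj] <- FALSE
    cur[bj, ] <- cur[, bj] <- Inf
  }
  merges
}

# leaf sets of the cluster formed at each merge step of a MergeTree
mergeLeafSets <- function(tree) {
  mg <- connValuesMerge(tree)
  n <- nLeaves(tree)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    lv <- function(j) if (j < 0) -j else sets[[j]]
    sets[[k]] <- sort(c(lv(mg[k, 1]), lv(mg[k, 2])))
  }
  sets
}

connValuesMerge <- function(tree) tree@merge
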