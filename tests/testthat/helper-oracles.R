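# Independent brute-force oracles, deliberately written with plain loops
# and set operations so they share no code with the package internals.

# closed neighbourhood (node plus its interactors) from a raw edge matrix
bfClosedNbhd <- function(edges, node) {
  nb <- node
  for (r in seq_len(nrow(edges))) {
    if (edges[r, 1L] == node) nb <- c(nb, edges[r, 2L])
    if (edges[r, 2L] == node) nb <- c(nb, edges[r, 1L])
  }
  unique(nb)
}

bfFsWeight <- function(edges, nodes, i, j) {
  ni <- bfClosedNbhd(edges, i)
  nj <- bfClosedNbhd(edges, j)
  cc <- length(intersect(ni, nj))
  if (cc == 0L) return(0)
  di <- length(setdiff(ni, nj))
  dj <- length(setdiff(nj, ni))
  navg <- 2 * nrow(edges) / length(nodes)
  lij <- max(0, navg - (di + cc))
  lji <- max(0, navg - (dj + cc))
  (2 * cc / (di + 2 * cc + lij)) * (2 * cc / (dj + 2 * cc + lji))
}

bfMScore <- function(a, b) {
  ov <- 0L
  for (x in unique(a)) if (x %in% b) ov <- ov + 1L
  ov^2 / (length(unique(a)) * length(unique(b)))
}

bfMatchCounts <- function(refList, predList, thres) {
  matchedRef <- logical(length(refList))
  matchedPred <- logical(length(predList))
  nPairs <- 0L
  for (i in seq_along(refList)) {
    for (j in seq_along(predList)) {
      if (bfMScore(refList[[i]], predList[[j]]) >= thres) {
        matchedRef[i] <- TRUE
        matchedPred[j] <- TRUE
        nPairs <- nPairs + 1L
      }
    }
  }
  list(nmc = sum(matchedRef), nmp = sum(matchedPred), pairs = nPairs)
}

bfSharedTerms <- function(annList, u, v) {
  tu <- annList[[u]]
  tv <- annList[[v]]
  if (is.null(tu) || is.null(tv)) return(0L)
  length(intersect(tu, tv))
}

# edge count inside a cluster by a double loop over unordered pairs
bfInternalEdges <- function(cluster, edges) {
  key <- paste(pmin(edges[, 1L], edges[, 2L]),
               pmax(edges[, 1L], edges[, 2L]))
  m <- 0L
  for (i in seq_along(cluster)) {
    for (j in seq_along(cluster)) {
      if (i < j) {
        k <- paste(min(cluster[i], cluster[j]),
                   max(cluster[i], cluster[j]))
        if (k %in% key) m <- m + 1L
      }
    }
  }
  m
}

# Erdos-Renyi style random simple graph over named nodes (uses the
# session RNG; callers fix the seed)
rGraph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  u <- character(0); v <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p) {
        u <- c(u, nodes[i]); v <- c(v, nodes[j])
      }
    }
  }
  list(nodes = nodes, u = u, v = v)
}

# random complex list over a protein universe
rComplexList <- function(nComplexes, universe, sizeMin = 3L, sizeMax = 6L) {
  lapply(seq_len(nComplexes), function(i)
    sample(universe, sample(sizeMin:sizeMax, 1L)))
}

# tiny fully-specified fixture shared by several suites: two cliques
# (K5, K4) joined by one bridge, each clique sharing a private GO term
bridgeFixture <- function() {
  a <- paste0("A", 1:5)
  b <- paste0("B", 1:4)
  pairs <- rbind(t(combn(a, 2L)), t(combn(b, 2L)), c("A1", "B1"))
  net <- ppiNetwork(pairs[, 1L], pairs[, 2L], kind = "dynamic")
  ann <- annotationMap(c(
    setNames(rep(list("GO:a"), 5), a),
    setNames(rep(list("GO:b"), 4), b)))
  list(net = net, ann = ann, cliqueA = sort(a), cliqueB = sort(b))
}

# collapse a replicate-bearing series through the writer/reader pair
readBack <- function(sim) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeExpression(sim$expression, f)
  readExpression(f)
}
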