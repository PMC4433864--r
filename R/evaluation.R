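#' @include gecluster.R
NULL

#' Matching score between two complexes
#'
#' Neighbourhood-affinity overlap score between protein sets A and B:
#' \deqn{M(A,B) = \frac{|V_A \cap V_B|^2}{|V_A| \cdot |V_B|}}
#' Symmetric, 0 iff disjoint, 1 iff the sets are identical.
#'
#' @param a,b character vectors of member identifiers (non-empty).
#' @return score in [0, 1].
#' @export
mScore <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("mScore requires non-empty complexes")
  ov <- length(intersect(a, b))
  ov * ov / (length(a) * length(b))
}

#' Match predicted complexes against a reference set
#'
#' A reference complex A and a predicted complex B match when
#' `mScore(A, B) >= mThres`.  N_mc / N_mp count distinct matched reference
#' / predicted complexes (not pairs).
#'
#' @param ref reference [ComplexSet-class].
#' @param pred predicted [ComplexSet-class].
#' @param mThres matching threshold in (0, 1]; default 0.2, in line with
#'   the complex-prediction literature.
#' @return a [MatchResult-class].
#' @export
matchComplexSets <- function(ref, pred, mThres = 0.2) {
  stopifnot(is(ref, "ComplexSet"), is(pred, "ComplexSet"),
            mThres > 0, mThres <= 1)
  rc <- ref@complexes; pc <- pred@complexes
  hits <- list()
  for (i in seq_along(rc)) {
    for (j in seq_along(pc)) {
      s <- mScore(rc[[i]], pc[[j]])
      if (s >= mThres)
        hits[[length(hits) + 1L]] <- data.frame(ref = i, pred = j,
                                                score = s)
    }
  }
  pairs <- if (length(hits)) do.call(rbind, hits)
           else data.frame(ref = integer(0), pred = integer(0),
                           score = numeric(0))
  new("MatchResult",
      nc = length(rc), np = length(pc),
      nmc = length(unique(pairs$ref)), nmp = length(unique(pairs$pred)),
      mThres = mThres, pairs = pairs)
}

#' Complex-level recall, precision and F1
#'
#' Recall = N_mc / N_c (matched reference complexes over all reference
#' complexes), Precision = N_mp / N_p (matched predictions over all
#' predictions), F1 = 2RP / (R + P).  Zero denominators yield 0 with a
#' warning.
#'
#' @param mr a [MatchResult-class].
#' @return numeric value.
#' @export
complexRecall <- function(mr) {
  stopifnot(is(mr, "MatchResult"))
  if (mr@nc == 0L) {
    warning("empty reference set; recall defined as 0")
    return(0)
  }
  mr@nmc / mr@nc
}

#' @rdname complexRecall
#' @export
complexPrecision <- function(mr) {
  stopifnot(is(mr, "MatchResult"))
  if (mr@np == 0L) {
    warning("empty prediction set; precision defined as 0")
    return(0)
  }
  mr@nmp / mr@np
}

#' @rdname complexRecall
#' @param r,p recall and precision values.
#' @export
complexF1 <- function(r, p) {
  if (r + p == 0) return(0)
  2 * r * p / (r + p)
}

#' Curate a reference complex set against a network
#'
#' Restricts each reference complex to proteins present in the evaluated
#' network and drops complexes whose surviving membership falls below
#' `minSize` -- benchmark complexes whose members are not expressed under
#' the condition cannot be recovered and are excluded from N_c.
#'
#' @param set a [ComplexSet-class].
#' @param net a [PPINetwork-class] or [CombinedNetwork-class] (or a
#'   character vector of node identifiers).
#' @param minSize minimum surviving size (default 3).
#' @return a curated [ComplexSet-class] (never larger than `set`).
#' @export
curateComplexSet <- function(set, net, minSize = 3L) {
  stopifnot(is(set, "ComplexSet"))
  nodes <- if (is.character(net)) net else networkNodes(net)
  kept <- lapply(set@complexes, function(m) m[m %in% nodes])
  keep <- lengths(kept) >= minSize
  complexSet(kept[keep], labels = set@labels[keep])
}

#' Summary statistics of a PPI network
#'
#' Clustering coefficient is the mean local clustering coefficient over
#' all nodes (nodes of degree < 2 contribute 0); the characteristic path
#' length is the mean shortest-path length over connected node pairs; the
#' diameter is the maximum shortest-path length over connected pairs.
#' Path statistics of disconnected networks are computed over connected
#' pairs only and the component count is reported alongside.
#'
#' @param net a [PPINetwork-class].
#' @return a [NetworkStats-class].
#' @export
networkStats <- function(net) {
  stopifnot(is(net, "PPINetwork"))
  g <- asIgraph(net)
  n <- igraph::vcount(g)
  cc <- if (n > 0) igraph::transitivity(g, type = "localaverage",
                                        isolates = "zero") else NaN
  dt <- igraph::distance_table(g, directed = FALSE)
  res <- dt$res  # counts of unordered connected pairs at distance 1, 2, ...
  if (sum(res) > 0) {
    cpl <- sum(res * seq_along(res)) / sum(res)
    diam <- max(which(res > 0))
  } else {
    cpl <- NaN
    diam <- NaN
  }
  deg <- igraph::degree(g)
  plHist <- if (sum(res) > 0) {
    stats::setNames(res, seq_along(res))[res > 0]
  } else stats::setNames(integer(0), character(0))
  new("NetworkStats",
      nodeCount = as.integer(n), edgeCount = as.integer(igraph::ecount(g)),
      clusteringCoefficient = as.numeric(cc), diameter = as.numeric(diam),
      characteristicPathLength = as.numeric(cpl),
      componentCount = as.integer(igraph::count_components(g)),
      degreeHistogram = table(deg),
      pathLengthHistogram = as.table(plHist))
}

#' Full complex-level evaluation report
#'
#' Convenience wrapper: optionally curates the reference against the
#' evaluated network, matches, and returns all headline numbers.
#'
#' @param pred predicted [ComplexSet-class].
#' @param ref reference [ComplexSet-class].
#' @param mThres matching threshold (default 0.2).
#' @param curateTo optional network (or node vector) to curate `ref`
#'   against before matching.
#' @param minSize curation size floor (default 3).
#' @return list with the curated reference size, `match`
#'   ([MatchResult-class]) and `recall`, `precision`, `f1`.
#' @export
evaluateComplexes <- function(pred, ref, mThres = 0.2, curateTo = NULL,
                              minSize = 3L) {
  if (!is.null(curateTo))
    ref <- curateComplexSet(ref, curateTo, minSize = minSize)
  mr <- matchComplexSets(ref, pred, mThres = mThres)
  r <- if (mr@nc > 0L) mr@nmc / mr@nc else 0
  p <- if (mr@np > 0L) mr@nmp / mr@np else 0
  list(nRef = mr@nc, nPred = mr@np, match = mr,
       recall = r, precision = p, f1 = complexF1(r, p))
}
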