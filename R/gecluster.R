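#' @include similarity.R
NULL

#' Construct a GECluster configuration
#'
#' @param fsMin FS-Weight threshold for strong similarity (default 0.25).
#' @param minSize minimum emitted cluster size (default 3).
#' @param overlap allow proteins already assigned to an emitted cluster to
#'   be re-admitted as members of later clusters (default FALSE).
#' @return a [GEClusterConfig-class].
#' @export
geClusterConfig <- function(fsMin = 0.25, minSize = 3L, overlap = FALSE) {
  new("GEClusterConfig", fsMin = as.numeric(fsMin),
      minSize = as.integer(minSize), overlap = isTRUE(overlap))
}

# weighted adjacency of a combined network as two aligned named lists:
# $nbr[[u]] = neighbour ids, $w[[u]] = edge weights in the same order
.combinedAdjacency <- function(cnet) {
  et <- cnet@edgeTable
  nodes <- cnet@nodes
  nbr <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  w <- lapply(stats::setNames(nodes, nodes), function(x) numeric(0))
  if (nrow(et) > 0L) {
    from <- c(et$u, et$v); to <- c(et$v, et$u); wt <- c(et$weight, et$weight)
    sp <- split(seq_along(from), from)
    for (x in names(sp)) {
      nbr[[x]] <- to[sp[[x]]]
      w[[x]] <- wt[sp[[x]]]
    }
  }
  list(nbr = nbr, w = w)
}

# memoised FS-Weight
.fsCache <- function(ctx) {
  env <- new.env(parent = emptyenv())
  function(i, j) {
    key <- if (i < j) paste(i, j, sep = "\r") else paste(j, i, sep = "\r")
    val <- env[[key]]
    if (is.null(val)) {
      val <- fsWeight(ctx, i, j)
      env[[key]] <- val
    }
    val
  }
}

#' Grow one cluster from a seed protein
#'
#' Starting from the seed alone, repeatedly scans the combined-network
#' neighbours of the current members (the candidate pool) in a
#' deterministic order -- descending total edge weight to current members,
#' then descending FS-Weight to the seed, then lexicographic -- and admits
#' the first candidate that (a) has strong functional similarity
#' (FS-Weight >= fsMin on the dynamic topology) with every current member
#' and (b) does not decrease the cluster density.  Stops when no candidate
#' is admissible.
#'
#' @param seed seed protein identifier.
#' @param combined a [CombinedNetwork-class].
#' @param dynamic the [PPINetwork-class] the FS-Weight context is built
#'   from (shares the combined network's node set).
#' @param cfg a [GEClusterConfig-class].
#' @param excluded identifiers barred from admission (already assigned
#'   proteins when overlap is off).
#' @return character vector of cluster members (sorted), including the
#'   seed.
#' @export
expandSeed <- function(seed, combined, dynamic, cfg = geClusterConfig(),
                       excluded = character(0)) {
  adj <- .combinedAdjacency(combined)
  fs <- .fsCache(fsWeightContext(dynamic))
  sort(.expandSeedImpl(seed, adj, fs, cfg, excluded))
}

# core greedy expansion over prebuilt adjacency + memoised FS
.expandSeedImpl <- function(seed, adj, fs, cfg, excluded) {
  members <- seed
  m <- 0L  # internal combined-edge count
  repeat {
    pool <- setdiff(unique(unlist(adj$nbr[members], use.names = FALSE)),
                    c(members, excluded))
    if (length(pool) == 0L) break
    # deterministic candidate order
    totW <- vapply(pool, function(cand) {
      hit <- adj$nbr[[cand]] %in% members
      sum(adj$w[[cand]][hit])
    }, numeric(1))
    fsSeed <- vapply(pool, function(cand) fs(cand, seed), numeric(1))
    pool <- pool[order(-totW, -fsSeed, pool, method = "radix")]
    added <- FALSE
    n <- length(members)
    for (cand in pool) {
      okFS <- all(vapply(members, function(mm)
        isStrong(fs(cand, mm), cfg@fsMin), logical(1)))
      if (!okFS) next
      dNew <- sum(adj$nbr[[cand]] %in% members)
      if (n >= 2L) {
        cc1 <- 2 * m / (n * (n - 1))
        cc2 <- 2 * (m + dNew) / ((n + 1) * n)
        if (cc2 < cc1 - .DENSITY_TOL) next
      }
      members <- c(members, cand)
      m <- m + dNew
      added <- TRUE
      break
    }
    if (!added) break
  }
  members
}

#' GECluster: seed-expansion protein complex detection
#'
#' Seeds are taken in strictly non-increasing combined-network degree
#' order (all edges, PPI and GO-added, count towards degree; ties broken
#' lexicographically).  Each unassigned seed is grown with [expandSeed()];
#' clusters reaching `minSize` are emitted and, with `overlap = FALSE`,
#' their members are consumed.  Members of discarded sub-minSize clusters
#' remain available to later seeds.  The output is deterministic: the same
#' inputs always produce the same complexes in the same order.
#'
#' @param combined a [CombinedNetwork-class].
#' @param dynamic the [PPINetwork-class] supplying FS-Weight topology
#'   (same node set as `combined`).
#' @param cfg a [GEClusterConfig-class].
#' @param verbose log seed tallies to the console.
#' @return a [ComplexSet-class]; labels are "C1", "C2", ... in emission
#'   order.
#' @export
geCluster <- function(combined, dynamic, cfg = geClusterConfig(),
                      verbose = FALSE) {
  stopifnot(is(combined, "CombinedNetwork"), is(dynamic, "PPINetwork"),
            is(cfg, "GEClusterConfig"))
  validObject(cfg)
  if (!setequal(networkNodes(combined), networkNodes(dynamic)))
    stop("combined and dynamic networks must share a node set")
  nodes <- combined@nodes
  if (length(nodes) == 0L)
    return(complexSet(list()))
  adj <- .combinedAdjacency(combined)
  fs <- .fsCache(fsWeightContext(dynamic))
  degree <- lengths(adj$nbr)[nodes]
  seeds <- nodes[order(-degree, nodes, method = "radix")]
  assigned <- new.env(parent = emptyenv())
  out <- list()
  nDiscard <- 0L
  for (seed in seeds) {
    if (!is.null(assigned[[seed]])) next
    excluded <- if (cfg@overlap) character(0) else ls(assigned)
    members <- .expandSeedImpl(seed, adj, fs, cfg, excluded)
    if (length(members) >= cfg@minSize) {
      out[[length(out) + 1L]] <- sort(members)
      for (mm in members) assigned[[mm]] <- TRUE
    } else {
      nDiscard <- nDiscard + 1L
    }
  }
  if (verbose)
    message(sprintf("GECluster: %d seeds, %d complexes emitted, %d below minSize",
                    length(seeds), length(out), nDiscard))
  complexSet(out, labels = if (length(out)) paste0("C", seq_along(out))
                           else character(0))
}
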