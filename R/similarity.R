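#' @include combined.R
NULL

# tolerance for the "density does not decrease" comparison
.DENSITY_TOL <- 1e-12

#' Precompute the FS-Weight context of a network
#'
#' FS-Weight is defined on the dynamic PPI network's topology: closed
#' neighbourhoods (a protein's interactors plus the protein itself) and
#' the average degree N_avg = 2|E|/|V|.
#'
#' @param net a [PPINetwork-class] (normally the dynamic network).
#' @return an [FSWeightContext-class].
#' @export
fsWeightContext <- function(net) {
  stopifnot(is(net, "PPINetwork"))
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  open <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
  nb <- lapply(stats::setNames(nodes, nodes), function(x)
    sort(c(x, open[[x]])))
  nAvg <- if (length(nodes)) 2 * nrow(e) / length(nodes) else 0
  new("FSWeightContext", neighborhood = nb, nAvg = nAvg)
}

#' FS-Weight functional similarity between two proteins
#'
#' Topological similarity built from shared versus exclusive closed
#' neighbourhoods, with a small-degree penalty term lambda that inflates
#' the denominator of proteins whose neighbourhood is smaller than the
#' network average:
#'
#' \deqn{FS(i,j) = \frac{2c}{d_i + 2c + \lambda_{ij}} \cdot
#'                \frac{2c}{d_j + 2c + \lambda_{ji}}}
#'
#' where \eqn{c = |N_i \cap N_j|} counts common neighbours (including i
#' and j themselves when adjacent), \eqn{d_i = |N_i \setminus N_j|}, and
#' \eqn{\lambda_{ij} = \max(0, N_{avg} - (d_i + c))}.  Symmetric, in
#' [0, 1], and 0 when the closed neighbourhoods are disjoint.  Nonadjacent
#' pairs are legal inputs.
#'
#' @param ctx an [FSWeightContext-class].
#' @param i,j distinct node identifiers present in the context.
#' @return similarity in [0, 1].
#' @export
fsWeight <- function(ctx, i, j) {
  stopifnot(is(ctx, "FSWeightContext"))
  nb <- ctx@neighborhood
  if (is.null(nb[[i]]) || is.null(nb[[j]]))
    stop("node not in FS-Weight context: ",
         if (is.null(nb[[i]])) i else j)
  if (i == j)
    stop("fsWeight requires two distinct proteins")
  ni <- nb[[i]]; nj <- nb[[j]]
  cc <- length(intersect(ni, nj))
  if (cc == 0L) return(0)
  di <- length(ni) - cc
  dj <- length(nj) - cc
  li <- max(0, ctx@nAvg - (di + cc))
  lj <- max(0, ctx@nAvg - (dj + cc))
  (2 * cc / (di + 2 * cc + li)) * (2 * cc / (dj + 2 * cc + lj))
}

#' Strong-similarity predicate
#'
#' @param s FS-Weight similarity value.
#' @param fsMin threshold in [0, 1]; the pair is "strongly similar" when
#'   `s >= fsMin` (inclusive boundary).
#' @return logical.
#' @export
isStrong <- function(s, fsMin) {
  stopifnot(fsMin >= 0, fsMin <= 1)
  s >= fsMin
}

#' Cluster density (Cluster_Coefficient)
#'
#' Density-style statistic of a candidate cluster: with m internal edges
#' and n nodes (n >= 2), the value is \eqn{2m / (n(n-1))} -- 1 for a
#' complete cluster of any size, increasing in m at fixed n, and strictly
#' decreased by adding a node without internal edges.
#'
#' @param cluster character vector of member identifiers (length >= 2).
#' @param graph edge source counted for m: a [CombinedNetwork-class]
#'   (edges of any weight, including GO-added and weight-0 PPI edges) or
#'   a [PPINetwork-class].
#' @return list with `m` (internal edge count), `n` (node count) and
#'   `value` (the density).
#' @export
clusterCoefficient <- function(cluster, graph) {
  cluster <- unique(cluster)
  n <- length(cluster)
  if (n < 2L)
    stop("cluster density requires at least 2 nodes")
  if (is(graph, "CombinedNetwork")) {
    et <- graph@edgeTable
    m <- sum(et$u %in% cluster & et$v %in% cluster)
  } else if (is(graph, "PPINetwork")) {
    e <- graph@edges
    m <- sum(e[, 1L] %in% cluster & e[, 2L] %in% cluster)
  } else stop("unsupported graph type")
  list(m = as.integer(m), n = as.integer(n),
       value = 2 * m / (n * (n - 1)))
}
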