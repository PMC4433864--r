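#' @include AllGenerics.R
NULL

#' @rdname networkNodes
setMethod("networkNodes", "PPINetwork", function(x) x@nodes)

#' @rdname networkNodes
setMethod("networkNodes", "CombinedNetwork", function(x) x@nodes)

#' @rdname networkEdges
setMethod("networkEdges", "PPINetwork", function(x) x@edges)

#' @rdname networkEdges
setMethod("networkEdges", "CombinedNetwork", function(x) x@edgeTable)

#' @rdname nodeCount
setMethod("nodeCount", "PPINetwork", function(x) length(x@nodes))

#' @rdname nodeCount
setMethod("nodeCount", "CombinedNetwork", function(x) length(x@nodes))

#' @rdname nodeCount
setMethod("edgeCount", "PPINetwork", function(x) nrow(x@edges))

#' @rdname nodeCount
setMethod("edgeCount", "CombinedNetwork", function(x) nrow(x@edgeTable))

#' @rdname provenance
setMethod("provenance", "PPINetwork", function(x) x@provenance)

#' @rdname provenance
setMethod("provenance", "CombinedNetwork", function(x) x@provenance)

#' @rdname complexes
setMethod("complexes", "ComplexSet", function(x) x@complexes)

#' @rdname complexLabels
setMethod("complexLabels", "ComplexSet", function(x) x@labels)

#' @rdname annotationList
setMethod("annotationList", "AnnotationMap", function(x) x@map)

#' Number of complexes in a set
#' @param x a ComplexSet.
#' @export
setMethod("length", "ComplexSet", function(x) length(x@complexes))

#' Extract one complex
#' @param x a ComplexSet.
#' @param i index.
#' @export
setMethod("[[", "ComplexSet", function(x, i) x@complexes[[i]])

#' Number of edges with origin "go_added"
#' @param x a CombinedNetwork.
#' @return integer count of annotation-only edges.
#' @export
addedEdgeCount <- function(x) {
  stopifnot(is(x, "CombinedNetwork"))
  x@addedEdgeCount
}

#' @rdname asIgraph
setMethod("asIgraph", "PPINetwork", function(x) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x@nodes), name = x@nodes)
  if (nrow(x@edges) > 0L)
    g <- igraph::add_edges(g, t(x@edges))
  g
})

#' @rdname asIgraph
setMethod("asIgraph", "CombinedNetwork", function(x) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x@nodes), name = x@nodes)
  et <- x@edgeTable
  if (nrow(et) > 0L) {
    g <- igraph::add_edges(g, rbind(et$u, et$v))
    igraph::E(g)$weight <- et$weight
    igraph::E(g)$origin <- et$origin
  }
  g
})

#' Display methods for GECluster classes
#' @param object object to display.
#' @name show-methods
#' @aliases show,PPINetwork-method show,CombinedNetwork-method show,ComplexSet-method show,AnnotationMap-method show,MatchResult-method show,NetworkStats-method show,EvolutionMap-method show,CompositionReport-method
#' @export
setMethod("show", "PPINetwork", function(object) {
  cat(sprintf("%s PPINetwork: %d nodes, %d edges\n",
              object@kind, length(object@nodes), nrow(object@edges)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "),
        "\n")
})

setMethod("show", "CombinedNetwork", function(object) {
  et <- object@edgeTable
  cat(sprintf(
    "CombinedNetwork: %d nodes, %d edges (%d GO-added), total weight %d\n",
    length(object@nodes), nrow(et), object@addedEdgeCount,
    sum(et$weight)))
})

setMethod("show", "ComplexSet", function(object) {
  sz <- lengths(object@complexes)
  cat(sprintf("ComplexSet: %d complexes", length(sz)))
  if (length(sz))
    cat(sprintf(", sizes %d-%d (median %g)", min(sz), max(sz),
                stats::median(sz)))
  cat("\n")
})

setMethod("show", "AnnotationMap", function(object) {
  cat(sprintf("AnnotationMap: %d proteins, %d distinct terms\n",
              length(object@map),
              length(unique(unlist(object@map, use.names = FALSE)))))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf(
    "MatchResult (M_thres = %g): N_c = %d, N_p = %d, N_mc = %d, N_mp = %d\n",
    object@mThres, object@nc, object@np, object@nmc, object@nmp))
  cat(sprintf("  Recall = %.4f  Precision = %.4f  F1 = %.4f\n",
              complexRecall(object), complexPrecision(object),
              complexF1(complexRecall(object), complexPrecision(object))))
})

setMethod("show", "NetworkStats", function(object) {
  cat(sprintf(paste0(
    "NetworkStats: %d nodes, %d edges, %d component(s)\n",
    "  clustering coefficient %.4f, diameter %g, ",
    "characteristic path length %.4f\n"),
    object@nodeCount, object@edgeCount, object@componentCount,
    object@clusteringCoefficient, object@diameter,
    object@characteristicPathLength))
})

setMethod("show", "EvolutionMap", function(object) {
  cat(sprintf("EvolutionMap over %d conditions (M_thres = %g)\n",
              length(object@labels), object@mThres))
  print(object@counts)
})

setMethod("show", "CompositionReport", function(object) {
  cat(sprintf(
    "CompositionReport: %d core, %d attachment, %d unclassified proteins\n",
    object@coreCount, object@attachmentCount, object@unclassifiedCount))
})
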