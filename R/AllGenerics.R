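#' @include AllClasses.R
NULL

#' Node identifiers of a network
#' @param x a PPINetwork or CombinedNetwork.
#' @return character vector of protein identifiers.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a network
#' @param x a PPINetwork or CombinedNetwork.
#' @return for a PPINetwork, a 2-column character matrix of canonical
#'   unordered pairs; for a CombinedNetwork, a data.frame with columns
#'   u, v, weight, origin.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Node and edge counts
#' @param x a PPINetwork or CombinedNetwork.
#' @return integer count.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname nodeCount
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Provenance / load report of an object
#' @param x a PPINetwork or CombinedNetwork.
#' @return a list of counts and source descriptors.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Complexes of a ComplexSet
#' @param x a ComplexSet.
#' @return list of character vectors (sorted member identifiers).
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))

#' Labels of a ComplexSet
#' @param x a ComplexSet.
#' @return character vector of per-complex labels.
#' @export
setGeneric("complexLabels", function(x) standardGeneric("complexLabels"))

#' Annotation map accessor
#' @param x an AnnotationMap.
#' @return named list of character term vectors.
#' @export
setGeneric("annotationList", function(x) standardGeneric("annotationList"))

#' Convert a network to an igraph object
#' @param x a PPINetwork or CombinedNetwork.
#' @return an igraph undirected simple graph; for combined networks edge
#'   attributes `weight` and `origin` are carried over.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
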