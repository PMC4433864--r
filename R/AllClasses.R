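#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom stats setNames
#' @importFrom utils combn
NULL

#' PPINetwork: an undirected, simple protein-protein interaction network
#'
#' Container for a static or dynamic (condition-specific) PPI network.
#' The edge set is stored canonically: each unordered pair appears once,
#' with endpoints sorted lexicographically, no self-loops.
#'
#' @slot nodes character vector of protein identifiers (verbatim, unique).
#' @slot edges character matrix with two columns; row i is the unordered
#'   pair (edges[i,1], edges[i,2]) with edges[i,1] < edges[i,2].
#' @slot kind either "static" or "dynamic".
#' @slot provenance free-form list: load report for networks read from file
#'   (kept / self-loops dropped / duplicates dropped), or the source network
#'   and time-point selection for dynamic networks.
#'
#' @seealso [readEdgeList()], [buildDynamic()]
#' @export
setClass("PPINetwork",
  representation(
    nodes = "character",
    edges = "matrix",
    kind = "character",
    provenance = "list"
  ),
  prototype(
    nodes = character(0),
    edges = matrix(character(0), ncol = 2L),
    kind = "static",
    provenance = list()
  )
)

setValidity("PPINetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a character matrix with 2 columns")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node identifiers")
  if (nrow(e) > 0L) {
    if (any(e[, 1L] == e[, 2L]))
      msg <- c(msg, "self-loop present")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edge endpoints not in canonical (sorted) order")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
      msg <- c(msg, "duplicate edges")
    if (!all(c(e) %in% object@nodes))
      msg <- c(msg, "edge endpoint not in node set")
  }
  if (!object@kind %in% c("static", "dynamic"))
    msg <- c(msg, "kind must be 'static' or 'dynamic'")
  if (length(msg)) msg else TRUE
})

#' CombinedNetwork: a dynamic PPI network weighted by shared GO-slim terms
#'
#' Nodes are exactly the dynamic network's nodes.  Every dynamic PPI edge is
#' present (origin "ppi", or "both" if the pair also shares terms ... origin
#' records whether the pair additionally shares annotation); every protein
#' pair sharing at least one GO-slim term has an edge with integer weight
#' equal to the shared-term count.  Pairs sharing terms but lacking a PPI
#' edge have origin "go_added".
#'
#' @slot nodes character vector (identical to the dynamic node set).
#' @slot edgeTable data.frame with columns u, v (canonical order), weight
#'   (integer shared-term count), origin (one of "ppi", "go_added", "both").
#' @slot addedEdgeCount number of edges with origin "go_added".
#' @slot provenance list recording the source network id.
#'
#' @seealso [buildCombined()]
#' @export
setClass("CombinedNetwork",
  representation(
    nodes = "character",
    edgeTable = "data.frame",
    addedEdgeCount = "integer",
    provenance = "list"
  ),
  prototype(
    nodes = character(0),
    edgeTable = data.frame(u = character(0), v = character(0),
                           weight = integer(0), origin = character(0),
                           stringsAsFactors = FALSE),
    addedEdgeCount = 0L,
    provenance = list()
  )
)

setValidity("CombinedNetwork", function(object) {
  msg <- character(0)
  et <- object@edgeTable
  if (!all(c("u", "v", "weight", "origin") %in% names(et)))
    return("edgeTable must have columns u, v, weight, origin")
  if (nrow(et) > 0L) {
    if (any(et$u >= et$v))
      msg <- c(msg, "edgeTable pairs must be canonical (u < v)")
    if (!all(c(et$u, et$v) %in% object@nodes))
      msg <- c(msg, "edge endpoint not in node set")
    if (any(et$weight < 0L))
      msg <- c(msg, "negative edge weight")
    if (!all(et$origin %in% c("ppi", "go_added", "both")))
      msg <- c(msg, "origin must be ppi, go_added or both")
    if (any(et$weight[et$origin == "go_added"] < 1L))
      msg <- c(msg, "go_added edge with weight < 1")
  }
  if (object@addedEdgeCount != sum(et$origin == "go_added"))
    msg <- c(msg, "addedEdgeCount inconsistent with edgeTable")
  if (length(msg)) msg else TRUE
})

#' AnnotationMap: protein-to-GO-slim-term assignments
#'
#' Many-to-many map from protein identifiers to GO-slim term identifiers
#' (opaque strings; all three aspects BP/MF/CC are treated alike).
#'
#' @slot map named list; each element is a character vector of term ids
#'   (possibly empty) for the protein named by the element.
#'
#' @seealso [readAnnotations()], [buildGOProteinSets()]
#' @export
setClass("AnnotationMap",
  representation(map = "list"),
  prototype(map = structure(list(), names = character(0)))
)

setValidity("AnnotationMap", function(object) {
  m <- object@map
  if (length(m) && is.null(names(m)))
    return("map must be a named list")
  if (anyDuplicated(names(m)))
    return("duplicate protein in map")
  if (length(m) && !all(vapply(m, is.character, logical(1))))
    return("map values must be character vectors of term ids")
  TRUE
})

#' ComplexSet: an ordered collection of protein complexes
#'
#' Each complex is a set (unique, sorted character vector) of protein
#' identifiers with at least two members.  Used both for predictions and
#' for reference (benchmark) complex collections.
#'
#' @slot complexes list of character vectors, each sorted and unique,
#'   length >= 2.
#' @slot labels character vector of per-complex labels (may be empty names).
#'
#' @seealso [readComplexes()], [geCluster()]
#' @export
setClass("ComplexSet",
  representation(complexes = "list", labels = "character"),
  prototype(complexes = list(), labels = character(0))
)

setValidity("ComplexSet", function(object) {
  cx <- object@complexes
  if (length(object@labels) != length(cx))
    return("labels length must match complex count")
  for (i in seq_along(cx)) {
    ci <- cx[[i]]
    if (!is.character(ci) || length(ci) < 2L)
      return(sprintf("complex %d has fewer than 2 members", i))
    if (anyDuplicated(ci))
      return(sprintf("complex %d has duplicate members", i))
  }
  TRUE
})

#' ExpressionSeries: a time-course expression matrix
#'
#' Thin extension of SummarizedExperiment.  Rows are genes, columns are
#' samples; colData carries a `timepoint` label and an integer `replicate`
#' index per column.  Values are non-negative expression measurements.
#' Readers collapse replicates at load time, so series in the pipeline
#' normally have one column per time point (replicate 1).
#'
#' @seealso [readExpression()], [expressionSeries()], [computeActivity()]
#' @export
setClass("ExpressionSeries", contains = "SummarizedExperiment")

setValidity("ExpressionSeries", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("timepoint", "replicate") %in% names(cd)))
    return("colData must have 'timepoint' and 'replicate' columns")
  v <- SummarizedExperiment::assay(object, "expr")
  if (!is.numeric(v))
    return("expression values must be numeric")
  if (anyNA(v))
    return("missing expression values are not allowed")
  if (any(v < 0))
    return("expression values must be non-negative")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("gene identifiers (rownames) must be present and unique")
  # time-point labels must form contiguous runs of replicates
  tp <- as.character(cd$timepoint)
  if (length(tp) > 1L) {
    r <- rle(tp)$values
    if (anyDuplicated(r))
      return("time-point labels must form contiguous replicate groups")
  }
  TRUE
})

#' ActivityTable: per-gene, per-time-point expression activity
#'
#' A gene is active at a time point when its expression there is at least
#' its own mean over all time points (the >= convention keeps constant
#' genes active everywhere).
#'
#' @slot active logical matrix, genes x time points.
#' @slot means named numeric vector of per-gene means over all time points.
#'
#' @seealso [computeActivity()], [buildDynamic()]
#' @export
setClass("ActivityTable",
  representation(active = "matrix", means = "numeric")
)

setValidity("ActivityTable", function(object) {
  if (!is.logical(object@active))
    return("active must be a logical matrix")
  if (length(object@means) != nrow(object@active))
    return("means length must equal gene count")
  if (!identical(names(object@means), rownames(object@active)))
    return("means names must match activity rownames")
  TRUE
})

#' FSWeightContext: precomputed topology for FS-Weight
#'
#' Closed neighbourhoods (each node's neighbour set including the node
#' itself) and the network's average degree, both taken from the dynamic
#' PPI network the similarity is defined on.
#'
#' @slot neighborhood named list of character vectors: closed neighbourhood
#'   per node.
#' @slot nAvg average degree, 2 * |edges| / |nodes|.
#'
#' @seealso [fsWeightContext()], [fsWeight()]
#' @export
setClass("FSWeightContext",
  representation(neighborhood = "list", nAvg = "numeric")
)

#' MatchResult: complex-level matching of predictions against a reference
#'
#' @slot nc,np sizes of the reference and predicted complex sets.
#' @slot nmc number of reference complexes matched by >= 1 prediction.
#' @slot nmp number of predicted complexes matched by >= 1 reference.
#' @slot mThres matching-score threshold used.
#' @slot pairs data.frame (ref, pred, score) of all matched pairs.
#'
#' @seealso [matchComplexSets()], [complexRecall()]
#' @export
setClass("MatchResult",
  representation(nc = "integer", np = "integer", nmc = "integer",
                 nmp = "integer", mThres = "numeric", pairs = "data.frame")
)

#' NetworkStats: summary statistics of a PPI network
#'
#' @slot nodeCount,edgeCount basic sizes.
#' @slot clusteringCoefficient mean local clustering coefficient (nodes of
#'   degree < 2 contribute 0).
#' @slot diameter maximum shortest-path length over connected pairs.
#' @slot characteristicPathLength mean shortest-path length over connected
#'   pairs.
#' @slot componentCount number of connected components.
#' @slot degreeHistogram table of node degrees.
#' @slot pathLengthHistogram table of shortest-path lengths over connected
#'   (unordered) pairs.
#'
#' @seealso [networkStats()]
#' @export
setClass("NetworkStats",
  representation(nodeCount = "integer", edgeCount = "integer",
                 clusteringCoefficient = "numeric", diameter = "numeric",
                 characteristicPathLength = "numeric",
                 componentCount = "integer",
                 degreeHistogram = "table", pathLengthHistogram = "table")
)

#' EvolutionMap: cross-condition complex relationships
#'
#' Pairwise matching of complex sets predicted under different conditions,
#' using the same matching score and threshold as the evaluation module.
#'
#' @slot labels condition (network) labels.
#' @slot counts symmetric matrix of matched-pair counts between conditions.
#' @slot pairs list (named by "label1|label2") of data.frames (a, b, score)
#'   giving the matched complex index pairs.
#' @slot mThres threshold used.
#'
#' @seealso [relateComplexSets()]
#' @export
setClass("EvolutionMap",
  representation(labels = "character", counts = "matrix", pairs = "list",
                 mThres = "numeric")
)

#' CompositionReport: core/attachment composition of predicted complexes
#'
#' @slot coreCount distinct core proteins appearing in >= 1 complex.
#' @slot attachmentCount distinct attachment proteins appearing in >= 1
#'   complex.
#' @slot unclassifiedCount distinct proteins in complexes that are in
#'   neither list.
#' @slot membership named integer vector: per-protein complex number (how
#'   many complexes contain the protein), over all proteins in the core and
#'   attachment lists (0 when absent from every complex).
#'
#' @seealso [complexComposition()]
#' @export
setClass("CompositionReport",
  representation(coreCount = "integer", attachmentCount = "integer",
                 unclassifiedCount = "integer", membership = "integer")
)

#' GEClusterConfig: parameters of the seed-expansion clusterer
#'
#' @slot fsMin FS-Weight threshold for "strong" functional similarity
#'   (default 0.25, the value that maximises F1 on the training data).
#' @slot minSize minimum emitted cluster size (default 3, matching the
#'   benchmark filter).
#' @slot overlap when FALSE (default) a protein joins at most one emitted
#'   cluster; when TRUE assigned proteins may be re-admitted as members of
#'   later clusters (never as seeds).
#'
#' @seealso [geClusterConfig()], [geCluster()]
#' @export
setClass("GEClusterConfig",
  representation(fsMin = "numeric", minSize = "integer", overlap = "logical"),
  prototype(fsMin = 0.25, minSize = 3L, overlap = FALSE)
)

setValidity("GEClusterConfig", function(object) {
  if (object@fsMin < 0 || object@fsMin > 1)
    return("fsMin must be in [0, 1]")
  if (object@minSize < 2L)
    return("minSize must be >= 2")
  TRUE
})

#' SyntheticSpec: parameters of the planted-complex benchmark generator
#'
#' @slot nComplexes number of planted complexes.
#' @slot sizeRange integer vector (min, max) of complex sizes (min >= 3).
#' @slot nBackground number of background proteins.
#' @slot pIn within-complex edge probability.
#' @slot pOut background / cross-complex edge probability (pOut < pIn).
#' @slot nStages number of time-course stages.
#' @slot nReplicates replicates per stage in the written expression file.
#' @slot schedule list of integer vectors: active stages per complex
#'   (empty list means every complex active at every stage).
#' @slot fidelity probability a complex member carries its complex's
#'   private GO-slim term.
#' @slot nDecoyTerms size of the decoy term pool used for background nodes.
#' @slot bgExpressedFraction fraction of background genes present in the
#'   expression matrix (absent genes are never active, emulating proteins
#'   with no expression record).
#' @slot noiseSd standard deviation of optional Gaussian noise overlaid on
#'   the two-level expression step function (0 = noiseless).
#' @slot highValue,lowValue expression levels during active / inactive
#'   stages.
#' @slot seed RNG seed fixing all randomness.
#'
#' @seealso [syntheticSpec()], [generateSynthetic()]
#' @export
setClass("SyntheticSpec",
  representation(
    nComplexes = "integer", sizeRange = "integer", nBackground = "integer",
    pIn = "numeric", pOut = "numeric", nStages = "integer",
    nReplicates = "integer", schedule = "list", fidelity = "numeric",
    nDecoyTerms = "integer", bgExpressedFraction = "numeric",
    noiseSd = "numeric", highValue = "numeric", lowValue = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (length(object@sizeRange) != 2L || object@sizeRange[1L] < 3L ||
      object@sizeRange[2L] < object@sizeRange[1L])
    msg <- c(msg, "sizeRange must be (min, max) with min >= 3")
  if (!(object@pOut >= 0 && object@pOut < object@pIn && object@pIn <= 1))
    msg <- c(msg, "require 0 <= pOut < pIn <= 1")
  if (object@fidelity < 0 || object@fidelity > 1)
    msg <- c(msg, "fidelity must be in [0, 1]")
  if (object@nStages < 1L)
    msg <- c(msg, "nStages must be >= 1")
  if (length(object@schedule) &&
      length(object@schedule) != object@nComplexes)
    msg <- c(msg, "schedule must be empty or have one entry per complex")
  for (s in object@schedule) {
    if (length(s) < 1L || any(s < 1L) || any(s > object@nStages))
      msg <- c(msg, "each schedule entry must be a non-empty subset of stages")
  }
  if (object@bgExpressedFraction < 0 || object@bgExpressedFraction > 1)
    msg <- c(msg, "bgExpressedFraction must be in [0, 1]")
  if (object@highValue <= object@lowValue)
    msg <- c(msg, "highValue must exceed lowValue")
  if (length(msg)) msg else TRUE
})
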