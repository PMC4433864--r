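#' @include dynamic.R
NULL

#' GO-Protein-Sets of a network
#'
#' For each GO-slim term, the set of network proteins annotated with it.
#' Proteins absent from the network are excluded; terms whose restricted
#' set is empty are dropped, terms with a single member are retained (they
#' simply generate no edges downstream).
#'
#' @param ann an [AnnotationMap-class].
#' @param net a [PPINetwork-class] (normally dynamic).
#' @return named list: term -> character vector of member proteins.
#' @export
buildGOProteinSets <- function(ann, net) {
  stopifnot(is(ann, "AnnotationMap"), is(net, "PPINetwork"))
  m <- ann@map[names(ann@map) %in% networkNodes(net)]
  if (length(m) == 0L)
    return(structure(list(), names = character(0)))
  prot <- rep(names(m), lengths(m))
  term <- unlist(m, use.names = FALSE)
  sets <- split(prot, term)
  lapply(sets, function(p) sort(unique(p)))
}

#' Build a combined (GO-slim-weighted) PPI network
#'
#' Weights every protein pair by the number of GO-slim terms the two
#' proteins share, keeping every dynamic PPI edge (weight possibly 0) and
#' adding an edge for every annotation-sharing pair that lacks a PPI edge.
#' The weight of an edge (u, v) always equals |terms(u) n terms(v)| over
#' the network's nodes; GO never adds nodes.
#'
#' @param net a dynamic [PPINetwork-class].
#' @param sets GO-Protein-Sets from [buildGOProteinSets()] (already
#'   restricted to `net`'s nodes).
#' @return a [CombinedNetwork-class].
#' @export
buildCombined <- function(net, sets) {
  stopifnot(is(net, "PPINetwork"))
  # shared-term count per pair: accumulate C(|set|,2) pair contributions
  keyU <- character(0); keyV <- character(0)
  for (members in sets) {
    k <- length(members)
    if (k < 2L) next
    idx <- utils::combn(k, 2L)
    keyU <- c(keyU, members[idx[1L, ]])
    keyV <- c(keyV, members[idx[2L, ]])
  }
  if (length(keyU)) {
    key <- paste(keyU, keyV, sep = "\r")  # members sorted, so canonical
    tab <- table(key)
    goPairs <- names(tab)
    goWeight <- as.integer(tab)
  } else {
    goPairs <- character(0)
    goWeight <- integer(0)
  }
  e <- networkEdges(net)
  ppiKey <- paste(e[, 1L], e[, 2L], sep = "\r")
  weight <- integer(length(ppiKey))
  hit <- match(ppiKey, goPairs)
  weight[!is.na(hit)] <- goWeight[hit[!is.na(hit)]]
  origin <- ifelse(is.na(hit), "ppi", "both")
  addKey <- setdiff(goPairs, ppiKey)
  addW <- goWeight[match(addKey, goPairs)]
  allKey <- c(ppiKey, addKey)
  allW <- c(weight, addW)
  allO <- c(origin, rep("go_added", length(addKey)))
  uv <- strsplit(allKey, "\r", fixed = TRUE)
  et <- data.frame(
    u = vapply(uv, `[`, character(1), 1L),
    v = vapply(uv, `[`, character(1), 2L),
    weight = as.integer(allW), origin = allO,
    stringsAsFactors = FALSE)
  et <- et[order(et$u, et$v), , drop = FALSE]
  rownames(et) <- NULL
  new("CombinedNetwork",
      nodes = networkNodes(net), edgeTable = et,
      addedEdgeCount = sum(allO == "go_added"),
      provenance = list(dynamicEdges = nrow(e),
                        goPairs = length(goPairs)))
}

#' Write / read a combined network as 4-column TSV (u, v, weight, origin)
#' @param cnet a [CombinedNetwork-class].
#' @param path file path.
#' @return invisibly `path` for the writer; a [CombinedNetwork-class] for
#'   the reader.
#' @export
writeCombined <- function(cnet, path) {
  stopifnot(is(cnet, "CombinedNetwork"))
  et <- cnet@edgeTable
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(et$u, et$v, et$weight, et$origin, sep = "\t"), con,
             sep = "\n")
  invisible(path)
}

#' @rdname writeCombined
#' @export
readCombined <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("malformed combined-network line ", bad[1L], " in ", path)
  et <- data.frame(
    u = vapply(fields, `[`, character(1), 1L),
    v = vapply(fields, `[`, character(1), 2L),
    weight = as.integer(vapply(fields, `[`, character(1), 3L)),
    origin = vapply(fields, `[`, character(1), 4L),
    stringsAsFactors = FALSE)
  et <- et[order(et$u, et$v), , drop = FALSE]
  rownames(et) <- NULL
  new("CombinedNetwork",
      nodes = sort(unique(c(et$u, et$v))), edgeTable = et,
      addedEdgeCount = sum(et$origin == "go_added"),
      provenance = list(path = path))
}
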