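#' @include AllClasses.R
NULL

# canonicalize raw unordered pairs: sort endpoints within a pair, drop
# nothing -- callers decide about loops/duplicates
.canonPairs <- function(u, v) {
  cbind(pmin(u, v), pmax(u, v))
}

.pairKey <- function(m) paste(m[, 1L], m[, 2L], sep = "\r")

# internal constructor: takes already-clean canonical pairs
.newPPINetwork <- function(nodes, edges, kind = "static",
                           provenance = list()) {
  o <- order(edges[, 1L], edges[, 2L])
  edges <- edges[o, , drop = FALSE]
  colnames(edges) <- c("u", "v")
  new("PPINetwork", nodes = sort(unique(nodes)), edges = edges,
      kind = kind, provenance = provenance)
}

#' Build a PPINetwork from an edge list in memory
#'
#' Self-loops are dropped and duplicate unordered pairs collapsed, exactly
#' as in [readEdgeList()]; node set is taken from the surviving edges.
#'
#' @param u,v character vectors of interacting protein identifiers.
#' @param kind "static" or "dynamic".
#' @return a [PPINetwork-class] whose provenance records the load report
#'   (input pairs, kept, selfLoops, duplicates).
#' @export
ppiNetwork <- function(u, v, kind = "static") {
  stopifnot(length(u) == length(v))
  nIn <- length(u)
  loop <- u == v
  m <- .canonPairs(u[!loop], v[!loop])
  dup <- duplicated(.pairKey(m))
  kept <- m[!dup, , drop = FALSE]
  .newPPINetwork(
    nodes = c(kept), edges = kept, kind = kind,
    provenance = list(input = nIn, kept = nrow(kept),
                      selfLoops = sum(loop), duplicates = sum(dup))
  )
}

#' Read a PPI edge list
#'
#' Reads a tab-separated edge list (two identifier columns; extra columns
#' are ignored), drops self-loops, and collapses duplicate pairs in either
#' orientation.  The counts of dropped records are kept in the network's
#' provenance so that input lines = kept + self-loops + duplicates.
#'
#' @param path path to a TSV file with >= 2 columns.
#' @param kind network kind recorded on the result ("static" by default).
#' @return a [PPINetwork-class].
#' @export
readEdgeList <- function(path, kind = "static") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop("empty edge-list file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f)
    length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L]), logical(1)))
  if (length(bad))
    stop("malformed edge-list line ", bad[1L], " in ", path)
  u <- vapply(fields, `[`, character(1), 1L)
  v <- vapply(fields, `[`, character(1), 2L)
  net <- ppiNetwork(u, v, kind = kind)
  net@provenance$path <- path
  net
}

#' Write a PPI edge list
#'
#' Writes canonical pairs (lexicographically sorted within and across
#' rows), tab-separated, LF line endings -- byte-stable for a given
#' network.
#'
#' @param net a [PPINetwork-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "PPINetwork"))
  e <- net@edges
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), con, sep = "\n")
  invisible(path)
}

# exact, parse-stable double formatting (re-reading and re-writing is a
# byte-level identity)
.fmtNum <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15,
         sprintf("%.0f", x), sprintf("%.17g", x))
}

#' Construct an ExpressionSeries
#'
#' @param values numeric matrix, genes x samples, with gene identifiers as
#'   rownames.
#' @param timepoints character vector of time-point labels per column
#'   (contiguous runs of replicates).
#' @param replicates integer vector of replicate indices per column
#'   (defaults to 1, 2, ... within each time point).
#' @return an [ExpressionSeries-class].
#' @export
expressionSeries <- function(values, timepoints,
                             replicates = stats::ave(
                               seq_along(timepoints), timepoints,
                               FUN = seq_along)) {
  stopifnot(is.matrix(values), ncol(values) == length(timepoints))
  colnames(values) <- paste0(timepoints, ":", replicates)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(timepoint = as.character(timepoints),
                                   replicate = as.integer(replicates)))
  new("ExpressionSeries", se)
}

#' Expression values and time points of a series
#' @param x an [ExpressionSeries-class].
#' @return `exprValues`: the numeric matrix; `timePoints`: the per-column
#'   time-point labels.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "expr")

#' @rdname exprValues
#' @export
timePoints <- function(x)
  as.character(SummarizedExperiment::colData(x)$timepoint)

#' Read a time-course expression matrix
#'
#' The file is TSV with a header row `gene<TAB>label:rep<TAB>...`; the
#' `:rep` suffix is optional and defaults to 1.  Replicate columns within
#' one time point are collapsed at load time under `replicatePolicy`.
#'
#' @param path path to the TSV file.
#' @param replicatePolicy "mean" (default; arithmetic mean of replicates)
#'   or "first" (keep the first replicate).
#' @return an [ExpressionSeries-class] with one column per time point.
#' @export
readExpression <- function(path, replicatePolicy = c("mean", "first")) {
  replicatePolicy <- match.arg(replicatePolicy)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression file needs a header and at least one gene row: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("expression header must name at least one sample: ", path)
  sampleLabels <- header[-1L]
  parts <- strsplit(sampleLabels, ":", fixed = TRUE)
  tp <- vapply(parts, `[`, character(1), 1L)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nBad <- which(lengths(rows) != length(header))
  if (length(nBad))
    stop("malformed expression line ", nBad[1L] + 1L, " in ", path)
  genes <- vapply(rows, `[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene identifier in ", path, ": ",
         genes[duplicated(genes)][1L])
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]),
           numeric(length(sampleLabels))))
  vals <- matrix(vals, nrow = length(sampleLabels))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric or empty expression value for gene '",
         genes[bad[2L]], "', sample '", sampleLabels[bad[1L]], "' in ",
         path)
  }
  vals <- t(vals)
  rownames(vals) <- genes
  # collapse replicates per time point, preserving first-appearance order
  tpOrder <- unique(tp)
  collapsed <- vapply(tpOrder, function(lab) {
    cols <- which(tp == lab)
    if (replicatePolicy == "mean" && length(cols) > 1L)
      rowMeans(vals[, cols, drop = FALSE])
    else vals[, cols[1L]]
  }, numeric(length(genes)))
  collapsed <- matrix(collapsed, nrow = length(genes),
                      dimnames = list(genes, NULL))
  expressionSeries(collapsed, tpOrder, rep(1L, length(tpOrder)))
}

#' Write an expression series
#'
#' Inverse of [readExpression()] on collapsed series; header cells are
#' `label:rep` and values are written in a parse-exact decimal form.
#'
#' @param es an [ExpressionSeries-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeExpression <- function(es, path) {
  stopifnot(is(es, "ExpressionSeries"))
  v <- exprValues(es)
  cd <- SummarizedExperiment::colData(es)
  header <- paste(c("gene", paste0(cd$timepoint, ":", cd$replicate)),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], .fmtNum(v[i, ])), collapse = "\t"),
    character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Construct an AnnotationMap
#' @param map named list: protein identifier -> character vector of
#'   GO-slim term identifiers.
#' @return an [AnnotationMap-class]; term vectors are sorted and
#'   de-duplicated.
#' @export
annotationMap <- function(map) {
  if (length(map) == 0L)
    return(new("AnnotationMap",
               map = structure(list(), names = character(0))))
  map <- lapply(map, function(t) sort(unique(as.character(t))))
  map <- map[order(names(map))]
  new("AnnotationMap", map = map)
}

#' Read protein-to-GO-slim annotations
#'
#' Two-column TSV, protein then term, many-to-many; extra columns (e.g.
#' a GAF aspect tag) are ignored.
#'
#' @param path path to the TSV file.
#' @return an [AnnotationMap-class].
#' @export
readAnnotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(annotationMap(structure(list(), names = character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f)
    length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L]), logical(1)))
  if (length(bad))
    stop("malformed annotation line ", bad[1L], " in ", path)
  p <- vapply(fields, `[`, character(1), 1L)
  t <- vapply(fields, `[`, character(1), 2L)
  annotationMap(split(t, p))
}

#' Write protein-to-GO-slim annotations
#' @param ann an [AnnotationMap-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAnnotations <- function(ann, path) {
  stopifnot(is(ann, "AnnotationMap"))
  m <- ann@map
  lines <- unlist(lapply(names(m), function(p)
    if (length(m[[p]])) paste(p, m[[p]], sep = "\t") else character(0)),
    use.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Construct a ComplexSet
#' @param complexes list of character vectors of member identifiers
#'   (each of size >= 2 after de-duplication).
#' @param labels optional character labels, one per complex.
#' @return a [ComplexSet-class]; members are sorted and de-duplicated,
#'   complex order is preserved.
#' @export
complexSet <- function(complexes, labels = NULL) {
  complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  if (is.null(labels))
    labels <- rep(NA_character_, length(complexes))
  new("ComplexSet", complexes = complexes, labels = as.character(labels))
}

#' Read a complex set
#'
#' One complex per line, members tab-separated.
#'
#' @param path path to the file.
#' @return a [ComplexSet-class].
#' @export
readComplexes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) unique(f[nzchar(f)]))
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("complex line ", bad[1L], " in ", path, " has fewer than 2 members")
  complexSet(fields)
}

#' Write a complex set
#'
#' One complex per line; members sorted lexicographically for byte-stable
#' output; complex order preserved.
#'
#' @param set a [ComplexSet-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeComplexes <- function(set, path) {
  stopifnot(is(set, "ComplexSet"))
  lines <- vapply(set@complexes, paste, character(1), collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a one-identifier-per-line protein list
#' @param path path to the file.
#' @return character vector (order preserved, blanks dropped).
#' @export
readProteinList <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines)]
}

#' Write a protein list, one identifier per line
#' @param proteins character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeProteinList <- function(proteins, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(proteins), con, sep = "\n")
  invisible(path)
}
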