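#' @include evaluation.R
NULL

#' Relate complex sets predicted under different conditions
#'
#' Computes, for every pair of conditions, the matched complex pairs
#' (matching score >= `mThres`, same matcher as the evaluation module)
#' and the total match count -- the machinery behind cross-condition
#' complex-evolution maps.
#'
#' @param sets list of [ComplexSet-class] objects (>= 2).
#' @param labels condition labels, one per set.
#' @param mThres matching threshold (default 0.2).
#' @return an [EvolutionMap-class]; `counts` is a symmetric matrix whose
#'   diagonal holds each set's self-match count.
#' @export
relateComplexSets <- function(sets, labels = NULL, mThres = 0.2) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(labels))
    labels <- paste0("N", seq_along(sets))
  stopifnot(length(labels) == length(sets))
  for (s in sets) stopifnot(is(s, "ComplexSet"))
  k <- length(sets)
  counts <- matrix(0L, k, k, dimnames = list(labels, labels))
  pairs <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      mr <- matchComplexSets(sets[[i]], sets[[j]], mThres = mThres)
      counts[i, j] <- nrow(mr@pairs)
      counts[j, i] <- counts[i, j]
      pairs[[paste(labels[i], labels[j], sep = "|")]] <-
        stats::setNames(mr@pairs, c("a", "b", "score"))
    }
  }
  new("EvolutionMap", labels = labels, counts = counts, pairs = pairs,
      mThres = mThres)
}

#' Core/attachment composition of a predicted complex set
#'
#' Counts the distinct core and attachment proteins (from caller-supplied
#' lists) that appear in at least one complex, and the per-protein
#' "protein complex number" -- the number of complexes a protein belongs
#' to.
#'
#' @param set a [ComplexSet-class].
#' @param core character vector of core protein identifiers.
#' @param attachment character vector of attachment protein identifiers
#'   (disjoint from `core`).
#' @return a [CompositionReport-class]; `membership` covers every protein
#'   in either list (0 when the protein is in no complex).
#' @export
complexComposition <- function(set, core, attachment) {
  stopifnot(is(set, "ComplexSet"))
  core <- unique(as.character(core))
  attachment <- unique(as.character(attachment))
  if (length(intersect(core, attachment)))
    stop("core and attachment lists must be disjoint")
  members <- unlist(set@complexes, use.names = FALSE)
  inAny <- unique(members)
  classified <- c(core, attachment)
  counts <- table(members)
  membership <- stats::setNames(integer(length(classified)), classified)
  hit <- intersect(classified, names(counts))
  membership[hit] <- as.integer(counts[hit])
  new("CompositionReport",
      coreCount = length(intersect(core, inAny)),
      attachmentCount = length(intersect(attachment, inAny)),
      unclassifiedCount = length(setdiff(inAny, classified)),
      membership = membership)
}

#' Composition accessors
#' @param x a [CompositionReport-class].
#' @return `coreProteinCount` / `attachmentProteinCount`: distinct list
#'   proteins appearing in >= 1 complex; `complexNumber`: named integer
#'   vector of per-protein complex membership counts.
#' @export
coreProteinCount <- function(x) {
  stopifnot(is(x, "CompositionReport"))
  x@coreCount
}

#' @rdname coreProteinCount
#' @export
attachmentProteinCount <- function(x) {
  stopifnot(is(x, "CompositionReport"))
  x@attachmentCount
}

#' @rdname coreProteinCount
#' @export
complexNumber <- function(x) {
  stopifnot(is(x, "CompositionReport"))
  x@membership
}
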