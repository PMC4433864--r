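#' @include evolution.R
NULL

#' Construct a synthetic benchmark specification
#'
#' Defines a planted-complex benchmark: dense within-complex wiring on a
#' sparse background, a private GO-slim term per complex carried by each
#' member with probability `fidelity`, decoy terms on background nodes,
#' and two-level step-function expression that places complex members at
#' or above their own temporal mean exactly during the complex's active
#' stages.
#'
#' @param nComplexes number of planted complexes (default 20).
#' @param sizeRange (min, max) complex size, min >= 3 (default 3-10).
#' @param nBackground background proteins (default 200).
#' @param pIn within-complex edge probability (default 0.9).
#' @param pOut background / cross-complex edge probability (default 0.01).
#' @param nStages time-course stages (default 3).
#' @param nReplicates replicates per stage in the written expression file
#'   (default 3, mirroring triplicate time-course designs).
#' @param schedule list of active-stage vectors, one per complex; empty
#'   list (default) schedules every complex active at every stage.
#' @param fidelity probability a member carries its complex's term
#'   (default 0.9).
#' @param nDecoyTerms decoy term pool for background nodes (default 25).
#' @param bgExpressedFraction fraction of background genes present in the
#'   expression matrix (default 1; genes omitted from the matrix are never
#'   active, emulating proteins with no expression record).
#' @param noiseSd Gaussian noise sd overlaid on the step function
#'   (default 0 = noiseless).
#' @param highValue,lowValue expression levels for active / inactive
#'   stages (defaults 10 and 2).
#' @param seed RNG seed fixing all randomness (default 1).
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nComplexes = 20L, sizeRange = c(3L, 10L),
                          nBackground = 200L, pIn = 0.9, pOut = 0.01,
                          nStages = 3L, nReplicates = 3L,
                          schedule = list(), fidelity = 0.9,
                          nDecoyTerms = 25L, bgExpressedFraction = 1,
                          noiseSd = 0, highValue = 10, lowValue = 2,
                          seed = 1L) {
  new("SyntheticSpec",
      nComplexes = as.integer(nComplexes),
      sizeRange = as.integer(sizeRange),
      nBackground = as.integer(nBackground),
      pIn = as.numeric(pIn), pOut = as.numeric(pOut),
      nStages = as.integer(nStages), nReplicates = as.integer(nReplicates),
      schedule = schedule, fidelity = as.numeric(fidelity),
      nDecoyTerms = as.integer(nDecoyTerms),
      bgExpressedFraction = as.numeric(bgExpressedFraction),
      noiseSd = as.numeric(noiseSd),
      highValue = as.numeric(highValue), lowValue = as.numeric(lowValue),
      seed = as.integer(seed))
}

#' Generate a synthetic benchmark
#'
#' Draws a static PPI network with planted dense complexes, a time-course
#' expression series, GO-slim annotations (one private term per complex
#' plus background decoys), the ground-truth complex set, and
#' core/attachment lists (the first half of each complex's members are
#' designated core, the rest attachment).  All randomness is fixed by
#' `spec@seed`; regeneration is bit-identical.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `static` ([PPINetwork-class]), `expression`
#'   ([ExpressionSeries-class] with replicate columns), `annotations`
#'   ([AnnotationMap-class]), `truth` ([ComplexSet-class]), `core`,
#'   `attachment` (character vectors), `membership` (named complex index
#'   per planted protein) and `spec`.
#' @export
generateSynthetic <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  szChoices <- seq(spec@sizeRange[1L], spec@sizeRange[2L])
  sizes <- szChoices[sample.int(length(szChoices), spec@nComplexes,
                                replace = TRUE)]
  nMember <- sum(sizes)
  memberIds <- sprintf("P%04d", seq_len(nMember))
  bgIds <- sprintf("B%04d", seq_len(spec@nBackground))
  membership <- rep(seq_len(spec@nComplexes), sizes)
  names(membership) <- memberIds
  allIds <- c(memberIds, bgIds)
  complexOf <- c(membership,
                 stats::setNames(rep(NA_integer_, length(bgIds)), bgIds))

  # static network: p_in within complexes, p_out elsewhere
  idx <- utils::combn(length(allIds), 2L)
  u <- allIds[idx[1L, ]]; v <- allIds[idx[2L, ]]
  sameComplex <- !is.na(complexOf[u]) & !is.na(complexOf[v]) &
    complexOf[u] == complexOf[v]
  p <- ifelse(sameComplex, spec@pIn, spec@pOut)
  keep <- stats::runif(length(p)) < p
  static <- ppiNetwork(u[keep], v[keep], kind = "static")

  # active-stage schedule
  schedule <- spec@schedule
  if (length(schedule) == 0L)
    schedule <- rep(list(seq_len(spec@nStages)), spec@nComplexes)

  # expression: step function H during active stages, L otherwise
  nExprBg <- round(spec@bgExpressedFraction * spec@nBackground)
  exprBg <- sort(sample(bgIds, nExprBg))
  genes <- c(memberIds, exprBg)
  stageVal <- matrix(spec@lowValue, nrow = length(genes),
                     ncol = spec@nStages,
                     dimnames = list(genes, NULL))
  for (g in memberIds)
    stageVal[g, schedule[[complexOf[g]]]] <- spec@highValue
  for (g in exprBg) {
    hi <- stats::runif(spec@nStages) < 0.5
    stageVal[g, hi] <- spec@highValue
  }
  tp <- rep(sprintf("t%d", seq_len(spec@nStages)), each = spec@nReplicates)
  vals <- stageVal[, rep(seq_len(spec@nStages), each = spec@nReplicates),
                   drop = FALSE]
  if (spec@noiseSd > 0)
    vals <- pmax(0, vals + matrix(stats::rnorm(length(vals), 0,
                                               spec@noiseSd),
                                  nrow = nrow(vals)))
  expr <- expressionSeries(vals, tp)

  # annotations: private term per complex at the stated fidelity,
  # one decoy term per background node
  ann <- list()
  for (g in memberIds) {
    if (stats::runif(1) < spec@fidelity)
      ann[[g]] <- sprintf("GO:C%03d", complexOf[g])
  }
  for (g in bgIds)
    ann[[g]] <- sprintf("GO:D%03d", sample.int(spec@nDecoyTerms, 1L))
  annotations <- annotationMap(ann)

  truth <- complexSet(split(memberIds, membership),
                      labels = sprintf("T%d", seq_len(spec@nComplexes)))
  core <- unlist(lapply(split(memberIds, membership), function(m)
    m[seq_len(ceiling(length(m) / 2))]), use.names = FALSE)
  attachment <- setdiff(memberIds, core)

  list(static = static, expression = expr, annotations = annotations,
       truth = truth, core = core, attachment = attachment,
       membership = membership, spec = spec)
}

#' Write the five synthetic artifacts to a directory
#'
#' Files: edges.tsv, expression.tsv, annotations.tsv, complexes.tsv,
#' core.txt, attachment.txt -- all via the package's format writers, so
#' regeneration under the same spec is byte-identical.
#'
#' @param sim result of [generateSynthetic()].
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of the paths written.
#' @export
writeSyntheticFixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "edges.tsv"),
    expression = file.path(dir, "expression.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    complexes = file.path(dir, "complexes.tsv"),
    core = file.path(dir, "core.txt"),
    attachment = file.path(dir, "attachment.txt"))
  writeEdgeList(sim$static, paths["edges"])
  writeExpression(sim$expression, paths["expression"])
  writeAnnotations(sim$annotations, paths["annotations"])
  writeComplexes(sim$truth, paths["complexes"])
  writeProteinList(sim$core, paths["core"])
  writeProteinList(sim$attachment, paths["attachment"])
  invisible(paths)
}
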