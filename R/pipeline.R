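#' @include synthetic.R
NULL

#' Run the full prediction pipeline
#'
#' Dynamic network construction -> combined network -> GECluster ->
#' (optional) complex-level evaluation, from in-memory objects.  This is
#' the programmatic equivalent of the command-line `run-all`.
#'
#' @param static a [PPINetwork-class].
#' @param expression an [ExpressionSeries-class] (replicates collapsed, or
#'   pass the result of [readExpression()]).
#' @param annotations an [AnnotationMap-class].
#' @param reference optional reference [ComplexSet-class] for evaluation.
#' @param selection time-point selection (default: all).
#' @param mode activity aggregation over the selection, "any" or "all".
#' @param fsMin,minSize,overlap clustering parameters, see
#'   [geClusterConfig()].
#' @param mThres matching threshold for evaluation (default 0.2).
#' @param curateReference curate the reference to the dynamic network's
#'   nodes before matching (default TRUE).
#' @param useDynamic set FALSE to skip the expression filter and run on
#'   the static network directly (for dynamic-vs-static comparisons).
#' @return list with `dynamic`, `combined`, `predicted`
#'   ([ComplexSet-class]) and, when a reference is given, `evaluation`
#'   (see [evaluateComplexes()]).
#' @export
runPipeline <- function(static, expression, annotations, reference = NULL,
                        selection = NULL, mode = "any", fsMin = 0.25,
                        minSize = 3L, overlap = FALSE, mThres = 0.2,
                        curateReference = TRUE, useDynamic = TRUE) {
  if (useDynamic) {
    act <- computeActivity(expression)
    if (is.null(selection))
      selection <- colnames(activityFlags(act))
    net <- buildDynamic(static, act, selection = selection, mode = mode)
  } else {
    net <- static
  }
  sets <- buildGOProteinSets(annotations, net)
  combined <- buildCombined(net, sets)
  cfg <- geClusterConfig(fsMin = fsMin, minSize = minSize,
                         overlap = overlap)
  predicted <- geCluster(combined, net, cfg)
  out <- list(dynamic = net, combined = combined, predicted = predicted)
  if (!is.null(reference)) {
    out$evaluation <- evaluateComplexes(
      predicted, reference, mThres = mThres,
      curateTo = if (curateReference) net else NULL, minSize = minSize)
  }
  out
}

#' Sweep the FS-Weight threshold
#'
#' Re-runs the clusterer over a grid of `fsMin` values against a fixed
#' combined/dynamic network pair and reports complex-level
#' recall/precision/F1 at each value -- the data behind
#' threshold-selection curves.
#'
#' @param combined a [CombinedNetwork-class].
#' @param dynamic matching [PPINetwork-class].
#' @param reference reference [ComplexSet-class] (already curated).
#' @param fsGrid numeric vector of thresholds (default 0.05 steps).
#' @param minSize,mThres as elsewhere.
#' @return data.frame with columns fsMin, nPredicted, recall, precision,
#'   f1.
#' @export
sweepFsMin <- function(combined, dynamic, reference,
                       fsGrid = seq(0.05, 1, by = 0.05), minSize = 3L,
                       mThres = 0.2) {
  rows <- lapply(fsGrid, function(f) {
    pred <- geCluster(combined, dynamic,
                      geClusterConfig(fsMin = f, minSize = minSize))
    ev <- evaluateComplexes(pred, reference, mThres = mThres)
    data.frame(fsMin = f, nPredicted = length(pred), recall = ev$recall,
               precision = ev$precision, f1 = ev$f1)
  })
  do.call(rbind, rows)
}

#' Run the pipeline from a YAML config file
#'
#' Reads paths and parameters (edges, expression, annotations, optional
#' reference; fs_min, m_thres, min_size, mode, replicate_policy,
#' selection) and executes [runPipeline()], writing predicted complexes
#' and a JSON report.
#'
#' @param configPath path to a YAML file.
#' @param outDir output directory (default: directory of the config).
#' @return invisibly, the [runPipeline()] result.
#' @export
runPipelineConfig <- function(configPath, outDir = dirname(configPath)) {
  cfg <- yaml::read_yaml(configPath)
  need <- c("edges", "expression", "annotations")
  miss <- need[!vapply(need, function(k) !is.null(cfg[[k]]), logical(1))]
  if (length(miss))
    stop("config missing required path(s): ", paste(miss, collapse = ", "))
  for (k in intersect(c("edges", "expression", "annotations", "reference"),
                      names(cfg)))
    if (!file.exists(cfg[[k]]))
      stop("input file not found: ", cfg[[k]])
  static <- readEdgeList(cfg$edges)
  expr <- readExpression(cfg$expression,
                         replicatePolicy = cfg$replicate_policy %||% "mean")
  ann <- readAnnotations(cfg$annotations)
  ref <- if (!is.null(cfg$reference)) readComplexes(cfg$reference)
  res <- runPipeline(
    static, expr, ann, reference = ref,
    selection = cfg$selection, mode = cfg$mode %||% "any",
    fsMin = cfg$fs_min %||% 0.25, minSize = cfg$min_size %||% 3L,
    mThres = cfg$m_thres %||% 0.2)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeComplexes(res$predicted, file.path(outDir, "predicted.tsv"))
  report <- list(
    dynamic = provenance(res$dynamic),
    combined = list(nodes = nodeCount(res$combined),
                    edges = edgeCount(res$combined),
                    addedEdges = addedEdgeCount(res$combined)),
    predicted = length(res$predicted))
  if (!is.null(res$evaluation))
    report$evaluation <- res$evaluation[c("nRef", "nPred", "recall",
                                          "precision", "f1")]
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
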