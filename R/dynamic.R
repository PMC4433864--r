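#' @include io.R
NULL

#' Per-gene expression activity against the temporal mean
#'
#' A gene's mean is the arithmetic mean of its expression over all time
#' points of the series; the gene is flagged active at a time point when
#' its value there is greater than or equal to that mean.  The inclusive
#' comparison keeps constant (e.g. housekeeping) profiles active at every
#' time point.
#'
#' @param series an [ExpressionSeries-class]; replicate columns, if
#'   present, are averaged within their time point first.
#' @return an [ActivityTable-class].
#' @export
computeActivity <- function(series) {
  stopifnot(is(series, "ExpressionSeries"))
  v <- exprValues(series)
  if (nrow(v) == 0L || ncol(v) == 0L)
    stop("empty expression series")
  tp <- timePoints(series)
  tpo <- unique(tp)
  # average replicate columns within each time point first, so the
  # temporal mean weights every time point equally
  v <- vapply(tpo, function(lab)
    rowMeans(v[, tp == lab, drop = FALSE]), numeric(nrow(v)))
  v <- matrix(v, ncol = length(tpo),
              dimnames = list(rownames(exprValues(series)), tpo))
  mu <- rowMeans(v)
  act <- v >= mu
  new("ActivityTable", active = act, means = mu)
}

#' Activity accessors
#' @param x an [ActivityTable-class].
#' @return `activityFlags`: logical genes x time-points matrix;
#'   `geneMeans`: named numeric vector of per-gene temporal means.
#' @export
activityFlags <- function(x) {
  stopifnot(is(x, "ActivityTable"))
  x@active
}

#' @rdname activityFlags
#' @export
geneMeans <- function(x) {
  stopifnot(is(x, "ActivityTable"))
  x@means
}

#' Build a dynamic (condition-specific) PPI network
#'
#' Restricts a static PPI network to proteins expressed above their own
#' temporal mean at the selected time points.  A protein is retained iff
#' it is active at any (`mode = "any"`) or all (`mode = "all"`) selected
#' time points; proteins with no expression record are never retained.
#' Edges survive iff both endpoints are retained; retained nodes left
#' without any edge are dropped.
#'
#' @param static a [PPINetwork-class].
#' @param activity an [ActivityTable-class] from [computeActivity()].
#' @param selection character vector of time-point labels (default: all
#'   time points of the activity table).
#' @param mode "any" or "all".
#' @return a dynamic [PPINetwork-class]; its provenance records the
#'   selection, mode and counts of nodes dropped as inactive / unmeasured /
#'   isolated.
#' @export
buildDynamic <- function(static, activity,
                         selection = colnames(activityFlags(activity)),
                         mode = c("any", "all")) {
  stopifnot(is(static, "PPINetwork"), is(activity, "ActivityTable"))
  mode <- match.arg(mode)
  act <- activity@active
  if (length(selection) == 0L)
    stop("time-point selection must be non-empty")
  unknown <- setdiff(selection, colnames(act))
  if (length(unknown))
    stop("unknown time-point label(s): ", paste(unknown, collapse = ", "))
  sel <- act[, selection, drop = FALSE]
  keepFlag <- if (mode == "any") rowSums(sel) > 0L
              else rowSums(sel) == length(selection)
  activeGenes <- rownames(act)[keepFlag]
  nodes <- networkNodes(static)
  retained <- intersect(nodes, activeGenes)
  e <- networkEdges(static)
  keepE <- e[, 1L] %in% retained & e[, 2L] %in% retained
  kept <- e[keepE, , drop = FALSE]
  connected <- unique(c(kept))
  .newPPINetwork(
    nodes = connected, edges = kept, kind = "dynamic",
    provenance = list(
      source = "static", selection = selection, mode = mode,
      staticNodes = length(nodes), staticEdges = nrow(e),
      unmeasured = sum(!nodes %in% rownames(act)),
      inactive = sum(nodes %in% rownames(act) & !nodes %in% activeGenes),
      isolatedDropped = length(retained) - length(connected),
      keptNodes = length(connected), keptEdges = nrow(kept)))
}
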