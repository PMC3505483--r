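#' @useDynLib HetNetProx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' HeteroGraph: a typed, undirected heterogeneous graph
#'
#' A `HeteroGraph` stores typed nodes and typed, reliability-annotated edges
#' of an integrated biological network (genes, proteins, pathways, articles,
#' phenotypes, ... linked by relationships such as `codes_for` or
#' `interacts_with`). The graph is effectively undirected but edge types are
#' directed: every edge type has an inverse type (e.g. `codes_for` /
#' `coded_by`), and each undirected relation is stored once, in a canonical
#' direction. Querying the reverse direction reports the inverse type.
#'
#' Invariants enforced by the validity method: unique non-empty node ids,
#' registered node-incident edge types, no self loops, at most one edge per
#' unordered node pair, reliabilities in \[0, 1\].
#'
#' @slot nodes data.frame with columns `id`, `type`.
#' @slot edges data.frame with columns `from`, `to`, `type`, `reliability`,
#'   stored in canonical direction.
#' @slot edgeTypes data.frame with columns `type`, `inverse`: the edge-type
#'   registry. A symmetric type may be its own inverse.
#'
#' @seealso [heteroGraph()], [loadEdgeList()], [applyWeights()]
#' @export
setClass("HeteroGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 edgeTypes = "data.frame"))

#' WeightedGraph: a HeteroGraph with per-edge probabilities
#'
#' Produced by [applyWeights()]: each edge carries a weight
#' \eqn{p(e) = q(e) \cdot i(e) \cdot r(e)} combining relevance,
#' informativeness and reliability (optionally capped at 1 so that weights
#' are probabilities). All proximity measures operate on this class.
#'
#' @slot graph the underlying [HeteroGraph-class].
#' @slot weight numeric vector, one weight per edge row (parallel to
#'   `graphEdges(graph)`).
#' @slot config the `WeightingConfig` list used to produce the weights.
#' @export
setClass("WeightedGraph",
  representation(graph = "HeteroGraph", weight = "numeric", config = "list"))

#' ProximityEstimate: a node-proximity value with provenance
#'
#' @slot value the proximity estimate (in \[0,1\] for probabilistic
#'   measures; >= 1 for a defined expected reliable distance between
#'   distinct nodes; `NA` flags an undefined conditional distance).
#' @slot stdError Monte-Carlo standard error, or `NA` for exact values.
#' @slot method label of the measure that produced the value.
#' @slot seed seed used for stochastic estimation, or `NA`.
#' @export
setClass("ProximityEstimate",
  representation(value = "numeric", stdError = "numeric",
                 method = "character", seed = "numeric"))

#' RocCurve: a ROC curve with its AUC
#'
#' Points are ordered by non-decreasing false positive rate, starting at
#' (0,0) and ending at (1,1); tied scores are processed as a single group so
#' ties appear as diagonal segments. `auc` equals the trapezoidal area,
#' which coincides with the Mann-Whitney statistic with ties counted 1/2.
#'
#' @slot points numeric matrix with columns `fpr`, `tpr`.
#' @slot auc area under the curve in \[0,1\].
#' @export
setClass("RocCurve",
  representation(points = "matrix", auc = "numeric"))

#' PrioritizationCase: a candidate gene set with truth labels
#'
#' A candidate set `S` from (for example) an association study, split into
#' true positives `S_P` and negatives `S_N = S - S_P` for evaluation,
#' optionally with an external reference set `S_R` of already known disease
#' genes (disjoint from `S`).
#'
#' @slot candidates character vector `S`.
#' @slot truthPositive character vector `S_P` (subset of candidates; may be
#'   empty when truth is unknown).
#' @slot reference character vector `S_R`, disjoint from `S` (may be empty).
#' @export
setClass("PrioritizationCase",
  representation(candidates = "character", truthPositive = "character",
                 reference = "character"))

#' ClusterResult: output of the single-cluster classifier
#'
#' @slot cluster character vector: the selected subset \eqn{\hat S_P}.
#' @slot score cluster score \eqn{\sum_{s \ne t} (p(s,t) - q)} over ordered
#'   pairs within the cluster.
#' @slot sensitivityQ the sensitivity parameter q used.
#' @slot restarts number of greedy restarts performed.
#' @slot seed seed used for the random initializations.
#' @export
setClass("ClusterResult",
  representation(cluster = "character", score = "numeric",
                 sensitivityQ = "numeric", restarts = "numeric",
                 seed = "numeric"))

setValidity("HeteroGraph", function(object) {
  nd <- object@nodes; ed <- object@edges; reg <- object@edgeTypes
  msgs <- character()
  if (!all(c("id", "type") %in% names(nd)))
    return("nodes must have columns 'id' and 'type'")
  if (!all(c("from", "to", "type", "reliability") %in% names(ed)))
    return("edges must have columns 'from', 'to', 'type', 'reliability'")
  if (!all(c("type", "inverse") %in% names(reg)))
    return("edgeTypes must have columns 'type' and 'inverse'")
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "node ids must be unique")
  if (any(!nzchar(nd$id))) msgs <- c(msgs, "node ids must be non-empty")
  if (any(!nzchar(nd$type))) msgs <- c(msgs, "node types must be non-empty")
  if (nrow(ed)) {
    if (any(ed$from == ed$to)) msgs <- c(msgs, "self loops are not allowed")
    if (!all(ed$from %in% nd$id) || !all(ed$to %in% nd$id))
      msgs <- c(msgs, "edge endpoints must be registered nodes")
    if (any(ed$reliability < 0 | ed$reliability > 1))
      msgs <- c(msgs, "reliabilities must lie in [0, 1]")
    tm <- tryCatch(.typeMap(reg), error = function(e) conditionMessage(e))
    if (is.character(tm) && is.null(names(tm)) && length(tm) == 1L)
      return(tm)
    if (!all(ed$type %in% names(tm)))
      msgs <- c(msgs, "all edge types must be registered")
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "at most one edge per unordered node pair")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setValidity("WeightedGraph", function(object) {
  if (length(object@weight) != nrow(object@graph@edges))
    return("one weight per edge required")
  if (any(object@weight < 0)) return("weights must be non-negative")
  cap <- isTRUE(object@config$cap)
  if (cap && any(object@weight > 1))
    return("capped weights must lie in [0, 1]")
  TRUE
})

setValidity("RocCurve", function(object) {
  pts <- object@points
  if (ncol(pts) != 2L) return("points must have two columns (fpr, tpr)")
  if (nrow(pts) < 2L) return("a ROC curve needs at least two points")
  if (any(pts < -1e-12) || any(pts > 1 + 1e-12))
    return("ROC points must lie in [0,1]^2")
  if (any(diff(pts[, 1L]) < -1e-12)) return("FPR must be non-decreasing")
  if (max(abs(pts[1L, ])) > 1e-12 || max(abs(pts[nrow(pts), ] - 1)) > 1e-12)
    return("curve must start at (0,0) and end at (1,1)")
  area <- sum(diff(pts[, 1L]) * (utils::head(pts[, 2L], -1L) +
                                 utils::tail(pts[, 2L], -1L)) / 2)
  if (abs(area - object@auc) > 1e-8)
    return("auc must equal the trapezoidal area of the points")
  TRUE
})

setValidity("PrioritizationCase", function(object) {
  if (anyDuplicated(object@candidates)) return("duplicate candidates")
  if (!all(object@truthPositive %in% object@candidates))
    return("truthPositive must be a subset of candidates")
  if (length(intersect(object@reference, object@candidates)))
    return("reference set must be disjoint from the candidate set")
  TRUE
})
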