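# Link-prediction harness: score candidate node pairs by proximity,
# evaluate with ROC/AUC, compare AUCs with the paired DeLong test, sample
# negative pairs, and tune per-type relevance coefficients one at a time.

#' Build a labeled pair set
#'
#' @param node1,node2 character vectors of node ids.
#' @param label binary labels (1/TRUE = positive).
#' @param provenance free-text description.
#' @return data.frame of class `LabeledPairSet` with columns `node1`,
#'   `node2`, `label`; duplicate unordered pairs are rejected.
#' @export
labeledPairSet <- function(node1, node2, label, provenance = "") {
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("labels must be binary")
  if (any(node1 == node2)) stop("a pair must join two distinct nodes")
  df <- data.frame(node1 = as.character(node1),
                   node2 = as.character(node2),
                   label = label, stringsAsFactors = FALSE)
  key <- paste(pmin(df$node1, df$node2), pmax(df$node1, df$node2),
               sep = "\r")
  if (anyDuplicated(key)) stop("duplicate unordered pairs")
  attr(df, "provenance") <- provenance
  class(df) <- c("LabeledPairSet", "data.frame")
  df
}

#' Read labeled pairs from TSV (`node1<TAB>node2<TAB>label`, label in {1,0})
#' @param path file path.
#' @export
readLabeledPairs <- function(path) {
  lines <- .readLinesNoComments(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) != 3L))
    stop("labeled pairs file must have 3 tab-separated columns")
  m <- do.call(rbind, parts)
  if (identical(tolower(m[1L, 1L]), "node1")) m <- m[-1L, , drop = FALSE]
  labeledPairSet(m[, 1L], m[, 2L], as.integer(m[, 3L]),
                 provenance = path)
}

#' @param pairs a LabeledPairSet.
#' @rdname readLabeledPairs
#' @export
writeLabeledPairs <- function(pairs, path) {
  .writeTsv(as.data.frame(pairs)[, c("node1", "node2", "label")], path)
}

#' Score candidate node pairs by proximity
#'
#' One proximity value per pair, using the measure selected in `params`.
#' Pairs referencing nodes absent from the graph are scored 0 with a
#' warning rather than dropped (real candidate lists contain unindexed
#' entities and silently dropping them would bias the AUC). For the exact
#' random walk, all stationary vectors are solved in one batch.
#'
#' @param wg a [WeightedGraph-class].
#' @param pairs a [labeledPairSet()] or data.frame with columns `node1`,
#'   `node2`.
#' @param params a [proximityParams()].
#' @return the input data.frame with a `score` column appended.
#' @export
scorePairs <- function(wg, pairs, params = proximityParams()) {
  df <- as.data.frame(pairs, stringsAsFactors = FALSE)
  known <- wg@graph@nodes$id
  ok <- df$node1 %in% known & df$node2 %in% known
  if (any(!ok))
    warning(sum(!ok), " pair(s) reference nodes absent from the graph; ",
            "scored 0")
  score <- numeric(nrow(df))
  if (any(ok)) {
    sub <- df[ok, , drop = FALSE]
    if (params$measure == "random_walk" && params$rwMethod == "exact") {
      nodes <- unique(c(sub$node1, sub$node2))
      st <- .rwStationary(wg, nodes, params$beta)
      score[ok] <- (st[cbind(sub$node1, sub$node2)] +
                    st[cbind(sub$node2, sub$node1)]) / 2
    } else if (params$measure == "best_path") {
      pos <- wg@weight > 0
      ig <- .asIgraph(wg@graph@nodes, wg@graph@edges[pos, , drop = FALSE])
      nodes1 <- unique(sub$node1)
      d <- igraph::distances(ig, v = nodes1, to = unique(sub$node2),
                             weights = -log(wg@weight[pos]))
      score[ok] <- exp(-d[cbind(sub$node1, sub$node2)])
      score[ok][sub$node1 == sub$node2] <- 1
    } else {
      score[ok] <- vapply(seq_len(nrow(sub)), function(i) {
        v <- proximityValue(proximity(wg, sub$node1[i], sub$node2[i],
                                      params))
        if (is.na(v)) 0 else v
      }, 1)
    }
  }
  df$score <- score
  df
}

#' ROC curve and AUC for scored pairs
#'
#' The curve iterates pairs in descending score order; tied scores are
#' processed as a single group, producing a diagonal segment. The AUC
#' equals the trapezoidal area of the curve, which coincides with the
#' Mann-Whitney statistic counting ties as 1/2 (the probability that a
#' random positive outranks a random negative).
#'
#' @param scores numeric scores, or a data.frame from [scorePairs()] with
#'   `score` and `label` columns.
#' @param labels binary labels (ignored when `scores` is a data.frame
#'   carrying them).
#' @return a [RocCurve-class].
#' @examples
#' rocAuc(c(0.9, 0.5, 0.7, 0.1), c(1, 1, 0, 0))@auc  # 0.75
#' @export
rocAuc <- function(scores, labels = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$score
  }
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC evaluation needs at least one positive and one negative")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l == 1L, grp, sum)
  fp <- tapply(l == 0L, grp, sum)
  pts <- cbind(fpr = c(0, cumsum(fp) / nNeg),
               tpr = c(0, cumsum(tp) / nPos))
  rownames(pts) <- NULL
  auc <- sum(diff(pts[, 1L]) *
             (utils::head(pts[, 2L], -1L) + utils::tail(pts[, 2L], -1L)) / 2)
  new("RocCurve", points = pts, auc = auc)
}

setMethod("show", "RocCurve", function(object) {
  cat("RocCurve with", nrow(object@points), "points, AUC =",
      format(object@auc, digits = 4), "\n")
})

# placement values for the DeLong covariance structure
.placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), 1)
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), 1)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Compare two AUCs on the same labeled pairs (paired DeLong test)
#'
#' Both score vectors must cover the same labeled pairs. The two-sided
#' p-value comes from the paired nonparametric AUC-difference test based on
#' the covariance of placement values. Identical score vectors give a
#' difference of 0 and p-value 1.
#'
#' @param scoresA,scoresB numeric score vectors (same pair order).
#' @param labels binary labels.
#' @return list with `aucA`, `aucB`, `pValue`, `z`.
#' @export
compareAuc <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("score vectors must cover the same labeled pairs")
  pa <- .placements(scoresA, labels)
  pb <- .placements(scoresB, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  if (m < 2L || n < 2L)
    stop("need at least two positives and two negatives")
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  varD <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
          (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (varD <= .Machine$double.eps) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(varD)
  }
  p <- 2 * stats::pnorm(-abs(z))
  list(aucA = pa$auc, aucB = pb$auc, pValue = p, z = z)
}

#' Sample negative node pairs from the support of the positives
#'
#' Negatives are drawn uniformly from the unordered pairings of nodes that
#' appear in the positive pairs, excluding the positives themselves and any
#' pair matching the exclusion predicate (e.g. "linked in either database
#' version"). Sampling nodes from the positive support keeps the negatives
#' comparable in how well-studied they are, rather than drawing easy,
#' sparsely linked entities.
#'
#' @param positives data.frame/matrix with two columns of node ids.
#' @param n number of negative pairs to draw.
#' @param excluded optional vectorized predicate `function(a, b)` returning
#'   TRUE for pairs that must not be sampled.
#' @param seed optional seed.
#' @return data.frame with columns `node1`, `node2`.
#' @export
sampleNegativePairs <- function(positives, n, excluded = NULL, seed = NULL) {
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  a <- as.character(positives[[1L]]); b <- as.character(positives[[2L]])
  support <- sort(unique(c(a, b)))
  if (length(support) < 2L) stop("not enough support nodes")
  cand <- t(utils::combn(support, 2L))
  posKey <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  candKey <- paste(cand[, 1L], cand[, 2L], sep = "\r")
  keep <- !(candKey %in% posKey)
  if (!is.null(excluded))
    keep <- keep & !excluded(cand[, 1L], cand[, 2L])
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) < n)
    stop("insufficient candidate pairs after exclusion: ", nrow(cand),
         " available, ", n, " requested")
  pick <- .withSeed(seed, sample.int(nrow(cand), n))
  data.frame(node1 = cand[pick, 1L], node2 = cand[pick, 2L],
             stringsAsFactors = FALSE)
}

#' Tune per-type relevance coefficients one at a time
#'
#' Mirrors the manual optimization protocol: after applying any pinned
#' relevances (e.g. `codes_for = 10`), the effect of each edge type is
#' evaluated independently by varying its relevance over `grid` while all
#' other types stay at the default 1, measuring training AUC at each value.
#' Each type is then set to its AUC-maximizing value, or left at the
#' default when the best improvement over the default is below `tolerance`
#' (operationalizing "no noticeable effect"; default 0.002 AUC). The
#' heuristic deliberately ignores dependencies between edge types. As a
#' final guard the combined map is evaluated on the training pairs and
#' replaced by the pinned-only map if it underperforms the baseline.
#'
#' @param graph a [HeteroGraph-class] (unweighted; weights are recomputed
#'   at every grid point).
#' @param train a [labeledPairSet()] with both classes.
#' @param tuneTypes character vector of edge types to tune.
#' @param grid positive relevance values to try.
#' @param pinned a [relevanceMap()] of relevances fixed in advance.
#' @param config base [weightingConfig()] supplying `alpha`, `degreeMode`
#'   and `cap`; its relevance map is ignored. Defaults to uncapped weights
#'   for the random walk.
#' @param params [proximityParams()] for scoring; defaults to the exact
#'   random walk, the measure under which the relevance protocol was
#'   designed (capped best-path scores saturate at 1 for large relevances
#'   and lose all ranking signal).
#' @param tolerance minimum AUC improvement to adopt a non-default value.
#' @param validation optional held-out [labeledPairSet()]; must be disjoint
#'   from `train` (no shared unordered pair).
#' @return list with `relevance` (the tuned [relevanceMap()]), `profiles`
#'   (per-type data.frames of grid value vs training AUC), `baselineAuc`,
#'   `trainedAuc` and, when `validation` is given, `validationAuc`.
#' @export
tuneRelevances <- function(graph, train, tuneTypes, grid,
                           pinned = relevanceMap(),
                           config = weightingConfig(cap = FALSE),
                           params = proximityParams("random_walk"),
                           tolerance = 0.002,
                           validation = NULL) {
  if (!length(grid)) stop("grid must be non-empty")
  if (any(grid < 0)) stop("grid values must be non-negative")
  if (!is.null(validation)) {
    k1 <- paste(pmin(train$node1, train$node2),
                pmax(train$node1, train$node2), sep = "\r")
    k2 <- paste(pmin(validation$node1, validation$node2),
                pmax(validation$node1, validation$node2), sep = "\r")
    if (length(intersect(k1, k2)))
      stop("train and validation sets must not share node pairs")
  }
  evalMap <- function(values) {
    rel <- relevanceMap(values, default = 1)
    cfg <- weightingConfig(alpha = config$alpha,
                           degreeMode = config$degreeMode,
                           cap = config$cap, relevance = rel)
    wg <- applyWeights(graph, cfg)
    sc <- suppressWarnings(scorePairs(wg, train, params))
    rocAuc(sc)@auc
  }
  pinnedValues <- pinned$values
  baseline <- evalMap(pinnedValues)
  profiles <- list()
  chosen <- pinnedValues
  for (ty in setdiff(tuneTypes, names(pinnedValues))) {
    aucs <- vapply(grid, function(v) {
      vals <- pinnedValues
      vals[ty] <- v
      evalMap(vals)
    }, 1)
    profiles[[ty]] <- data.frame(value = grid, auc = aucs)
    best <- which.max(aucs)
    if (aucs[best] - baseline >= tolerance)
      chosen[ty] <- grid[best]
  }
  trainedAuc <- evalMap(chosen)
  if (trainedAuc < baseline) {  # guard: never underperform the baseline
    chosen <- pinnedValues
    trainedAuc <- baseline
  }
  out <- list(relevance = relevanceMap(chosen, default = 1),
              profiles = profiles, baselineAuc = baseline,
              trainedAuc = trainedAuc)
  if (!is.null(validation)) {
    rel <- out$relevance
    cfg <- weightingConfig(alpha = config$alpha,
                           degreeMode = config$degreeMode,
                           cap = config$cap, relevance = rel)
    wg <- applyWeights(graph, cfg)
    sc <- suppressWarnings(scorePairs(wg, validation, params))
    out$validationAuc <- rocAuc(sc)@auc
  }
  out
}
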