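# Candidate-gene prioritization: supervised reference-set scoring,
# leave-one-out evaluation protocol, k-nearest-neighbour scoring, and the
# single-cluster classifier with greedy multi-restart search.

#' Build a prioritization case
#'
#' @param candidates candidate gene ids `S`.
#' @param truthPositive known true positives `S_P` (subset of `S`); the
#'   rest of `S` are the negatives `S_N`.
#' @param reference optional external reference set `S_R` of known disease
#'   genes, disjoint from `S`.
#' @return a [PrioritizationCase-class].
#' @export
prioritizationCase <- function(candidates, truthPositive = character(),
                               reference = character()) {
  new("PrioritizationCase", candidates = as.character(candidates),
      truthPositive = as.character(truthPositive),
      reference = as.character(reference))
}

#' @rdname prioritizationCase
#' @param case a PrioritizationCase.
#' @export
truthNegatives <- function(case) {
  setdiff(case@candidates, case@truthPositive)
}

#' Read a prioritization case from JSON
#'
#' Format: `{"candidates": [...], "reference": [...], "truth_positive":
#' [...]}` with the last two optional.
#' @param path JSON file path.
#' @export
readPrioritizationCase <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prioritizationCase(x$candidates,
                     truthPositive = if (is.null(x$truth_positive))
                       character() else x$truth_positive,
                     reference = if (is.null(x$reference)) character()
                       else x$reference)
}

setMethod("show", "PrioritizationCase", function(object) {
  cat("PrioritizationCase:", length(object@candidates), "candidates (",
      length(object@truthPositive), "known positive ),",
      length(object@reference), "reference genes\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: |cluster| =", length(object@cluster), ", score =",
      format(object@score, digits = 5), ", q =", object@sensitivityQ, "\n")
})

.checkProx <- function(prox, ids) {
  if (is.null(dimnames(prox)[[1L]]))
    stop("proximity matrix must carry node ids as dimnames")
  missing <- setdiff(ids, rownames(prox))
  if (length(missing))
    stop("proximity matrix lacks node(s): ",
         paste(missing, collapse = ", "))
}

#' Supervised scores: average proximity to a reference set
#'
#' `score(s) = 1/|S_R| * sum_{t in S_R} p(s, t)` for every candidate.
#'
#' @param prox symmetric proximity matrix over `S` and `S_R` (dimnames
#'   required), from [proximityMatrix()].
#' @param case a [prioritizationCase()] with a non-empty reference set.
#' @return named numeric vector of candidate scores.
#' @export
supervisedScores <- function(prox, case) {
  if (!length(case@reference)) stop("reference set is empty")
  .checkProx(prox, c(case@candidates, case@reference))
  rowMeans(prox[case@candidates, case@reference, drop = FALSE])
}

#' Leave-one-out supervised scores (evaluation protocol)
#'
#' When no external reference set exists, each known positive `p` is scored
#' with the reference `S_P \ {p}`, and each negative is scored as the
#' average over all size-`|S_P| - 1` subsets of `S_P` (every subset used
#' equally often; the full average over subsets algebraically equals the
#' mean proximity to all of `S_P`, since each positive appears in exactly
#' `|S_P| - 1` of the `|S_P|` subsets). Requires known truth labels: this
#' is an evaluation protocol, not a field method.
#'
#' @param prox symmetric proximity matrix over `S`.
#' @param case a [prioritizationCase()] with `|S_P| >= 2`.
#' @return named numeric vector of scores over all candidates.
#' @export
looSupervisedScores <- function(prox, case) {
  sp <- case@truthPositive
  if (length(sp) < 2L) stop("leave-one-out needs at least 2 positives")
  .checkProx(prox, case@candidates)
  sn <- truthNegatives(case)
  scores <- numeric(0)
  # positives: mean proximity to the other positives (diagonal never read)
  for (p in sp) {
    others <- setdiff(sp, p)
    scores[p] <- mean(prox[p, others])
  }
  # negatives: exact average over all leave-one-out subsets = mean over S_P
  if (length(sn))
    scores[sn] <- rowMeans(prox[sn, sp, drop = FALSE])
  scores[case@candidates]
}

#' K-nearest-neighbour scores
#'
#' `score(s)` is the mean of the `k` largest proximities from `s` to the
#' other candidates: false positives of an association study are unlikely
#' to have several close neighbours in the candidate set, while genuinely
#' related genes are. Default `k = 4` (found suitable when five true
#' positives are expected).
#'
#' @param prox symmetric proximity matrix over the candidates.
#' @param candidates candidate ids (defaults to the matrix dimnames).
#' @param k number of neighbours, `1 <= k <= |S| - 1`.
#' @return named numeric vector of scores.
#' @export
knnScores <- function(prox, candidates = rownames(prox), k = 4L) {
  .checkProx(prox, candidates)
  n <- length(candidates)
  if (k < 1L || k > n - 1L) stop("k must lie in [1, |S| - 1]")
  out <- vapply(candidates, function(s) {
    v <- prox[s, setdiff(candidates, s)]
    mean(sort(v, decreasing = TRUE)[seq_len(k)])
  }, 1)
  stats::setNames(out, candidates)
}

#' Cluster score of a candidate subset
#'
#' `Score = sum over ordered pairs (s, t), s != t, within the subset of
#' (p(s, t) - q)`; with a symmetric proximity this is twice the sum over
#' unordered pairs. Empty and singleton subsets score 0. `q` is the
#' sensitivity parameter: adding a gene increases the score exactly when
#' its average proximity to the current cluster exceeds `q`.
#'
#' @param prox symmetric proximity matrix.
#' @param subset character vector of member ids.
#' @param q sensitivity threshold.
#' @return numeric score.
#' @export
clusterScore <- function(prox, subset, q) {
  if (length(subset) < 2L) return(0)
  .checkProx(prox, subset)
  pm <- prox[subset, subset, drop = FALSE]
  2 * sum(pm[upper.tri(pm)] - q)
}

#' Single-cluster selection by greedy multi-restart search
#'
#' Finds a candidate subset (approximately) maximizing [clusterScore()],
#' the single-cluster relaxation of the maximum edge-weighted clique
#' problem. From each random initial subset (each candidate included
#' independently with probability 1/2), all `|S|` single-element moves
#' between the cluster and its complement are evaluated and the move with
#' the largest strictly positive improvement is applied (ties broken by the
#' smallest node id for reproducibility) until no move improves. The
#' best-scoring terminal state over `restarts` initializations is returned;
#' the empty cluster (score 0) is admissible.
#'
#' @param prox symmetric proximity matrix over the candidates.
#' @param candidates candidate ids.
#' @param q sensitivity threshold.
#' @param restarts number of random initializations (default 100; more
#'   yields no practical improvement).
#' @param seed optional seed.
#' @return a [ClusterResult-class].
#' @export
clusterSelect <- function(prox, candidates = rownames(prox), q,
                          restarts = 100L, seed = NULL) {
  .checkProx(prox, candidates)
  if (restarts < 1L) stop("restarts must be >= 1")
  candidates <- sort(candidates)  # tie-break order: smallest id first
  n <- length(candidates)
  pm <- prox[candidates, candidates, drop = FALSE]
  diag(pm) <- 0  # the diagonal is never read by the score
  pq <- pm - q
  diag(pq) <- 0
  bestScore <- 0
  bestCluster <- character()
  .withSeed(seed, {
    for (r in seq_len(restarts)) {
      inC <- stats::runif(n) < 0.5
      # contribution of s: sum_{t in C, t != s} (p(s,t) - q)
      contrib <- as.numeric(pq %*% inC)
      score <- sum(contrib[inC])
      repeat {
        delta <- ifelse(inC, -2 * contrib, 2 * contrib)
        best <- which.max(delta)
        if (delta[best] <= 1e-12) break
        s <- best
        if (inC[s]) {
          inC[s] <- FALSE
          contrib <- contrib - pq[, s]
        } else {
          inC[s] <- TRUE
          contrib <- contrib + pq[, s]
        }
        # contrib[s] itself is unchanged by s's own move (C \ {s} fixed,
        # and the diagonal of pq is zero)
        score <- score + delta[best]
      }
      if (score > bestScore + 1e-12) {
        bestScore <- score
        bestCluster <- candidates[inC]
      }
    }
  })
  new("ClusterResult", cluster = bestCluster, score = bestScore,
      sensitivityQ = q, restarts = as.numeric(restarts),
      seed = as.numeric(if (is.null(seed)) NA_real_ else seed))
}

#' Threshold a score vector into predicted positives/negatives
#'
#' `S_P = {s : score(s) >= cutoff}` (>= convention), `S_N` the rest.
#'
#' @param scores named numeric vector.
#' @param cutoff threshold.
#' @return list with `positive` and `negative` id vectors.
#' @export
thresholdClassify <- function(scores, cutoff) {
  list(positive = names(scores)[scores >= cutoff],
       negative = names(scores)[scores < cutoff])
}

#' Pseudo-ROC for the cluster-based classifier
#'
#' The cluster classifier partitions rather than ranks, so a conventional
#' ROC cannot be built from a single run. Instead, for each sensitivity
#' value in `qGrid`, [clusterSelect()] is run on every case; each case's
#' true/false positive rate is computed from the selected cluster against
#' the truth labels, and the rates are averaged across cases to give one
#' composite point per `q`. Points are ordered by decreasing `q`; the
#' resulting curve is not guaranteed to be monotone and is returned as-is.
#'
#' @param cases list of [prioritizationCase()]s with truth labels.
#' @param proxList list of proximity matrices, one per case (a single
#'   matrix covering all cases may be given).
#' @param qGrid sensitivity thresholds (non-empty).
#' @param restarts greedy restarts per run.
#' @param seed optional seed.
#' @return data.frame with columns `q`, `fpr`, `tpr` (one composite point
#'   per threshold, ordered by decreasing `q`).
#' @export
clusterPseudoRoc <- function(cases, proxList, qGrid, restarts = 100L,
                             seed = NULL) {
  if (!length(qGrid)) stop("qGrid must be non-empty")
  if (is.matrix(proxList)) proxList <- rep(list(proxList), length(cases))
  stopifnot(length(proxList) == length(cases))
  qGrid <- sort(qGrid, decreasing = TRUE)
  seeds <- if (is.null(seed)) rep(list(NULL), length(qGrid))
           else as.list(seed + seq_along(qGrid))
  rows <- lapply(seq_along(qGrid), function(qi) {
    q <- qGrid[qi]
    tprs <- fprs <- numeric(length(cases))
    for (ci in seq_along(cases)) {
      case <- cases[[ci]]
      res <- clusterSelect(proxList[[ci]], case@candidates, q,
                           restarts = restarts, seed = seeds[[qi]])
      sp <- case@truthPositive
      sn <- truthNegatives(case)
      tprs[ci] <- if (length(sp)) length(intersect(res@cluster, sp)) /
        length(sp) else 0
      fprs[ci] <- if (length(sn)) length(intersect(res@cluster, sn)) /
        length(sn) else 0
    }
    c(q = q, fpr = mean(fprs), tpr = mean(tprs))
  })
  as.data.frame(do.call(rbind, rows))
}
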