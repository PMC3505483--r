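# Independent brute-force oracles used to verify the implementations.
# These deliberately avoid the code paths they check.

# max over all simple paths of the product of edge weights
bruteBestPath <- function(wg, s, t) {
  ed <- graphEdges(wg)
  w <- edgeWeights(wg)
  if (s == t) return(1)
  best <- 0
  recurse <- function(cur, visited, prob) {
    inc <- which((ed$from == cur | ed$to == cur) & w > 0)
    for (e in inc) {
      nxt <- if (ed$from[e] == cur) ed$to[e] else ed$from[e]
      if (nxt %in% visited) next
      p <- prob * w[e]
      if (nxt == t) {
        if (p > best) best <<- p
      } else {
        recurse(nxt, c(visited, nxt), p)
      }
    }
  }
  recurse(s, s, 1)
  best
}

# AUC as the exhaustive concordant-pair count with ties worth 1/2
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# vectorized Mann-Whitney AUC (outer comparison; independent of rocAuc)
vecAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# paired permutation test for an AUC difference: under the null the two
# score vectors are exchangeable within each pair
permutationAucTest <- function(scoresA, scoresB, labels, nPerm = 10000,
                               seed = 1) {
  set.seed(seed)
  obs <- abs(vecAuc(scoresA, labels) - vecAuc(scoresB, labels))
  n <- length(labels)
  hits <- 0
  for (i in seq_len(nPerm)) {
    flip <- runif(n) < 0.5
    a <- ifelse(flip, scoresB, scoresA)
    b <- ifelse(flip, scoresA, scoresB)
    d <- abs(vecAuc(a, labels) - vecAuc(b, labels))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  hits / nPerm
}

# exhaustive single-cluster optimum over all 2^n subsets, by accumulating
# each unordered pair's margin into every mask containing both members
bruteClusterOptimum <- function(prox, candidates, q) {
  n <- length(candidates)
  masks <- 0:(2^n - 1)
  sc <- numeric(length(masks))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    both <- bitwAnd(masks, bitwOr(2^(i - 1), 2^(j - 1))) ==
      bitwOr(2^(i - 1), 2^(j - 1))
    sc[both] <- sc[both] + 2 * (prox[candidates[i], candidates[j]] - q)
  }
  best <- which.max(sc)
  if (sc[best] <= 0) return(list(score = 0, cluster = character()))
  mask <- masks[best]
  list(score = sc[best],
       cluster = candidates[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
}

# leave-one-out protocol by explicit enumeration of all reference subsets
bruteLooScores <- function(prox, case) {
  sp <- case@truthPositive
  sn <- setdiff(case@candidates, sp)
  k <- length(sp) - 1L
  scores <- numeric(0)
  for (p in sp) scores[p] <- mean(prox[p, setdiff(sp, p)])
  subsets <- combn(sp, k, simplify = FALSE)
  for (n in sn)
    scores[n] <- mean(vapply(subsets, function(sr) mean(prox[n, sr]), 1))
  scores[case@candidates]
}
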