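# Node proximity measures on weighted graphs: probability of best path,
# two-terminal network reliability, expected reliable distance, and the
# symmetric random walk with restart. Monte-Carlo estimators carry explicit
# seeds and standard errors; an exhaustive oracle verifies the estimators
# on small instances.

# run expr with a locally seeded RNG, restoring global state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters for proximity computation
#'
#' @param measure one of `"best_path"`, `"reliability"`,
#'   `"expected_reliable_distance"`, `"random_walk"`.
#' @param beta restart probability in (0,1) for the random walk;
#'   default 0.2.
#' @param nSamples Monte-Carlo realizations for the probabilistic
#'   estimators; default 10000.
#' @param rwMethod `"exact"` (sparse linear solve of the stationary
#'   distribution, tolerance ~1e-12) or `"simulate"` (walk simulation
#'   counting visit frequencies).
#' @param rwIterations simulation length; default 1e6 steps.
#' @param seed seed for all stochastic operations (identical seeds
#'   reproduce identical estimates bit-for-bit); `NA` leaves the RNG
#'   state alone.
#' @param bound logical: evaluate Monte-Carlo measures on the bounded
#'   neighborhood subgraph around the two terminals (default TRUE; the
#'   exact computation of reliability and conditional distance is
#'   intractable on large graphs).
#' @param maxNodes,maxDepth bounding parameters passed to
#'   [neighborhoodSubgraph()]; defaults 1000 nodes, 4 hops.
#' @return an object of class `ProximityParams` (a list).
#' @export
proximityParams <- function(measure = c("random_walk", "best_path",
                                        "reliability",
                                        "expected_reliable_distance"),
                            beta = 0.2, nSamples = 10000L,
                            rwMethod = c("exact", "simulate"),
                            rwIterations = 1e6, seed = NA_integer_,
                            bound = TRUE, maxNodes = 1000L, maxDepth = 4L) {
  measure <- match.arg(measure)
  rwMethod <- match.arg(rwMethod)
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)")
  if (nSamples < 1) stop("nSamples must be positive")
  if (rwIterations < 1) stop("rwIterations must be positive")
  structure(list(measure = measure, beta = beta,
                 nSamples = as.integer(nSamples), rwMethod = rwMethod,
                 rwIterations = rwIterations, seed = seed,
                 bound = isTRUE(bound), maxNodes = as.integer(maxNodes),
                 maxDepth = as.integer(maxDepth)),
            class = "ProximityParams")
}

.newEstimate <- function(value, stdError = NA_real_, method = "exact",
                         seed = NA_real_) {
  new("ProximityEstimate", value = as.numeric(value),
      stdError = as.numeric(stdError), method = method,
      seed = as.numeric(if (is.null(seed)) NA_real_ else seed))
}

setMethod("show", "ProximityEstimate", function(object) {
  cat("ProximityEstimate [", object@method, "]: ",
      format(object@value, digits = 6), sep = "")
  if (!is.na(object@stdError))
    cat(" +/-", format(object@stdError, digits = 3))
  cat("\n")
})

#' @rdname proximityValue
#' @export
setGeneric("proximityValue", function(x) standardGeneric("proximityValue"))

#' Extract the numeric value / standard error of a ProximityEstimate
#' @param x a [ProximityEstimate-class] (numbers pass through unchanged).
#' @rdname proximityValue
#' @export
setMethod("proximityValue", "ProximityEstimate", function(x) x@value)
#' @rdname proximityValue
#' @export
setMethod("proximityValue", "numeric", function(x) x)

#' @rdname proximityValue
#' @export
setGeneric("proximityStdError", function(x) standardGeneric("proximityStdError"))
#' @rdname proximityValue
#' @export
setMethod("proximityStdError", "ProximityEstimate", function(x) x@stdError)

.checkNodes <- function(wg, ids) {
  missing <- setdiff(ids, wg@graph@nodes$id)
  if (length(missing))
    stop("unknown node(s): ", paste(missing, collapse = ", "))
}

.checkCapped <- function(wg) {
  if (any(wg@weight > 1))
    stop("this measure requires capped edge weights in [0, 1]; ",
         "use weightingConfig(cap = TRUE)")
}

#' Probability of the best path between two nodes
#'
#' The probability of a path is the product of its edge probabilities; the
#' measure is the maximum over all s-t paths, computed as a shortest path
#' under the -log transform of the weights. Zero-weight edges are treated
#' as absent. Returns 0 for disconnected pairs and 1 for `s == t`.
#'
#' @param wg a [WeightedGraph-class] with capped weights.
#' @param s,t node ids.
#' @return numeric in \[0, 1\].
#' @export
bestPathProbability <- function(wg, s, t) {
  .checkNodes(wg, c(s, t))
  .checkCapped(wg)
  if (s == t) return(1)
  pos <- wg@weight > 0
  ig <- .asIgraph(wg@graph@nodes, wg@graph@edges[pos, , drop = FALSE])
  d <- igraph::distances(ig, v = s, to = t, weights = -log(wg@weight[pos]))
  unname(exp(-d[1L, 1L]))
}

#' Sample one random realization of a probabilistic graph
#'
#' Each edge is kept independently with probability equal to its weight.
#'
#' @param wg a [WeightedGraph-class] with capped weights.
#' @param seed optional seed.
#' @return logical vector over the edge rows: kept or not.
#' @export
sampleRealization <- function(wg, seed = NULL) {
  if (any(wg@weight < 0 | wg@weight > 1))
    stop("realization sampling requires weights in [0, 1]")
  .withSeed(seed, stats::runif(length(wg@weight)) < wg@weight)
}

# bounded two-terminal working subgraph + integer-indexed edge list
.mcPrepare <- function(wg, s, t, params) {
  sub <- if (params$bound)
    neighborhoodSubgraph(wg, c(s, t), params$maxNodes, params$maxDepth)
  else wg
  pos <- sub@weight > 0
  edges <- sub@graph@edges[pos, , drop = FALSE]
  ids <- sub@graph@nodes$id
  idx <- stats::setNames(seq_along(ids), ids)
  list(from = unname(idx[edges$from]), to = unname(idx[edges$to]),
       w = sub@weight[pos], nv = length(ids), s = unname(idx[s]),
       t = unname(idx[t]))
}

#' Two-terminal network reliability (Monte-Carlo)
#'
#' Estimates the probability that a random realization of the probabilistic
#' graph (each edge kept independently with its weight) contains a path
#' between `s` and `t`, as the fraction of `nSamples` realizations in which
#' the terminals are connected. The standard error is
#' `sqrt(v * (1 - v) / n)`. By default the estimate is computed on the
#' bounded neighborhood subgraph around the terminals.
#'
#' @param wg a [WeightedGraph-class] with capped weights.
#' @param s,t node ids.
#' @param params a [proximityParams()].
#' @return a [ProximityEstimate-class].
#' @seealso [exactReliabilityOracle()] for the exhaustive small-instance
#'   computation.
#' @export
networkReliability <- function(wg, s, t,
                               params = proximityParams("reliability")) {
  .checkNodes(wg, c(s, t))
  .checkCapped(wg)
  if (s == t) return(.newEstimate(1, 0, "reliability", params$seed))
  pr <- .mcPrepare(wg, s, t, params)
  d <- .withSeed(params$seed,
                 cpp_mc_distances(pr$from, pr$to, pr$w, pr$nv, pr$s, pr$t,
                                  params$nSamples))
  v <- mean(d >= 0L)
  .newEstimate(v, sqrt(v * (1 - v) / params$nSamples), "reliability",
               params$seed)
}

#' Expected reliable distance (Monte-Carlo)
#'
#' Estimates the expected hop-count shortest-path distance between `s` and
#' `t` conditioned on the terminals being connected in the realization:
#' the mean distance over connected sampled realizations. When no sampled
#' realization connects the terminals, the conditional distance is
#' undefined and the value is `NA`.
#'
#' @inheritParams networkReliability
#' @return a [ProximityEstimate-class]; `value` is `NA` when undefined.
#' @export
expectedReliableDistance <- function(wg, s, t,
                                     params = proximityParams(
                                       "expected_reliable_distance")) {
  .checkNodes(wg, c(s, t))
  .checkCapped(wg)
  if (s == t)
    return(.newEstimate(0, 0, "expected_reliable_distance", params$seed))
  pr <- .mcPrepare(wg, s, t, params)
  d <- .withSeed(params$seed,
                 cpp_mc_distances(pr$from, pr$to, pr$w, pr$nv, pr$s, pr$t,
                                  params$nSamples))
  conn <- d[d >= 0L]
  if (!length(conn))
    return(.newEstimate(NA_real_, NA_real_, "expected_reliable_distance",
                        params$seed))
  se <- if (length(conn) > 1L) stats::sd(conn) / sqrt(length(conn)) else NA_real_
  .newEstimate(mean(conn), se, "expected_reliable_distance", params$seed)
}

#' Exact reliability and expected reliable distance by enumeration
#'
#' Enumerates all `2^|E|` realizations of the probabilistic graph, summing
#' the realization probabilities of those connecting `s` and `t`
#' (reliability) and the probability-weighted conditional hop distances
#' (expected reliable distance). Exact to floating point; limited to 20
#' edges. This is the brute-force verifier for the Monte-Carlo estimators.
#'
#' @param wg a [WeightedGraph-class] with capped weights (at most 20
#'   edges).
#' @param s,t node ids.
#' @return named list with elements `reliability` and `erd` (`NA` when the
#'   terminals are never connected).
#' @export
exactReliabilityOracle <- function(wg, s, t) {
  .checkNodes(wg, c(s, t))
  .checkCapped(wg)
  if (edgeCount(wg) > 20L)
    stop("exactReliabilityOracle supports at most 20 edges")
  params <- proximityParams("reliability", bound = FALSE)
  pr <- .mcPrepare(wg, s, t, params)
  out <- cpp_exact_reliability(pr$from, pr$to, pr$w, pr$nv, pr$s, pr$t)
  list(reliability = out[1L], erd = out[2L])
}

# --- random walk with restart ---------------------------------------------

# component membership over positive-weight edges
.componentsOf <- function(wg) {
  pos <- wg@weight > 0
  ig <- .asIgraph(wg@graph@nodes, wg@graph@edges[pos, , drop = FALSE])
  comp <- igraph::components(ig)$membership
  comp[wg@graph@nodes$id]
}

# Stationary distributions of the restarting walk for several source nodes.
# Returns a matrix rows = sources, cols = all node ids. The walk restarts
# to its source with probability beta and otherwise moves to a neighbour
# with probability proportional to edge weight; within a connected
# component of the positive-weight graph no node is dangling, and an
# isolated source yields the point mass on itself.
.rwStationary <- function(wg, sources, beta) {
  ids <- wg@graph@nodes$id
  out <- matrix(0, nrow = length(sources), ncol = length(ids),
                dimnames = list(sources, ids))
  comp <- .componentsOf(wg)
  pos <- wg@weight > 0
  ed <- wg@graph@edges[pos, , drop = FALSE]
  w <- wg@weight[pos]
  idx <- stats::setNames(seq_along(ids), ids)
  for (cid in unique(comp[sources])) {
    members <- ids[comp == cid]
    src <- sources[comp[sources] == cid]
    if (length(members) == 1L) {
      out[src, members] <- 1
      next
    }
    sel <- ed$from %in% members  # both endpoints share the component
    ef <- idx[ed$from[sel]]; et <- idx[ed$to[sel]]; ew <- w[sel]
    local <- stats::setNames(seq_along(members), members)
    i <- c(local[ids[ef]], local[ids[et]])
    j <- c(local[ids[et]], local[ids[ef]])
    W <- Matrix::sparseMatrix(i = i, j = j, x = c(ew, ew),
                              dims = c(length(members), length(members)))
    deg <- Matrix::rowSums(W)
    P <- W / deg
    A <- Matrix::Diagonal(length(members)) - (1 - beta) * Matrix::t(P)
    B <- Matrix::sparseMatrix(i = unname(local[src]),
                              j = seq_along(src), x = beta,
                              dims = c(length(members), length(src)))
    pi <- as.matrix(Matrix::solve(A, B))
    out[src, members] <- t(pi)
  }
  out
}

# simulated directed score d'_RW(s, t): visit frequency at t
.rwSimulate <- function(wg, s, beta, iters) {
  ids <- wg@graph@nodes$id
  idx <- stats::setNames(seq_along(ids), ids)
  pos <- wg@weight > 0
  ed <- wg@graph@edges[pos, , drop = FALSE]
  w <- wg@weight[pos]
  # CSR adjacency with cumulative weights
  from <- c(unname(idx[ed$from]), unname(idx[ed$to]))
  to <- c(unname(idx[ed$to]), unname(idx[ed$from]))
  ww <- c(w, w)
  ord <- order(from)
  from <- from[ord]; to <- to[ord]; ww <- ww[ord]
  cnt <- tabulate(from, nbins = length(ids))
  ptr <- c(0L, cumsum(cnt))
  cumw <- ww
  for (v in seq_along(ids)) {
    lo <- ptr[v] + 1L; hi <- ptr[v + 1L]
    if (hi >= lo) cumw[lo:hi] <- cumsum(ww[lo:hi])
  }
  visits <- cpp_rw_visits(ptr, to, cumw, beta, unname(idx[s]), iters,
                          length(ids))
  stats::setNames(visits[-1L], ids) / iters
}

#' Symmetric random walk with restart proximity
#'
#' The directed score `d'_RW(s, t)` is the stationary probability of a walk
#' that at each step restarts to `s` with probability `beta` and otherwise
#' moves to a random neighbor with probability proportional to the edge
#' weight; the proximity is the symmetric average
#' `(d'_RW(s,t) + d'_RW(t,s)) / 2`. Uncapped weights are allowed. With
#' `rwMethod = "exact"` the stationary system is solved directly; with
#' `"simulate"` the walk is run for `rwIterations` steps and visits at the
#' target are counted (every step counts; a restart counts as a visit to
#' the source, and a node without neighbors forces a restart).
#'
#' @inheritParams networkReliability
#' @return a [ProximityEstimate-class].
#' @examples
#' reg <- edgeTypeRegistry("interacts_with")
#' g <- heteroGraph(data.frame(id = c("a", "b"), type = "Protein"),
#'                  data.frame(from = "a", to = "b",
#'                             type = "interacts_with", reliability = 1))
#' wg <- applyWeights(g, weightingConfig(alpha = 0, cap = FALSE))
#' # closed form: pi = beta e_s + (1 - beta) pi P gives pi(t) = 4/9
#' randomWalkProximity(wg, "a", "b",
#'                     proximityParams("random_walk", beta = 0.2))
#' @export
randomWalkProximity <- function(wg, s, t,
                                params = proximityParams("random_walk")) {
  .checkNodes(wg, c(s, t))
  if (params$rwMethod == "exact") {
    st <- .rwStationary(wg, unique(c(s, t)), params$beta)
    val <- (st[s, t] + st[t, s]) / 2
    return(.newEstimate(unname(val), NA_real_, "random_walk", params$seed))
  }
  val <- .withSeed(params$seed, {
    fwd <- .rwSimulate(wg, s, params$beta, params$rwIterations)[t]
    bwd <- .rwSimulate(wg, t, params$beta, params$rwIterations)[s]
    (fwd + bwd) / 2
  })
  se <- sqrt(val * (1 - val) / params$rwIterations)  # rough binomial scale
  .newEstimate(unname(val), unname(se), "random_walk_sim", params$seed)
}

#' Compute one proximity value
#'
#' Dispatches to the measure selected in `params`.
#'
#' @inheritParams networkReliability
#' @return a [ProximityEstimate-class].
#' @export
proximity <- function(wg, s, t, params = proximityParams()) {
  switch(params$measure,
    best_path = .newEstimate(bestPathProbability(wg, s, t),
                             NA_real_, "best_path", params$seed),
    reliability = networkReliability(wg, s, t, params),
    expected_reliable_distance = expectedReliableDistance(wg, s, t, params),
    random_walk = randomWalkProximity(wg, s, t, params))
}

#' Symmetric proximity matrix over a node set
#'
#' Computes all pairwise proximities among `nodes`. The matrix is symmetric
#' by construction (the random-walk score is the symmetric average of the
#' two rooted scores; the probabilistic measures are inherently symmetric).
#' The diagonal is the self-proximity for the random walk and 1.0 for the
#' probabilistic measures; classifier scores never read it. For the exact
#' random walk all stationary distributions are obtained from one sparse
#' factorization per connected component, so large batches stay cheap.
#'
#' @param wg a [WeightedGraph-class].
#' @param nodes character vector of node ids.
#' @param params a [proximityParams()].
#' @return numeric matrix with `nodes` as dimnames.
#' @export
proximityMatrix <- function(wg, nodes, params = proximityParams()) {
  .checkNodes(wg, nodes)
  n <- length(nodes)
  if (params$measure == "random_walk" && params$rwMethod == "exact") {
    st <- .rwStationary(wg, nodes, params$beta)
    M <- (st[, nodes, drop = FALSE] + t(st[, nodes, drop = FALSE])) / 2
    dimnames(M) <- list(nodes, nodes)
    return(M)
  }
  if (params$measure == "best_path") {
    .checkCapped(wg)
    pos <- wg@weight > 0
    ig <- .asIgraph(wg@graph@nodes, wg@graph@edges[pos, , drop = FALSE])
    d <- igraph::distances(ig, v = nodes, to = nodes,
                           weights = -log(wg@weight[pos]))
    M <- exp(-d)
    diag(M) <- 1
    dimnames(M) <- list(nodes, nodes)
    return(M)
  }
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(M) <- if (params$measure == "random_walk") {
    vapply(nodes, function(v)
      proximityValue(randomWalkProximity(wg, v, v, params)), 1)
  } else 1
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    v <- proximityValue(proximity(wg, nodes[i], nodes[j], params))
    M[i, j] <- M[j, i] <- v
  }
  M
}
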