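# Three-factor edge weighting: relevance x informativeness x reliability,
# with an optional cap at 1 for probabilistic proximity measures.

#' Per-edge-type relevance coefficients
#'
#' Each edge type has a fixed relevance coefficient `q >= 0` expressing the
#' prior importance of that relationship type; unlisted types resolve to
#' `default`. An edge type and its inverse always resolve to the same
#' value (whichever name is listed wins; listing both with different
#' values is an error at resolution time).
#'
#' @param values named numeric vector of relevances by edge-type label.
#' @param default relevance used for unlisted types (default 1).
#' @return an object of class `RelevanceMap` (a list).
#' @examples
#' relevanceMap(c(codes_for = 10, refers_to = 4), default = 1)
#' @export
relevanceMap <- function(values = numeric(), default = 1) {
  values <- unlist(values)
  if (length(values) && (is.null(names(values)) || any(!nzchar(names(values)))))
    stop("relevance values must be named by edge type")
  if (any(values < 0) || default < 0)
    stop("relevances must be non-negative")
  structure(list(values = values, default = as.numeric(default)),
            class = "RelevanceMap")
}

# resolve relevance per edge type, honouring inverse names
.resolveRelevance <- function(map, types, registry) {
  inv <- .inverseTypes(registry, types)
  v <- map$values
  out <- rep(map$default, length(types))
  hitF <- types %in% names(v)
  hitR <- inv %in% names(v)
  if (any(hitF & hitR & types != inv)) {
    both <- which(hitF & hitR & types != inv)
    bad <- both[v[types[both]] != v[inv[both]]]
    if (length(bad))
      stop("edge type '", types[bad[1L]],
           "' and its inverse are listed with different relevances")
  }
  out[hitR] <- v[inv[hitR]]
  out[hitF] <- v[types[hitF]]
  out
}

#' Edge-weighting configuration
#'
#' @param alpha degree-penalty exponent in \[0,1\]; default 0.25. With
#'   `alpha = 0` the informativeness term is identically 1.
#' @param degreeMode `"linktype_independent"` (penalty uses total node
#'   degrees) or `"linktype_specific"` (degree with respect to edges of the
#'   same type, as seen from each endpoint).
#' @param cap logical: cap weights at 1 so they are probabilities. Required
#'   by the probabilistic measures (best path, reliability, expected
#'   reliable distance); the random walk uses uncapped weights.
#' @param relevance a [relevanceMap()].
#' @return an object of class `WeightingConfig` (a list).
#' @export
weightingConfig <- function(alpha = 0.25,
                            degreeMode = c("linktype_independent",
                                           "linktype_specific"),
                            cap = TRUE,
                            relevance = relevanceMap()) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  degreeMode <- match.arg(degreeMode)
  if (!inherits(relevance, "RelevanceMap"))
    stop("relevance must be a RelevanceMap")
  structure(list(alpha = alpha, degreeMode = degreeMode, cap = isTRUE(cap),
                 relevance = relevance),
            class = "WeightingConfig")
}

#' Read / write a weighting configuration as JSON
#'
#' Format:
#' `{"alpha": 0.25, "degree_mode": "linktype_independent", "cap": true,
#'   "default_relevance": 1.0, "relevance": {"codes_for": 10.0}}`.
#'
#' @param path JSON file path.
#' @return for `readWeightingConfig`, a `WeightingConfig`.
#' @export
readWeightingConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rel <- relevanceMap(
    if (length(x$relevance)) unlist(x$relevance) else numeric(),
    default = if (is.null(x$default_relevance)) 1 else x$default_relevance)
  weightingConfig(
    alpha = if (is.null(x$alpha)) 0.25 else x$alpha,
    degreeMode = if (is.null(x$degree_mode)) "linktype_independent"
                 else x$degree_mode,
    cap = if (is.null(x$cap)) TRUE else isTRUE(x$cap),
    relevance = rel)
}

#' @param config a `WeightingConfig`.
#' @rdname readWeightingConfig
#' @export
writeWeightingConfig <- function(config, path) {
  stopifnot(inherits(config, "WeightingConfig"))
  jsonlite::write_json(
    list(alpha = config$alpha, degree_mode = config$degreeMode,
         cap = config$cap,
         default_relevance = config$relevance$default,
         relevance = as.list(config$relevance$values)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# per-edge informativeness for all edges at once
.informativenessAll <- function(g, alpha, degreeMode) {
  ed <- g@edges
  if (!nrow(ed)) return(numeric())
  if (alpha == 0) return(rep(1, nrow(ed)))
  if (degreeMode == "linktype_independent") {
    cnt <- table(c(ed$from, ed$to))
    dU <- as.numeric(cnt[ed$from])
    dV <- as.numeric(cnt[ed$to])
  } else {
    inv <- .inverseTypes(g@edgeTypes, ed$type)
    keys <- c(paste(ed$from, ed$type, sep = "\r"),
              paste(ed$to, inv, sep = "\r"))
    cnt <- table(keys)
    dU <- as.numeric(cnt[keys[seq_len(nrow(ed))]])
    dV <- as.numeric(cnt[keys[nrow(ed) + seq_len(nrow(ed))]])
  }
  dU^(-alpha) * dV^(-alpha)
}

#' Degree-based edge informativeness
#'
#' The informativeness of an edge `(u, v)` penalizes hub nodes:
#' \deqn{i(u,v) = \deg(u)^{-\alpha} \cdot \deg(v)^{-\alpha}}
#' where degrees are total degrees (`linktype_independent`) or degrees
#' restricted to edges of the same type as seen from each endpoint
#' (`linktype_specific`). Degrees come from the unweighted topology.
#'
#' @param x a HeteroGraph or WeightedGraph.
#' @param alpha exponent in \[0,1\], default 0.25.
#' @param degreeMode see [weightingConfig()].
#' @return numeric vector in (0, 1\], one value per edge row of the graph.
#' @export
informativeness <- function(x, alpha = 0.25,
                            degreeMode = c("linktype_independent",
                                           "linktype_specific")) {
  degreeMode <- match.arg(degreeMode)
  if (is(x, "WeightedGraph")) x <- x@graph
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  .informativenessAll(x, alpha, degreeMode)
}

#' Combine relevance, informativeness and reliability into an edge weight
#'
#' Returns the plain product `q * i * r`, or `min(q * i * r, 1)` when
#' `cap = TRUE` (so the weight is interpretable as the probability that the
#' edge represents an existing, relevant and informative relationship).
#' All arguments recycle to a common length.
#'
#' @param relevance relevance coefficient(s), `>= 0`.
#' @param informativeness informativeness value(s) in (0, 1\].
#' @param reliability reliability value(s) in \[0, 1\].
#' @param cap logical.
#' @return numeric vector of weights.
#' @export
edgeWeight <- function(relevance, informativeness, reliability, cap = TRUE) {
  if (any(relevance < 0)) stop("relevance must be non-negative")
  w <- relevance * informativeness * reliability
  if (cap) w <- pmin(w, 1) else w
}

#' Apply an edge-weighting configuration to a graph
#'
#' Computes `p(e) = q(e) * i(e) * r(e)` for every edge (capped at 1 when
#' `config$cap`), producing a [WeightedGraph-class]. The result is
#' deterministic given the graph and configuration.
#'
#' @param graph a HeteroGraph.
#' @param config a [weightingConfig()].
#' @return a [WeightedGraph-class].
#' @examples
#' reg <- edgeTypeRegistry("interacts_with")
#' g <- heteroGraph(data.frame(id = c("a", "b"), type = "Protein"),
#'                  data.frame(from = "a", to = "b",
#'                             type = "interacts_with", reliability = 0.7))
#' edgeWeights(applyWeights(g, weightingConfig(alpha = 0.25)))
#' @export
applyWeights <- function(graph, config = weightingConfig()) {
  stopifnot(is(graph, "HeteroGraph"), inherits(config, "WeightingConfig"))
  ed <- graph@edges
  q <- .resolveRelevance(config$relevance, ed$type, graph@edgeTypes)
  i <- .informativenessAll(graph, config$alpha, config$degreeMode)
  w <- edgeWeight(q, i, ed$reliability, cap = config$cap)
  new("WeightedGraph", graph = graph, weight = as.numeric(w),
      config = unclass(config))
}

#' Load a weighted edge-list TSV
#'
#' Reads the 7-column format written by [saveEdgeList()] on a
#' [WeightedGraph-class] (canonical 6 columns plus `weight`).
#'
#' @param path TSV file path.
#' @param edgeTypes optional edge-type registry.
#' @param cap whether the stored weights are capped probabilities.
#' @return a [WeightedGraph-class].
#' @export
loadWeightedEdgeList <- function(path, edgeTypes = NULL, cap = TRUE) {
  lines <- .readLinesNoComments(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf != 7L)) stop("weighted edge list must have 7 columns")
  m <- do.call(rbind, parts)
  if (identical(tolower(m[1L, 1L]), "source_id")) m <- m[-1L, , drop = FALSE]
  nodes <- unique(data.frame(id = c(m[, 1L], m[, 4L]),
                             type = c(m[, 2L], m[, 5L]),
                             stringsAsFactors = FALSE))
  edges <- data.frame(from = m[, 1L], to = m[, 4L], type = m[, 3L],
                      reliability = as.numeric(m[, 6L]),
                      stringsAsFactors = FALSE)
  w <- as.numeric(m[, 7L])
  if (any(is.na(w)) || any(w < 0)) stop("invalid weight column")
  g <- heteroGraph(nodes, edges, edgeTypes)
  # map weights through canonicalization/collapse by unordered pair
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
               sep = "\r")
  wByKey <- tapply(w, key, max)
  gkey <- paste(pmin(g@edges$from, g@edges$to),
                pmax(g@edges$from, g@edges$to), sep = "\r")
  new("WeightedGraph", graph = g, weight = as.numeric(wByKey[gkey]),
      config = list(cap = cap))
}
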