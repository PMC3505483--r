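# Typed heterogeneous graph model: registry, construction, TSV i/o, degrees,
# neighborhood bounding and graph filtering.

#' Build an edge-type registry
#'
#' Every edge type has exactly one inverse type; a symmetric type (e.g.
#' `interacts_with`) may be its own inverse. Both directions of a relation
#' resolve through the registry: the inverse of the inverse is the type
#' itself.
#'
#' @param types character vector of edge-type names.
#' @param inverses character vector of the same length with the inverse
#'   name of each type; defaults to `types` (all types symmetric).
#' @return data.frame with columns `type`, `inverse`.
#' @examples
#' edgeTypeRegistry(c("codes_for", "interacts_with"),
#'                  c("coded_by", "interacts_with"))
#' @export
edgeTypeRegistry <- function(types, inverses = types) {
  stopifnot(is.character(types), length(types) == length(inverses))
  if (any(!nzchar(types)) || any(!nzchar(inverses)))
    stop("edge-type names must be non-empty")
  reg <- data.frame(type = as.character(types),
                    inverse = as.character(inverses),
                    stringsAsFactors = FALSE)
  .typeMap(reg)  # errors on inconsistency
  reg
}

#' Read an edge-type registry from a TSV file
#'
#' Expected format: two tab-separated columns `type` and `inverse_type`,
#' optional header, `#` comment lines allowed.
#'
#' @param path file path.
#' @return data.frame with columns `type`, `inverse`.
#' @export
readEdgeTypeRegistry <- function(path) {
  lines <- .readLinesNoComments(path)
  if (!length(lines)) stop("empty edge-type registry: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("malformed registry row (expected 2 fields) at data line ", bad[1L])
  m <- do.call(rbind, parts)
  if (identical(tolower(m[1L, 1L]), "type")) m <- m[-1L, , drop = FALSE]
  edgeTypeRegistry(m[, 1L], m[, 2L])
}

# named map: type -> inverse, for both directions; errors on conflicts
.typeMap <- function(reg) {
  map <- character()
  add <- function(a, b) {
    if (!is.na(map[a]) && map[a] != b)
      stop("edge type '", a, "' has conflicting inverses '", map[a],
           "' and '", b, "'")
    map[a] <<- b
  }
  map[reg$type] <- NA_character_
  map[reg$inverse] <- NA_character_
  for (i in seq_len(nrow(reg))) {
    add(reg$type[i], reg$inverse[i])
    add(reg$inverse[i], reg$type[i])
  }
  map
}

.inverseTypes <- function(reg, types) {
  unname(.typeMap(reg)[types])
}

#' Construct a HeteroGraph
#'
#' Edges are brought into canonical direction (lexicographically smaller
#' `(source_type, edge_type)` tuple, with node ids breaking exact ties) and
#' parallel edges between the same unordered node pair are collapsed,
#' keeping the maximum reliability; this preserves the strongest evidence
#' for the relation. Self loops are rejected.
#'
#' @param nodes data.frame with columns `id`, `type`.
#' @param edges data.frame with columns `from`, `to`, `type` and optionally
#'   `reliability` (default 1).
#' @param edgeTypes an edge-type registry from [edgeTypeRegistry()].
#' @return a validated [HeteroGraph-class].
#' @export
heteroGraph <- function(nodes, edges = NULL, edgeTypes = NULL) {
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), reliability = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$reliability)) edges$reliability <- 1
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        type = as.character(edges$type),
                        reliability = as.numeric(edges$reliability),
                        stringsAsFactors = FALSE)
  }
  if (is.null(edgeTypes))
    edgeTypes <- edgeTypeRegistry(unique(edges$type))
  if (nrow(edges)) {
    if (any(is.na(edges$reliability) | edges$reliability < 0 |
            edges$reliability > 1))
      stop("reliability outside [0, 1]")
    tm <- .typeMap(edgeTypes)
    unknown <- setdiff(edges$type, names(tm))
    if (length(unknown))
      stop("unregistered edge type(s): ", paste(unknown, collapse = ", "))
    if (any(edges$from == edges$to)) stop("self loops are not allowed")
    ntype <- stats::setNames(nodes$type, nodes$id)
    if (any(is.na(ntype[edges$from])) || any(is.na(ntype[edges$to])))
      stop("edge endpoint not in node table")
    edges <- .canonicalizeEdges(edges, ntype, tm)
    edges <- .collapseEdges(edges)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("HeteroGraph", nodes = nodes, edges = edges, edgeTypes = edgeTypes)
}

# canonical direction: lexicographically smaller (source_type, edge_type)
# tuple; exact ties (symmetric type between same node types) broken by id
.canonicalizeEdges <- function(edges, ntype, tm) {
  inv <- unname(tm[edges$type])
  keyF <- paste(ntype[edges$from], edges$type, sep = "\r")
  keyR <- paste(ntype[edges$to], inv, sep = "\r")
  flip <- keyR < keyF | (keyR == keyF & edges$to < edges$from)
  if (any(flip)) {
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    edges$type[flip] <- inv[flip]
  }
  edges
}

.collapseEdges <- function(edges) {
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
               sep = "\r")
  ord <- order(key, -edges$reliability)
  edges <- edges[ord, , drop = FALSE]
  edges[!duplicated(key[ord]), , drop = FALSE]
}

.readLinesNoComments <- function(path, keepIndex = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  out <- lines[keep]
  if (keepIndex) attr(out, "lineNumbers") <- which(keep)
  out
}

#' Load a heterogeneous graph from an edge-list TSV
#'
#' Canonical format, one edge per row:
#' `source_id<TAB>source_type<TAB>edge_type<TAB>target_id<TAB>target_type<TAB>reliability`
#' with the reliability column optional (default 1.0). `#`-prefixed lines
#' are comments; an optional header row is detected by a non-numeric
#' reliability field. Duplicate unordered pairs are collapsed keeping the
#' maximum reliability, and rows written with an inverse edge-type name are
#' stored in canonical direction.
#'
#' @param path TSV file path.
#' @param edgeTypes edge-type registry ([edgeTypeRegistry()] /
#'   [readEdgeTypeRegistry()]). When `NULL`, every edge type in the file is
#'   registered as its own inverse (symmetric).
#' @return a validated [HeteroGraph-class].
#' @seealso [saveEdgeList()]
#' @export
loadEdgeList <- function(path, edgeTypes = NULL) {
  lines <- .readLinesNoComments(path, keepIndex = TRUE)
  lineNo <- attr(lines, "lineNumbers")
  if (!length(lines))
    return(heteroGraph(data.frame(id = character(), type = character()),
                       NULL, edgeTypes))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  # header: first row with 5-6 fields whose 6th field is not a number
  start <- 1L
  if (nf[1L] >= 5L) {
    relField <- if (nf[1L] >= 6L) parts[[1L]][6L] else NA_character_
    if ((!is.na(relField) && is.na(suppressWarnings(as.numeric(relField)))) ||
        identical(tolower(parts[[1L]][1L]), "source_id"))
      start <- 2L
  }
  if (start > length(parts))
    return(heteroGraph(data.frame(id = character(), type = character()),
                       NULL, edgeTypes))
  parts <- parts[start:length(parts)]
  lineNo <- lineNo[start:length(nf)]
  nf <- nf[start:length(nf)]
  bad <- which(nf < 5L | nf > 6L)
  if (length(bad))
    stop("malformed row at line ", lineNo[bad[1L]],
         ": expected 5 or 6 tab-separated fields, got ", nf[bad[1L]])
  m <- matrix("", nrow = length(parts), ncol = 6L)
  for (i in seq_along(parts))
    m[i, seq_len(nf[i])] <- parts[[i]]
  rel <- ifelse(nf == 6L, m[, 6L], "1")
  relNum <- suppressWarnings(as.numeric(rel))
  bad <- which(is.na(relNum))
  if (length(bad))
    stop("malformed reliability at line ", lineNo[bad[1L]], ": '",
         rel[bad[1L]], "'")
  bad <- which(relNum < 0 | relNum > 1)
  if (length(bad))
    stop("reliability outside [0, 1] at line ", lineNo[bad[1L]], ": ",
         relNum[bad[1L]])
  nodes <- unique(data.frame(id = c(m[, 1L], m[, 4L]),
                             type = c(m[, 2L], m[, 5L]),
                             stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$id)) {
    dup <- nodes$id[duplicated(nodes$id)][1L]
    stop("node '", dup, "' listed with conflicting node types")
  }
  edges <- data.frame(from = m[, 1L], to = m[, 4L], type = m[, 3L],
                      reliability = relNum, stringsAsFactors = FALSE)
  if (!is.null(edgeTypes)) {
    unknown <- setdiff(edges$type, names(.typeMap(edgeTypes)))
    if (length(unknown))
      stop("unregistered edge type(s): ", paste(unknown, collapse = ", "))
  }
  heteroGraph(nodes, edges, edgeTypes)
}

#' Write a graph as an edge-list TSV
#'
#' Writes the canonical 6-column format accepted by [loadEdgeList()]; a
#' [WeightedGraph-class] gains a seventh `weight` column.
#'
#' @param x a HeteroGraph or WeightedGraph.
#' @param path output file path.
#' @param header write a header row (default TRUE).
#' @return `path`, invisibly.
#' @rdname saveEdgeList
#' @export
setMethod("saveEdgeList", "HeteroGraph", function(x, path, header = TRUE) {
  df <- .edgeListFrame(x)
  .writeTsv(df, path, header)
})

#' @rdname saveEdgeList
#' @export
setMethod("saveEdgeList", "WeightedGraph", function(x, path, header = TRUE) {
  df <- .edgeListFrame(x@graph)
  df$weight <- x@weight
  .writeTsv(df, path, header)
})

.edgeListFrame <- function(g) {
  ntype <- stats::setNames(g@nodes$type, g@nodes$id)
  data.frame(source_id = g@edges$from,
             source_type = unname(ntype[g@edges$from]),
             edge_type = g@edges$type,
             target_id = g@edges$to,
             target_type = unname(ntype[g@edges$to]),
             reliability = g@edges$reliability,
             stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path, header = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname HeteroGraph-class
#' @export
setMethod("graphNodes", "HeteroGraph", function(x) x@nodes)
#' @rdname HeteroGraph-class
#' @export
setMethod("graphEdges", "HeteroGraph", function(x) x@edges)
#' @rdname HeteroGraph-class
#' @export
setMethod("edgeTypes", "HeteroGraph", function(x) x@edgeTypes)
#' @rdname HeteroGraph-class
#' @export
setMethod("nodeCount", "HeteroGraph", function(x) nrow(x@nodes))
#' @rdname HeteroGraph-class
#' @export
setMethod("edgeCount", "HeteroGraph", function(x) nrow(x@edges))

#' @rdname WeightedGraph-class
#' @export
setMethod("graphNodes", "WeightedGraph", function(x) x@graph@nodes)
#' @rdname WeightedGraph-class
#' @export
setMethod("graphEdges", "WeightedGraph", function(x) x@graph@edges)
#' @rdname WeightedGraph-class
#' @export
setMethod("edgeTypes", "WeightedGraph", function(x) x@graph@edgeTypes)
#' @rdname WeightedGraph-class
#' @export
setMethod("nodeCount", "WeightedGraph", function(x) nrow(x@graph@nodes))
#' @rdname WeightedGraph-class
#' @export
setMethod("edgeCount", "WeightedGraph", function(x) nrow(x@graph@edges))
#' @rdname WeightedGraph-class
#' @export
setMethod("edgeWeights", "WeightedGraph", function(x) x@weight)

setMethod("show", "HeteroGraph", function(object) {
  cat("HeteroGraph with", nrow(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  if (nrow(object@nodes)) {
    tab <- sort(table(object@nodes$type), decreasing = TRUE)
    cat("  node types:",
        paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
        "\n")
  }
  if (nrow(object@edges)) {
    tab <- sort(table(object@edges$type), decreasing = TRUE)
    cat("  edge types:",
        paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "),
        "\n")
  }
})

setMethod("show", "WeightedGraph", function(object) {
  cat("WeightedGraph (cap =", isTRUE(object@config$cap), ")\n")
  show(object@graph)
  if (length(object@weight))
    cat("  weights: [", signif(min(object@weight), 4), ",",
        signif(max(object@weight), 4), "]\n")
})

# type of each edge as seen from a given endpoint vector
.typeSeenFrom <- function(g, node, edges = g@edges) {
  inv <- .inverseTypes(g@edgeTypes, edges$type)
  ifelse(edges$from == node, edges$type, inv)
}

#' Degree of a node
#'
#' Counts incident undirected relations once each (an edge and its inverse
#' view are the same relation). With `edgeType` given, counts only incident
#' edges whose type *as seen from this node* equals the label: an edge
#' stored as `(gene, codes_for, protein)` counts toward `codes_for` at the
#' gene and toward its inverse at the protein.
#'
#' @param x a HeteroGraph or WeightedGraph.
#' @param node node id.
#' @param edgeType optional edge-type label to filter by.
#' @return non-negative integer.
#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "HeteroGraph", function(x, node, edgeType = NULL) {
  if (!node %in% x@nodes$id) stop("unknown node: ", node)
  ed <- x@edges
  inc <- ed$from == node | ed$to == node
  if (is.null(edgeType)) return(sum(inc))
  ed <- ed[inc, , drop = FALSE]
  sum(.typeSeenFrom(x, node, ed) == edgeType)
})

#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "WeightedGraph", function(x, node, edgeType = NULL) {
  nodeDegree(x@graph, node, edgeType)
})

# induced subgraph on a set of node ids (preserves weights when present)
.inducedHetero <- function(g, ids) {
  keep <- g@edges$from %in% ids & g@edges$to %in% ids
  new("HeteroGraph",
      nodes = g@nodes[g@nodes$id %in% ids, , drop = FALSE],
      edges = g@edges[keep, , drop = FALSE],
      edgeTypes = g@edgeTypes)
}

.inducedWeighted <- function(wg, ids) {
  keep <- wg@graph@edges$from %in% ids & wg@graph@edges$to %in% ids
  g <- new("HeteroGraph",
           nodes = wg@graph@nodes[wg@graph@nodes$id %in% ids, , drop = FALSE],
           edges = wg@graph@edges[keep, , drop = FALSE],
           edgeTypes = wg@graph@edgeTypes)
  new("WeightedGraph", graph = g, weight = wg@weight[keep],
      config = wg@config)
}

# igraph view; prob = per-edge probability used for best-path distances
.asIgraph <- function(nodes, edges) {
  igraph::graph_from_data_frame(
    d = edges[, c("from", "to"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes$id, stringsAsFactors = FALSE))
}

# min hop distance and max best-path probability from a terminal set
.terminalProximity <- function(nodes, edges, prob, terminals) {
  ig <- .asIgraph(nodes, edges)
  hop <- igraph::distances(ig, v = terminals, weights = NA)
  minHop <- if (nrow(hop)) apply(hop, 2L, min) else
    stats::setNames(numeric(0), character(0))
  pos <- prob > 0
  igp <- .asIgraph(nodes, edges[pos, , drop = FALSE])
  wd <- igraph::distances(igp, v = terminals, weights = -log(prob[pos]))
  bp <- exp(-apply(wd, 2L, min))
  list(minHop = minHop[nodes$id], bestProb = bp[nodes$id])
}

#' Bounded neighborhood subgraph around terminal nodes
#'
#' Returns the induced subgraph on the nodes reachable from any terminal
#' within `maxDepth` hops, truncated to the `maxNodes` nodes with the
#' highest best-path probability to the nearest terminal (edge
#' probabilities are the weights of a [WeightedGraph-class] or the
#' reliabilities of a [HeteroGraph-class]; ties broken by node id).
#' Terminals are always retained. This is the bounding step used by the
#' Monte-Carlo proximity measures.
#'
#' @param x a HeteroGraph or WeightedGraph.
#' @param terminals character vector of node ids.
#' @param maxNodes maximum number of nodes retained (>= number of
#'   terminals).
#' @param maxDepth maximum hop distance from the nearest terminal.
#' @return an object of the same class as `x`.
#' @rdname neighborhoodSubgraph
#' @export
setMethod("neighborhoodSubgraph", "HeteroGraph",
  function(x, terminals, maxNodes = 1000L, maxDepth = 4L) {
    ids <- .boundedNodeSet(x@nodes, x@edges, x@edges$reliability,
                           terminals, maxNodes, maxDepth)
    .inducedHetero(x, ids)
  })

#' @rdname neighborhoodSubgraph
#' @export
setMethod("neighborhoodSubgraph", "WeightedGraph",
  function(x, terminals, maxNodes = 1000L, maxDepth = 4L) {
    ids <- .boundedNodeSet(x@graph@nodes, x@graph@edges, x@weight,
                           terminals, maxNodes, maxDepth)
    .inducedWeighted(x, ids)
  })

.boundedNodeSet <- function(nodes, edges, prob, terminals, maxNodes,
                            maxDepth) {
  missing <- setdiff(terminals, nodes$id)
  if (length(missing)) stop("unknown terminal(s): ",
                            paste(missing, collapse = ", "))
  if (maxNodes < length(terminals))
    stop("maxNodes must be at least the number of terminals")
  if (!nrow(edges)) return(terminals)
  tp <- .terminalProximity(nodes, edges, prob, terminals)
  reach <- nodes$id[tp$minHop <= maxDepth]
  reach <- union(terminals, reach)
  isTerm <- reach %in% terminals
  bp <- tp$bestProb[reach]
  bp[is.na(bp)] <- 0
  ord <- order(!isTerm, -bp, reach)
  reach[ord][seq_len(min(maxNodes, length(reach)))]
}

#' Filter a graph by node types, edge types or an edge predicate
#'
#' Removes all nodes of the given types (with their incident edges), all
#' edges whose type or inverse type matches `dropEdgeTypes`, and all edges
#' for which the predicate returns TRUE. Used for reduced-data ablation
#' experiments (e.g. removing all phenotype nodes or all edges derived
#' from a particular source database). The registries are unchanged.
#'
#' @param x a HeteroGraph.
#' @param dropNodeTypes character vector of node-type labels to remove.
#' @param dropEdgeTypes character vector of edge-type labels to remove
#'   (either direction's name matches).
#' @param dropEdges optional predicate `function(edges)` returning a
#'   logical vector over the edge data.frame; matching edges are removed.
#' @return a HeteroGraph (possibly empty).
#' @rdname filterGraph
#' @export
setMethod("filterGraph", "HeteroGraph",
  function(x, dropNodeTypes = character(), dropEdgeTypes = character(),
           dropEdges = NULL) {
    nodes <- x@nodes
    edges <- x@edges
    if (length(dropNodeTypes)) {
      dropIds <- nodes$id[nodes$type %in% dropNodeTypes]
      nodes <- nodes[!nodes$type %in% dropNodeTypes, , drop = FALSE]
      edges <- edges[!(edges$from %in% dropIds | edges$to %in% dropIds),
                     , drop = FALSE]
    }
    if (length(dropEdgeTypes)) {
      inv <- .inverseTypes(x@edgeTypes, edges$type)
      edges <- edges[!(edges$type %in% dropEdgeTypes |
                       inv %in% dropEdgeTypes), , drop = FALSE]
    }
    if (!is.null(dropEdges) && nrow(edges)) {
      drop <- dropEdges(edges)
      stopifnot(is.logical(drop), length(drop) == nrow(edges))
      edges <- edges[!drop, , drop = FALSE]
    }
    new("HeteroGraph", nodes = nodes, edges = edges,
        edgeTypes = x@edgeTypes)
  })
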