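# Synthetic heterogeneous graphs with planted structure: heavy-tailed typed
# background edges, gene families wired through shared pathway nodes, and
# held-out "future" gene-gene association links. Every other module is
# testable against these graphs without any external database.

#' Default edge-type registry of the synthetic generator
#' @export
syntheticRegistry <- function() {
  edgeTypeRegistry(
    c("codes_for", "interacts_with", "associated_with", "refers_to",
      "participates_in", "member_of"),
    c("coded_by", "interacts_with", "associated_with", "referred_by",
      "has_participant", "has_member"))
}

#' Configuration for the synthetic-graph generator
#'
#' Defaults describe a graph of about 2,000 nodes over 4 node types and 6
#' edge types with 20 planted families of 8 genes, sized so the full test
#' suite runs in minutes. Background edges attach endpoints with
#' probability proportional to `(degree + 1)^skew`, giving heavy-tailed
#' degrees (hub articles and pathways). Curated edge types carry
#' reliability 1; predicted associations draw reliabilities from
#' Beta(4, 2), echoing databases where only predicted links carry
#' sub-unit confidences.
#'
#' @param nodeCounts named counts per node type.
#' @param edgeSpecs data.frame with columns `type`, `fromType`, `toType`,
#'   `count`, `skew`, `reliability` (`"curated"` or `"beta"`).
#' @param nFamilies,familySize planted gene families.
#' @param familyPathways dedicated pathway nodes per family.
#' @param intraFamilyEdgeProb probability that a family gene joins each of
#'   its family pathways (multi-hop signal through shared intermediates).
#' @param familyPairEdgeProb probability of a direct predicted association
#'   between two genes of the same family (the plantable links).
#' @param crossFamilyEdgeProb probability of a noise gene-pathway edge to
#'   another family's pathway.
#' @param futureLinkFraction fraction of direct same-family association
#'   edges moved out of the visible graph as held-out future links.
#' @param seed generator seed.
#' @return an object of class `GeneratorConfig` (a list).
#' @export
generatorConfig <- function(nodeCounts = c(Gene = 600, Protein = 600,
                                           Pathway = 120, Article = 680),
                            edgeSpecs = NULL,
                            nFamilies = 20L, familySize = 8L,
                            familyPathways = 3L,
                            intraFamilyEdgeProb = 0.8,
                            familyPairEdgeProb = 0.5,
                            crossFamilyEdgeProb = 0.01,
                            futureLinkFraction = 0.5,
                            seed = 1L) {
  if (is.null(edgeSpecs))
    edgeSpecs <- data.frame(
      type = c("codes_for", "interacts_with", "refers_to", "member_of",
               "participates_in", "associated_with"),
      fromType = c("Gene", "Protein", "Article", "Protein", "Gene", "Gene"),
      toType = c("Protein", "Protein", "Gene", "Pathway", "Pathway",
                 "Gene"),
      count = c(600L, 800L, 2000L, 400L, 400L, 600L),
      skew = c(0, 0.5, 1, 0.5, 0.5, 0.5),
      reliability = c("curated", "curated", "curated", "curated",
                      "curated", "beta"),
      stringsAsFactors = FALSE)
  probs <- c(intraFamilyEdgeProb, familyPairEdgeProb, crossFamilyEdgeProb,
             futureLinkFraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(nodeCounts < 0) || any(edgeSpecs$count < 0))
    stop("counts must be non-negative")
  missing <- setdiff(unique(c(edgeSpecs$fromType, edgeSpecs$toType)),
                     names(nodeCounts))
  if (length(missing))
    stop("edge spec references missing node type(s): ",
         paste(missing, collapse = ", "))
  if (nFamilies > 0) {
    if (nFamilies * familySize > nodeCounts[["Gene"]])
      stop("not enough genes for the requested families")
    if (nFamilies * familyPathways > nodeCounts[["Pathway"]])
      stop("not enough pathways for the requested families")
  }
  structure(list(nodeCounts = nodeCounts, edgeSpecs = edgeSpecs,
                 nFamilies = as.integer(nFamilies),
                 familySize = as.integer(familySize),
                 familyPathways = as.integer(familyPathways),
                 intraFamilyEdgeProb = intraFamilyEdgeProb,
                 familyPairEdgeProb = familyPairEdgeProb,
                 crossFamilyEdgeProb = crossFamilyEdgeProb,
                 futureLinkFraction = futureLinkFraction,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

.nodeIds <- function(type, n) {
  if (n == 0) return(character())
  prefix <- c(Gene = "g", Protein = "p", Pathway = "pw", Article = "a")
  pre <- if (type %in% names(prefix)) prefix[[type]] else
    tolower(substr(type, 1L, 2L))
  sprintf("%s%04d", pre, seq_len(n))
}

# sequential preferential attachment: endpoint probability ~ (deg + 1)^skew
.attachEdges <- function(fromPool, toPool, count, skew, degEnv) {
  if (count == 0)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  deg <- degEnv$deg
  from <- character(count); to <- character(count)
  for (i in seq_len(count)) {
    pf <- (deg[fromPool] + 1)^skew
    pt <- (deg[toPool] + 1)^skew
    f <- sample(fromPool, 1L, prob = pf)
    t <- sample(toPool, 1L, prob = pt)
    while (t == f) t <- sample(toPool, 1L, prob = pt)
    from[i] <- f; to[i] <- t
    deg[f] <- deg[f] + 1; deg[t] <- deg[t] + 1
  }
  degEnv$deg <- deg
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

.drawReliability <- function(kind, n) {
  if (kind == "curated") rep(1, n) else stats::rbeta(n, 4, 2)
}

#' Generate a synthetic heterogeneous graph with planted truth
#'
#' Builds typed nodes, attaches background edges per spec with
#' degree-skewed endpoint selection, wires each planted family to its
#' dedicated pathway nodes (so family members are proximal through shared
#' intermediates, not necessarily through direct edges), adds direct
#' predicted associations between same-family gene pairs, and finally
#' moves a fraction of those direct edges out of the visible graph as
#' held-out future links. Deterministic given the seed.
#'
#' @param config a [generatorConfig()].
#' @param seed overrides `config$seed` when given.
#' @return list with elements `graph` (the visible [HeteroGraph-class]),
#'   and `truth`: a list with `futureLinks` (data.frame `node1`, `node2`),
#'   `families` (list of gene-id vectors), `hiddenEdges` (edge rows removed
#'   from the visible graph).
#' @export
generateGraph <- function(config = generatorConfig(), seed = config$seed) {
  stopifnot(inherits(config, "GeneratorConfig"))
  .withSeed(seed, {
    nc <- config$nodeCounts
    nodes <- do.call(rbind, lapply(names(nc), function(ty)
      data.frame(id = .nodeIds(ty, nc[[ty]]), type = ty,
                 stringsAsFactors = FALSE)))
    byType <- split(nodes$id, nodes$type)
    degEnv <- new.env()
    degEnv$deg <- stats::setNames(numeric(nrow(nodes)), nodes$id)

    edges <- list()
    for (i in seq_len(nrow(config$edgeSpecs))) {
      sp <- config$edgeSpecs[i, ]
      ft <- byType[[sp$fromType]]; tt <- byType[[sp$toType]]
      if (!length(ft) || !length(tt) || sp$count == 0) next
      e <- .attachEdges(ft, tt, sp$count, sp$skew, degEnv)
      e$type <- sp$type
      e$reliability <- .drawReliability(sp$reliability, nrow(e))
      edges[[length(edges) + 1L]] <- e
    }

    families <- list()
    if (config$nFamilies > 0) {
      genes <- byType$Gene
      paths <- byType$Pathway
      famGenes <- sample(genes, config$nFamilies * config$familySize)
      famPaths <- sample(paths, config$nFamilies * config$familyPathways)
      for (f in seq_len(config$nFamilies)) {
        members <- famGenes[(f - 1L) * config$familySize +
                              seq_len(config$familySize)]
        fpaths <- famPaths[(f - 1L) * config$familyPathways +
                             seq_len(config$familyPathways)]
        families[[f]] <- members
        # family signal: shared pathway memberships
        grid <- expand.grid(from = members, to = fpaths,
                            stringsAsFactors = FALSE)
        keep <- stats::runif(nrow(grid)) < config$intraFamilyEdgeProb
        if (any(keep))
          edges[[length(edges) + 1L]] <- data.frame(
            from = grid$from[keep], to = grid$to[keep],
            type = "participates_in",
            reliability = 1, stringsAsFactors = FALSE)
        # direct predicted associations between family members
        pairIdx <- utils::combn(members, 2L)
        keep <- stats::runif(ncol(pairIdx)) < config$familyPairEdgeProb
        if (any(keep))
          edges[[length(edges) + 1L]] <- data.frame(
            from = pairIdx[1L, keep], to = pairIdx[2L, keep],
            type = "associated_with",
            reliability = stats::rbeta(sum(keep), 4, 2),
            stringsAsFactors = FALSE)
        # cross-family gene-pathway noise
        others <- setdiff(famGenes, members)
        ngrid <- expand.grid(from = others, to = fpaths,
                             stringsAsFactors = FALSE)
        keep <- stats::runif(nrow(ngrid)) < config$crossFamilyEdgeProb
        if (any(keep))
          edges[[length(edges) + 1L]] <- data.frame(
            from = ngrid$from[keep], to = ngrid$to[keep],
            type = "participates_in",
            reliability = 1, stringsAsFactors = FALSE)
      }
    }

    full <- heteroGraph(nodes, do.call(rbind, edges), syntheticRegistry())

    # hold out a fraction of the direct same-family associations
    hidden <- data.frame(from = character(), to = character(),
                         type = character(), reliability = numeric(),
                         stringsAsFactors = FALSE)
    if (config$nFamilies > 0 && config$futureLinkFraction > 0) {
      fam <- stats::setNames(rep(seq_along(families),
                                 each = config$familySize),
                             unlist(families))
      ed <- full@edges
      sameFam <- ed$type == "associated_with" &
        ed$from %in% names(fam) & ed$to %in% names(fam)
      sameFam[sameFam] <- fam[ed$from[sameFam]] == fam[ed$to[sameFam]]
      cand <- which(sameFam)
      nHide <- round(length(cand) * config$futureLinkFraction)
      if (nHide > 0) {
        hide <- sort(cand[sample.int(length(cand), nHide)])
        hidden <- ed[hide, , drop = FALSE]
        visibleEdges <- ed[-hide, , drop = FALSE]
      } else {
        visibleEdges <- ed
      }
    } else {
      visibleEdges <- full@edges
    }
    graph <- new("HeteroGraph", nodes = full@nodes,
                 edges = visibleEdges, edgeTypes = full@edgeTypes)
    rownames(hidden) <- NULL
    list(graph = graph,
         truth = list(
           futureLinks = data.frame(node1 = hidden$from,
                                    node2 = hidden$to,
                                    stringsAsFactors = FALSE),
           families = families,
           hiddenEdges = hidden))
  })
}

.pairKeys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Build a labeled link-prediction pair set from planted truth
#'
#' Positives are sampled from the held-out future links; negatives are
#' sampled from pairings of the positive-support nodes, excluding any pair
#' linked in the visible or hidden graph.
#'
#' @param truth the `truth` element of [generateGraph()].
#' @param graph the visible graph.
#' @param nPos,nNeg numbers of positive and negative pairs.
#' @param seed optional seed.
#' @return a [labeledPairSet()].
#' @export
makeLinkCases <- function(truth, graph, nPos, nNeg, seed = NULL) {
  fl <- truth$futureLinks
  if (nrow(fl) < nPos)
    stop("only ", nrow(fl), " future links available, ", nPos,
         " positives requested")
  linkedKeys <- c(.pairKeys(graph@edges$from, graph@edges$to),
                  .pairKeys(truth$hiddenEdges$from, truth$hiddenEdges$to))
  .withSeed(seed, {
    pos <- fl[sample.int(nrow(fl), nPos), , drop = FALSE]
    neg <- sampleNegativePairs(
      pos, nNeg,
      excluded = function(a, b) .pairKeys(a, b) %in% linkedKeys)
    labeledPairSet(c(pos$node1, neg$node1), c(pos$node2, neg$node2),
                   c(rep(1L, nPos), rep(0L, nNeg)),
                   provenance = "synthetic planted future links")
  })
}

#' Build prioritization cases from planted families
#'
#' Each case draws its positives from a single planted family and its
#' negatives from the union of the other families (never from non-family
#' genes, which avoids the bias that well-studied disease genes carry more
#' edges). Families are reused round-robin when `nCases` exceeds the
#' family count.
#'
#' @param truth the `truth` element of [generateGraph()].
#' @param nCases number of cases.
#' @param nPositive,nNegative sizes of `S_P` and `S_N`.
#' @param seed optional seed.
#' @return list of [prioritizationCase()]s.
#' @export
makePrioritizationCases <- function(truth, nCases, nPositive, nNegative,
                                    seed = NULL) {
  fams <- truth$families
  if (length(fams) < 2L) stop("need at least two families")
  if (nPositive > length(fams[[1L]]))
    stop("nPositive exceeds the family size")
  othersPool <- function(f) unlist(fams[-f])
  if (nNegative > length(othersPool(1L)))
    stop("nNegative exceeds the pool of other-family genes")
  .withSeed(seed, {
    lapply(seq_len(nCases), function(i) {
      f <- ((i - 1L) %% length(fams)) + 1L
      sp <- sample(fams[[f]], nPositive)
      sn <- sample(othersPool(f), nNegative)
      prioritizationCase(c(sp, sn), truthPositive = sp)
    })
  })
}
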