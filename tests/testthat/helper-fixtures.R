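# Shared fixtures: tiny graphs with known closed-form proximities, and a
# random small-graph generator for property tests.

symReg <- function() edgeTypeRegistry("link")

bioReg <- function() {
  edgeTypeRegistry(c("codes_for", "interacts_with"),
                   c("coded_by", "interacts_with"))
}

# single edge a--b
pairGraph <- function(r = 1) {
  heteroGraph(data.frame(id = c("a", "b"), type = "N"),
              data.frame(from = "a", to = "b", type = "link",
                         reliability = r),
              symReg())
}

# direct edge s--t (0.5) plus independent 2-edge path s--m--t (0.5, 0.5):
# reliability 1 - 0.5 * 0.75 = 0.625, ERD (0.5*1 + 0.125*2)/0.625 = 1.2
threeEdgeGraph <- function() {
  heteroGraph(data.frame(id = c("s", "t", "m"), type = "N"),
              data.frame(from = c("s", "s", "m"), to = c("t", "m", "t"),
                         type = "link", reliability = c(0.5, 0.5, 0.5)),
              symReg())
}

# WeightedGraph with weights equal to the reliabilities
asWeighted <- function(g, cap = TRUE) {
  applyWeights(g, weightingConfig(alpha = 0, cap = cap,
                                  relevance = relevanceMap(default = 1)))
}

# random connected-ish weighted graph with <= maxEdges edges
randomSmallGraph <- function(nNodes, maxEdges, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(nNodes))
  all <- t(combn(ids, 2L))
  k <- min(maxEdges, nrow(all))
  pick <- sample.int(nrow(all), k)
  g <- heteroGraph(data.frame(id = ids, type = "N"),
                   data.frame(from = all[pick, 1L], to = all[pick, 2L],
                              type = "link",
                              reliability = round(runif(k, 0.05, 0.95), 3)),
                   symReg())
  asWeighted(g)
}

smallGeneratorConfig <- function() {
  generatorConfig(
    nodeCounts = c(Gene = 120, Protein = 120, Pathway = 40, Article = 120),
    edgeSpecs = data.frame(
      type = c("codes_for", "interacts_with", "refers_to", "member_of",
               "participates_in", "associated_with"),
      fromType = c("Gene", "Protein", "Article", "Protein", "Gene", "Gene"),
      toType = c("Protein", "Protein", "Gene", "Pathway", "Pathway", "Gene"),
      count = c(120L, 160L, 400L, 80L, 80L, 120L),
      skew = c(0, 0.5, 1, 0.5, 0.5, 0.5),
      reliability = c("curated", "curated", "curated", "curated",
                      "curated", "beta"),
      stringsAsFactors = FALSE),
    nFamilies = 8L, familySize = 6L)
}
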