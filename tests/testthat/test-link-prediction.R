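test_that("rocAuc matches the worked examples and handles ties as 1/2", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))@auc, 1.0)
  expect_equal(rocAuc(c(0.9, 0.5, 0.7, 0.1), c(1, 1, 0, 0))@auc, 0.75)
  expect_equal(rocAuc(c(0.5, 0.5), c(1, 0))@auc, 0.5)
  expect_error(rocAuc(c(1, 2), c(1, 1)), "at least one")

  # curve contract: anchored, monotone FPR, trapezoid area == auc
  roc <- rocAuc(c(0.9, 0.5, 0.5, 0.1, 0.3), c(1, 1, 0, 0, 1))
  pts <- roc@points
  expect_equal(pts[1, ], c(fpr = 0, tpr = 0))
  expect_equal(pts[nrow(pts), ], c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts[, 1]) >= 0))
})

test_that("rocAuc equals the brute-force concordant-pair statistic", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(5:200, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    # discretized scores induce plenty of ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(rocAuc(scores, labels)@auc, bruteAuc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(5)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  a0 <- rocAuc(scores, labels)@auc
  expect_equal(rocAuc(exp(3 * scores), labels)@auc, a0)
  expect_equal(rocAuc(rank(scores, ties.method = "average"), labels)@auc, a0)
})

test_that("paired AUC comparison agrees with a permutation oracle", {
  # identical scores: zero difference, p = 1
  set.seed(11)
  s <- runif(30); l <- rep(c(1, 0), 15)
  cmp <- compareAuc(s, s, l)
  expect_equal(cmp$aucA, cmp$aucB)
  expect_equal(cmp$pValue, 1)
  expect_equal(cmp$aucA, rocAuc(s, l)@auc)  # consistency with rocAuc

  # perfectly separating vs anti-separating on 20+20 pairs
  l2 <- rep(c(1, 0), each = 20)
  good <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  expect_lt(compareAuc(good, 1 - good, l2)$pValue, 0.001)

  # moderate signal: DeLong p within 0.02 of the paired permutation test
  for (seed in c(3, 17)) {
    set.seed(seed)
    n <- 40
    lab <- rep(c(1, 0), each = n / 2)
    sa <- lab * 0.35 + runif(n)
    sb <- lab * 0.15 + runif(n)
    pDeLong <- compareAuc(sa, sb, lab)$pValue
    pPerm <- permutationAucTest(sa, sb, lab, nPerm = 4000, seed = seed)
    expect_lt(abs(pDeLong - pPerm), 0.02)
  }
})

test_that("negative-pair sampling stays inside the admissible support", {
  pos <- data.frame(node1 = c("a", "c"), node2 = c("b", "d"))
  neg <- sampleNegativePairs(pos, 2, seed = 1)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  admissible <- key(c("a", "a", "b", "b"), c("c", "d", "c", "d"))
  expect_true(all(key(neg$node1, neg$node2) %in% admissible))
  expect_equal(nrow(unique(neg)), 2)

  expect_error(
    sampleNegativePairs(pos, 2, excluded = function(a, b) rep(TRUE, length(a))),
    "insufficient")

  # uniformity across the 4 admissible pairs of a 4-node support
  draws <- table(unlist(lapply(1:1000, function(s) {
    d <- sampleNegativePairs(pos, 1, seed = s)
    key(d$node1, d$node2)
  })))
  expect_true(all(abs(draws / 1000 - 0.25) < 3 * sqrt(0.25 * 0.75 / 1000) + 0.01))

  # determinism
  expect_identical(sampleNegativePairs(pos, 2, seed = 42),
                   sampleNegativePairs(pos, 2, seed = 42))
})

test_that("scorePairs handles adjacency, identity and missing nodes", {
  wg <- asWeighted(heteroGraph(
    data.frame(id = c("a", "b", "c", "d"), type = "N"),
    data.frame(from = "a", to = "b", type = "link", reliability = 0.9),
    symReg()))
  pairs <- data.frame(node1 = c("a", "c", "a", "ghost"),
                      node2 = c("b", "d", "a", "b"))
  expect_warning(sc <- scorePairs(wg, pairs, proximityParams("best_path")),
                 "absent")
  expect_equal(sc$score, c(0.9, 0, 1, 0))
  # reliability route against the oracle
  wg3 <- asWeighted(threeEdgeGraph())
  sc3 <- scorePairs(wg3, data.frame(node1 = "s", node2 = "t"),
                    proximityParams("reliability", nSamples = 20000,
                                    seed = 8))
  expect_lt(abs(sc3$score - 0.625), 4 * sqrt(0.625 * 0.375 / 20000))
})

test_that("labeled pair sets validate and round-trip through TSV", {
  lp <- labeledPairSet(c("a", "c"), c("b", "d"), c(1, 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLabeledPairs(lp, f)
  lp2 <- readLabeledPairs(f)
  expect_equal(as.data.frame(lp2), as.data.frame(lp), ignore_attr = TRUE)
  expect_error(labeledPairSet(c("a", "b"), c("b", "a"), c(1, 0)),
               "duplicate")
  expect_error(labeledPairSet("a", "a", 1), "distinct")
  expect_error(labeledPairSet("a", "b", 2), "binary")
})

test_that("one-at-a-time relevance tuning finds the signal-carrying type", {
  sim <- generateGraph(smallGeneratorConfig(), seed = 61)
  train <- makeLinkCases(sim$truth, sim$graph, 25, 25, seed = 62)

  # grid {1} is the identity: defaults returned unchanged
  id <- tuneRelevances(sim$graph, train, c("participates_in"), grid = 1)
  expect_equal(id$relevance$values, numeric(0) , ignore_attr = TRUE)
  expect_equal(id$trainedAuc, id$baselineAuc)

  grid <- c(0.25, 1, 5, 10)
  res <- tuneRelevances(sim$graph, train,
                        c("participates_in", "refers_to"), grid,
                        pinned = relevanceMap(c(codes_for = 10)))
  # pinned values survive; never below the baseline on training data
  # (recovery of the planted signal type is checked at full generator
  # scale in the acceptance suite)
  expect_equal(res$relevance$values[["codes_for"]], 10)
  expect_gte(res$trainedAuc, res$baselineAuc)
  # profiles cover the full grid for each tuned type
  expect_equal(res$profiles$participates_in$value, grid)

  # held-out evaluation: split one sample into disjoint train/validation
  all <- makeLinkCases(sim$truth, sim$graph, 24, 24, seed = 63)
  pos <- which(all$label == 1); neg <- which(all$label == 0)
  trIdx <- c(pos[1:12], neg[1:12])
  heldOut <- labeledPairSet(all$node1[-trIdx], all$node2[-trIdx],
                            all$label[-trIdx])
  train <- labeledPairSet(all$node1[trIdx], all$node2[trIdx],
                          all$label[trIdx])
  res2 <- tuneRelevances(sim$graph, train, c("participates_in"), grid,
                         pinned = relevanceMap(c(codes_for = 10)),
                         validation = heldOut)
  expect_gte(res2$validationAuc, res2$baselineAuc - 0.05)
  expect_error(tuneRelevances(sim$graph, train, "refers_to", numeric()),
               "non-empty")
  expect_error(tuneRelevances(sim$graph, train, "refers_to", c(-1, 1)),
               "non-negative")
  expect_error(
    tuneRelevances(sim$graph, train, "refers_to", 1, validation = train),
    "share")
})
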