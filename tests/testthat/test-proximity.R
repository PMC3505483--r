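test_that("best-path probability equals exhaustive path enumeration", {
  wg <- asWeighted(threeEdgeGraph())
  # direct 0.5 beats the 0.25 two-edge path
  expect_equal(bestPathProbability(wg, "s", "t"), 0.5)
  expect_equal(bestPathProbability(wg, "s", "s"), 1)

  single <- asWeighted(pairGraph(r = 0.6))
  expect_equal(bestPathProbability(single, "a", "b"), 0.6)

  disc <- heteroGraph(data.frame(id = c("s", "t"), type = "N"), NULL,
                      symReg())
  expect_equal(bestPathProbability(asWeighted(disc), "s", "t"), 0)

  # property: agreement with brute-force simple-path enumeration
  for (seed in 1:25) {
    wg <- randomSmallGraph(nNodes = sample(4:8, 1), maxEdges = 12,
                           seed = 1000 + seed)
    ids <- graphNodes(wg)$id
    st <- sample(ids, 2)
    expect_equal(bestPathProbability(wg, st[1], st[2]),
                 bruteBestPath(wg, st[1], st[2]), tolerance = 1e-10)
  }
})

test_that("realization sampling is Bernoulli per edge and seed-stable", {
  g <- heteroGraph(data.frame(id = c("a", "b", "c"), type = "N"),
                   data.frame(from = c("a", "b"), to = c("b", "c"),
                              type = "link", reliability = c(1, 0)),
                   symReg())
  wg <- asWeighted(g)
  r <- sampleRealization(wg, seed = 1)
  expect_identical(r, c(TRUE, FALSE))
  expect_identical(sampleRealization(wg, seed = 9),
                   sampleRealization(wg, seed = 9))

  half <- asWeighted(pairGraph(r = 0.5))
  draws <- vapply(1:10000, function(s) sampleRealization(half, seed = s),
                  logical(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 10000) + 0.005)
})

test_that("exact oracle reproduces closed-form reliability and ERD", {
  wg <- asWeighted(threeEdgeGraph())
  o <- exactReliabilityOracle(wg, "s", "t")
  expect_equal(o$reliability, 0.625)
  expect_equal(o$erd, 1.2)

  chain <- heteroGraph(data.frame(id = c("s", "a", "t"), type = "N"),
                       data.frame(from = c("s", "a"), to = c("a", "t"),
                                  type = "link", reliability = 0.5),
                       symReg())
  o2 <- exactReliabilityOracle(asWeighted(chain), "s", "t")
  expect_equal(o2$reliability, 0.25)
  expect_equal(o2$erd, 2.0)

  o3 <- exactReliabilityOracle(asWeighted(pairGraph(0.9)), "a", "b")
  expect_equal(o3$reliability, 0.9)
  expect_equal(o3$erd, 1.0)
})

test_that("Monte-Carlo reliability and ERD track the exact oracle", {
  wg <- asWeighted(threeEdgeGraph())
  p <- proximityParams("reliability", nSamples = 20000, seed = 5,
                       bound = FALSE)
  est <- networkReliability(wg, "s", "t", p)
  expect_lt(abs(proximityValue(est) - 0.625),
            4 * proximityStdError(est) + 1e-9)
  # exact endpoints
  one <- asWeighted(pairGraph(1))
  expect_equal(proximityValue(networkReliability(one, "a", "b", p)), 1)
  disc <- asWeighted(heteroGraph(data.frame(id = c("s", "t"), type = "N"),
                                 NULL, symReg()))
  expect_equal(proximityValue(networkReliability(disc, "s", "t", p)), 0)
  # conditioning makes a single imperfect edge exact
  e3 <- expectedReliableDistance(asWeighted(pairGraph(0.3)), "a", "b",
                                 proximityParams("expected_reliable_distance",
                                                 nSamples = 5000, seed = 2))
  expect_equal(proximityValue(e3), 1.0)
  # all-zero weights: undefined conditional distance
  zed <- asWeighted(pairGraph(0))
  ez <- expectedReliableDistance(zed, "a", "b",
                                 proximityParams("expected_reliable_distance",
                                                 nSamples = 200, seed = 2))
  expect_true(is.na(proximityValue(ez)))
  # identical seeds reproduce identical estimates bit for bit
  a <- networkReliability(wg, "s", "t", p)
  b <- networkReliability(wg, "s", "t", p)
  expect_identical(proximityValue(a), proximityValue(b))
})

test_that("increasing an edge weight never decreases reliability (oracle)", {
  for (seed in 1:10) {
    wg <- randomSmallGraph(5, 8, seed = 2000 + seed)
    ids <- graphNodes(wg)$id
    st <- sample(ids, 2)
    base <- exactReliabilityOracle(wg, st[1], st[2])$reliability
    bump <- wg
    e <- sample(edgeCount(wg), 1)
    bump@weight[e] <- min(1, bump@weight[e] + 0.3)
    expect_gte(exactReliabilityOracle(bump, st[1], st[2])$reliability,
               base - 1e-12)
    # best path is one witness of connection: pbp <= reliability
    expect_lte(bestPathProbability(wg, st[1], st[2]), base + 1e-12)
  }
})

test_that("degenerate all-weights-one limit: reliability 1, ERD = hop distance", {
  g <- heteroGraph(data.frame(id = c("s", "a", "b", "t"), type = "N"),
                   data.frame(from = c("s", "a", "b"),
                              to = c("a", "b", "t"),
                              type = "link", reliability = 1), symReg())
  wg <- asWeighted(g)
  o <- exactReliabilityOracle(wg, "s", "t")
  expect_equal(o$reliability, 1)
  expect_equal(o$erd, 3)
})

test_that("random walk with restart matches the closed form and simulation", {
  wg <- asWeighted(pairGraph(1), cap = FALSE)
  p <- proximityParams("random_walk", beta = 0.2)
  # pi_s = beta + (1-beta) pi_t, pi_t = (1-beta) pi_s => pi_t = 4/9
  expect_equal(proximityValue(randomWalkProximity(wg, "a", "b", p)), 4 / 9,
               tolerance = 1e-9)
  # self-proximity: stationary mass at the root itself
  expect_equal(proximityValue(randomWalkProximity(wg, "a", "a", p)), 5 / 9,
               tolerance = 1e-9)
  # stationary vector sums to one
  st <- HetNetProx:::.rwStationary(wg, "a", 0.2)
  expect_equal(sum(st), 1, tolerance = 1e-9)

  # simulation converges to the exact solve on a 20-node graph
  wg20 <- randomSmallGraph(20, 60, seed = 77)
  wg20@config$cap <- FALSE
  ids <- graphNodes(wg20)$id
  exact <- proximityValue(randomWalkProximity(wg20, ids[1], ids[2], p))
  sim <- proximityValue(randomWalkProximity(
    wg20, ids[1], ids[2],
    proximityParams("random_walk", beta = 0.2, rwMethod = "simulate",
                    rwIterations = 1e6, seed = 4)))
  expect_lt(abs(exact - sim), 0.01)
})

test_that("isolated nodes and zero-weight edges are handled in the walk", {
  g <- heteroGraph(data.frame(id = c("a", "b", "z"), type = "N"),
                   data.frame(from = c("a", "b"), to = c("b", "z"),
                              type = "link", reliability = c(1, 0)),
                   symReg())
  wg <- asWeighted(g)
  p <- proximityParams("random_walk", beta = 0.2)
  # z is unreachable through the zero-weight edge
  expect_equal(proximityValue(randomWalkProximity(wg, "a", "z", p)), 0)
  # a walk rooted at the isolated node stays there
  expect_equal(proximityValue(randomWalkProximity(wg, "z", "z", p)), 1)
  # simulation agrees (forced restarts at the dangling root)
  sim <- randomWalkProximity(wg, "z", "z",
                             proximityParams("random_walk",
                                             rwMethod = "simulate",
                                             rwIterations = 1000, seed = 1))
  expect_equal(proximityValue(sim), 1)
})

test_that("proximity matrices are symmetric with the documented diagonal", {
  wg <- asWeighted(pairGraph(0.6))
  M <- proximityMatrix(wg, c("a", "b"), proximityParams("best_path"))
  expect_equal(M, matrix(c(1, 0.6, 0.6, 1), 2, 2,
                         dimnames = list(c("a", "b"), c("a", "b"))))
  wg3 <- randomSmallGraph(8, 14, seed = 31)
  ids <- graphNodes(wg3)$id[1:5]
  for (meas in c("best_path", "random_walk")) {
    M <- proximityMatrix(wg3, ids, proximityParams(meas))
    expect_equal(M, t(M))
  }
  # chain: reliability entry between the ends equals the path product
  chain <- asWeighted(heteroGraph(
    data.frame(id = c("x", "y", "z"), type = "N"),
    data.frame(from = c("x", "y"), to = c("y", "z"), type = "link",
               reliability = 0.5), symReg()))
  Mr <- proximityMatrix(chain, c("x", "z"),
                        proximityParams("reliability", nSamples = 20000,
                                        seed = 3))
  o <- exactReliabilityOracle(chain, "x", "z")
  expect_lt(abs(Mr["x", "z"] - o$reliability), 4 * sqrt(0.25 / 20000) + 0.005)
  expect_equal(Mr["x", "x"], 1)
})
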