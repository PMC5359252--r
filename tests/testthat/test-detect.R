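# Network detection: score arithmetic, greedy vs exhaustive search,
# k-partite partitioning, invariances.

cfgMean <- detectionConfig(lambdaGamma = 0)  # plain global-mean centering

test_that("scoreSubgraph computes the centered sum over scoring edges", {
  # constant W at lambda: every subgraph scores exactly 0
  W <- matrix(2, 5, 5); diag(W) <- 0
  net <- detectedNetwork(c(1, 3, 5), "clique")
  expect_equal(scoreSubgraph(W, net, lambda = 2), 0)

  # 4-node graph, clique {1,2,3} with W = 5 on its 3 edges, 1 elsewhere:
  # lambda = mean = 3, score = 3 * (5 - 3) = 6
  W <- matrix(1, 4, 4)
  W[1, 2] <- W[2, 1] <- W[1, 3] <- W[3, 1] <- W[2, 3] <- W[3, 2] <- 5
  diag(W) <- 0
  lam <- mean(W[upper.tri(W)])
  expect_equal(lam, 3)
  expect_equal(scoreSubgraph(W, detectedNetwork(1:3, "clique"), lam), 6)

  # adding a node whose edges all fall below lambda strictly lowers the score
  expect_lt(scoreSubgraph(W, detectedNetwork(1:4, "clique"), lam), 6)

  # k-partite scoring edges are the between-set pairs only
  netKP <- detectedNetwork(1:4, "k_partite", partition = list(1:2, 3:4))
  expect_equal(nrow(scoringEdges(netKP)), 4)
  expect_equal(scoreSubgraph(W, netKP, 0), 5 + 1 + 5 + 1)
})

test_that("a planted heavy clique is recovered exactly and matches brute force", {
  set.seed(41)
  W <- blockWeightMatrix(10, background = 0, blocks = list(
    list(nodes = 3:6, w = 8)))
  W[upper.tri(W)][W[upper.tri(W)] == 0] <- runif(sum(W[upper.tri(W)] == 0))
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  nets <- detectCliqueNetworks(W, cfgMean)
  lam <- effectiveLambda(W, cfgMean)
  expect_equal(networkNodes(nets[[1]]), 3:6)
  orc <- oracleBestSubset(W, lam)
  expect_equal(networkScore(nets[[1]]), orc$score, tolerance = 1e-9)
  expect_equal(networkNodes(nets[[1]]), sort(orc$nodes))
})

test_that("two disjoint planted cliques come back node-disjoint in score order", {
  # default dispersion margin: with a plain mean threshold the exhaustive
  # optimum on this instance is the *union* of both cliques bridged by weak
  # edges, which is exactly the absorption the margin exists to prevent
  set.seed(42)
  cfgDef <- detectionConfig()
  W <- blockWeightMatrix(12, background = 0, blocks = list(
    list(nodes = 1:4, w = 9), list(nodes = 7:9, w = 7)))
  W[upper.tri(W)][W[upper.tri(W)] == 0] <- runif(sum(W[upper.tri(W)] == 0), 0, 0.5)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  nets <- detectCliqueNetworks(W, cfgDef)
  expect_gte(length(nets), 2)
  n1 <- networkNodes(nets[[1]]); n2 <- networkNodes(nets[[2]])
  expect_length(intersect(n1, n2), 0)
  expect_gte(networkScore(nets[[1]]), networkScore(nets[[2]]))
  expect_equal(n1, 1:4)
  expect_equal(n2, 7:9)
  # first extraction matches the global exhaustive optimum
  orc <- oracleBestSubset(W, effectiveLambda(W, cfgDef))
  expect_equal(networkScore(nets[[1]]), orc$score, tolerance = 1e-9)
})

test_that("a zero weight matrix yields no networks", {
  W <- matrix(0, 8, 8)
  expect_length(detectCliqueNetworks(W, cfgMean), 0)
  expect_length(detectAll(W, cfgMean), 0)
})

test_that("4-node k-partite example matches exhaustive partition enumeration", {
  W <- matrix(0.1, 4, 4)
  W[1, 3] <- W[3, 1] <- W[1, 4] <- W[4, 1] <- 5
  W[2, 3] <- W[3, 2] <- W[2, 4] <- W[4, 2] <- 5
  diag(W) <- 0
  net <- detectKPartiteNetwork(W, 1:4, cfgMean)
  expect_equal(networkTopology(net), "k_partite")
  expect_equal(length(networkPartition(net)), 2)
  expect_equal(networkPartition(net), list(1:2, 3:4))
  orc <- oracleBestPartition(W, effectiveLambda(W, cfgMean), kMax = 3)
  expect_equal(networkScore(net), orc$score, tolerance = 1e-9)
  expect_equal(orc$k, 2)
})

test_that("constant W gives the degenerate no-network k-partite result", {
  W <- matrix(3, 6, 6); diag(W) <- 0
  expect_null(detectKPartiteNetwork(W, 1:6, cfgMean))
  expect_error(detectKPartiteNetwork(W, 1:3, cfgMean), "at least 4")
})

test_that("a planted 3-partite structure is recovered with k = 3", {
  # heavy between-set, light within-set over 9 nodes
  W <- matrix(6, 9, 9)
  sets <- list(1:3, 4:6, 7:9)
  for (s in sets) W[s, s] <- 0.2
  diag(W) <- 0
  net <- detectKPartiteNetwork(W, 1:9, cfgMean)
  expect_equal(length(networkPartition(net)), 3)
  expect_equal(networkPartition(net), sets)
  orc <- oracleBestPartition(W, effectiveLambda(W, cfgMean), kMax = 3)
  expect_equal(orc$k, 3)
  expect_equal(networkScore(net), orc$score, tolerance = 1e-9)
})

test_that("detectAll assigns topologies and prefers the better reading", {
  # default dispersion margin: with a plain mean threshold the exhaustive
  # optimum is the union of both structures bridged by background edges
  W <- blockWeightMatrix(12, background = 0.5, blocks = list(
    list(nodes = 1:3, w = 6)))
  # bipartite block {4,5} | {6,7}: heavy between, light within
  for (i in 4:5) for (j in 6:7) W[i, j] <- W[j, i] <- 6
  W[4, 5] <- W[5, 4] <- 0.2
  W[6, 7] <- W[7, 6] <- 0.2
  cfgDef <- detectionConfig()
  nets <- detectAll(W, cfgDef)
  topo <- vapply(nets, networkTopology, character(1))
  nodesList <- lapply(nets, networkNodes)
  iCl <- which(vapply(nodesList, function(x) setequal(x, 1:3), logical(1)))
  iKP <- which(vapply(nodesList, function(x) setequal(x, 4:7), logical(1)))
  expect_length(iCl, 1)
  expect_length(iKP, 1)
  expect_equal(topo[iCl], "clique")
  expect_equal(topo[iKP], "k_partite")
  expect_equal(networkPartition(nets[[iKP]]), list(4:5, 6:7))
  # k-partite reading strictly beats the clique reading on the same nodes
  lam <- effectiveLambda(W, cfgDef)
  expect_gt(networkScore(nets[[iKP]]),
            scoreSubgraph(W, detectedNetwork(4:7, "clique"), lam))
  # scores are sorted descending
  sc <- vapply(nets, networkScore, numeric(1))
  expect_true(all(diff(sc) <= 1e-12))
})

test_that("node relabeling permutes detected node sets identically", {
  set.seed(55)
  W <- blockWeightMatrix(10, background = 0, blocks = list(
    list(nodes = 2:5, w = 7)))
  W[upper.tri(W)][W[upper.tri(W)] == 0] <-
    runif(sum(W[upper.tri(W)] == 0), 0, 0.8)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  perm <- sample(10)
  Wp <- W[perm, perm]  # node v of W sits at position match(v, perm) in Wp
  nets <- detectCliqueNetworks(W, cfgMean)
  netsP <- detectCliqueNetworks(Wp, cfgMean)
  expect_equal(length(nets), length(netsP))
  expect_equal(sort(match(networkNodes(nets[[1]]), perm)),
               networkNodes(netsP[[1]]))
  expect_equal(networkScore(nets[[1]]), networkScore(netsP[[1]]),
               tolerance = 1e-9)
})

test_that("planted-clique recovery is monotone in effect size", {
  deltas <- c(0.15, 0.3, 0.6)
  jac <- vapply(deltas, function(d) {
    out <- simulateConnectomes(generatorConfig(
      nNodes = 30, nSubjectsA = 25, nSubjectsB = 25,
      planted = list(plantedClique(1:6, d)), seed = 321))
    W <- weightMatrix(edgewiseTests(out$sample))
    nets <- detectAll(W)
    if (!length(nets)) return(0)
    max(vapply(nets, function(n) jaccard(networkNodes(n), 1:6), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(jac) >= 0))
  expect_equal(jac[3], 1)
})

test_that("three planted blocks are recovered at study scale", {
  cfg <- generatorConfig(
    nNodes = 90, nSubjectsA = 48, nSubjectsB = 65,
    planted = list(
      plantedClique(1:12, -0.5),
      plantedPartite(list(21:25, 26:31), 0.5),
      plantedClique(41:46, 0.45)),
    seed = 2024)
  out <- simulateConnectomes(cfg)
  W <- weightMatrix(edgewiseTests(out$sample))
  nets <- detectAll(W)
  expect_gte(length(nets), 3)
  nodesList <- lapply(nets, networkNodes)
  for (planted in list(1:12, 21:31, 41:46)) {
    best <- max(vapply(nodesList, function(x) jaccard(x, planted),
                       numeric(1)))
    expect_gte(best, 0.8)
  }
})
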