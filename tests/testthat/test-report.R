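# Reporting artifacts and LOOCV validation.

test_that("heatmap ordering lists detected networks first and is a permutation", {
  nt <- syntheticNodeTable(10)
  expect_equal(heatmapOrder(list(), nt), 1:10)

  net <- detectedNetwork(c(9, 2, 5, 7, 3), "clique", score = 10)
  ord <- heatmapOrder(list(net), nt)
  expect_equal(ord[1:5], c(2, 3, 5, 7, 9))
  expect_equal(ord[6:10], c(1, 4, 6, 8, 10))
  expect_setequal(ord, 1:10)

  # k-partite: set 1 then set 2, each by atlas index; then leftovers
  kp <- detectedNetwork(c(1, 4, 6, 8), "k_partite",
                        partition = list(c(6, 1), c(8, 4)), score = 5)
  ord2 <- heatmapOrder(list(net, kp), nt)
  expect_equal(ord2, c(2, 3, 5, 7, 9, 1, 6, 4, 8, 10))
  # networks ordered by descending score regardless of list order
  expect_equal(heatmapOrder(list(kp, net), nt), ord2)

  expect_error(heatmapOrder(list(net, detectedNetwork(c(2, 11, 12), "clique")),
                            nt), "disjoint")
})

test_that("heatmap order is a permutation for random disjoint networks", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(8:15, 1)
    nt <- syntheticNodeTable(n)
    pool <- sample(n)
    nets <- list(detectedNetwork(pool[1:3], "clique", score = runif(1)),
                 detectedNetwork(pool[4:7], "k_partite",
                                 partition = list(pool[4:5], pool[6:7]),
                                 score = runif(1)))
    expect_setequal(heatmapOrder(nets, nt), seq_len(n))
  }
})

test_that("directional edge tables carry group-named directions sorted by W", {
  out <- simulateConnectomes(generatorConfig(
    nNodes = 8, nSubjectsA = 6, nSubjectsB = 6,
    planted = list(plantedClique(1:4, -1.2)),  # hypoconnected in group B
    groupLabels = c("TC", "ASD"), seed = 19))
  ev <- edgewiseTests(out$sample)
  net <- detectedNetwork(1:4, "clique")
  tab <- directionalEdgeTable(net, ev, nodeTable(out$sample))
  expect_equal(nrow(tab), 6)             # m(m-1)/2 scoring edges
  expect_true(all(diff(tab$W) <= 1e-12))
  # strong negative delta in ASD: every clique edge is TC > ASD
  expect_true(all(tab$direction == "TC>ASD"))
  st <- edgeStats(ev)
  expect_equal(sort(tab$W, decreasing = TRUE),
               sort(st$W[st$i <= 4 & st$j <= 4], decreasing = TRUE))
})

test_that("direction labels flip when the manifest group order is swapped", {
  out <- simulateConnectomes(generatorConfig(
    nNodes = 6, nSubjectsA = 5, nSubjectsB = 5,
    planted = list(plantedClique(1:3, 1.5)),
    groupLabels = c("g1", "g2"), seed = 23))
  s <- out$sample
  mats <- lapply(seq_len(ncol(s)), function(i) subjectMatrix(s, i))
  names(mats) <- subjectIds(s)
  # swap the manifest labels themselves: g1 subjects become g2 and back
  g <- as.character(subjectGroups(s))
  swapped <- ConnectomeSample(
    mats, factor(ifelse(g == "g1", "g2", "g1"), levels = c("g1", "g2")),
    nodeTable = nodeTable(s), subjectIds = subjectIds(s))
  net <- detectedNetwork(1:3, "clique")
  t1 <- directionalEdgeTable(net, edgewiseTests(s), nodeTable(s))
  t2 <- directionalEdgeTable(net, edgewiseTests(swapped), nodeTable(s))
  flip <- c("g1>g2" = "g2>g1", "g2>g1" = "g1>g2")
  expect_equal(unname(flip[t1$direction]), t2$direction)
  # merely reordering the factor levels does not change what the labels say
  reord <- ConnectomeSample(
    mats, factor(g, levels = c("g2", "g1")),
    nodeTable = nodeTable(s), subjectIds = subjectIds(s))
  t3 <- directionalEdgeTable(net, edgewiseTests(reord), nodeTable(s))
  expect_equal(t3$direction, t1$direction)
})

test_that("network report files have the expected shape", {
  out <- simulateConnectomes(generatorConfig(
    nNodes = 25, nSubjectsA = 10, nSubjectsB = 10,
    planted = list(plantedPartite(list(1:9, 10:19), 0.8)), seed = 3))
  ev <- edgewiseTests(out$sample)
  nt <- nodeTable(out$sample)
  dir <- withr::local_tempdir()

  # empty network list: original order, no edge lists
  writeNetworkReport(list(), ev, nt, dir)
  ord <- read.csv(file.path(dir, "node_order.csv"))
  expect_equal(ord$node, 1:25)
  expect_length(list.files(dir, pattern = "network.*edges"), 0)
  expect_length(jsonlite::read_json(file.path(dir, "networks.json")), 0)

  # a clique on m nodes emits m(m-1)/2 edge rows; a bipartite network with
  # set sizes 9 and 10 emits 90 between-set rows
  nets <- list(
    detectedNetwork(1:19, "k_partite", partition = list(1:9, 10:19),
                    score = 50),
    detectedNetwork(20:24, "clique", score = 20))
  writeNetworkReport(nets, ev, nt, dir)
  e1 <- read.csv(file.path(dir, "network1_edges.csv"))
  e2 <- read.csv(file.path(dir, "network2_edges.csv"))
  expect_equal(nrow(e1), 90)
  expect_equal(nrow(e2), 10)
  # every bipartite edge connects a set-1 node to a set-2 node
  expect_true(all((e1$node_i %in% 1:9) != (e1$node_i %in% 10:19)))
  expect_true(all((e1$node_i %in% 1:9 & e1$node_j %in% 10:19) |
                    (e1$node_i %in% 10:19 & e1$node_j %in% 1:9)))
  js <- jsonlite::read_json(file.path(dir, "networks.json"))
  expect_equal(js[[1]]$topology, "k_partite")
  expect_equal(js[[2]]$topology, "clique")

  expect_error(writeNetworkReport(list(detectedNetwork(24:26, "clique")),
                                  ev, nt, dir), "unknown node")
})

test_that("perfectly separated groups classify at accuracy 1 with both kernels", {
  out <- simulateConnectomes(generatorConfig(
    nNodes = 10, nSubjectsA = 8, nSubjectsB = 8, subjectSD = 0.1,
    planted = list(plantedClique(1:4, 2)), seed = 15))
  fe <- affectedEdges(out$truth)
  for (k in c("radial", "linear")) {
    rep <- classifyLOOCV(out$sample, fe, kernel = k)
    expect_equal(rep@accuracy, 1.0)
    expect_equal(rep@nCorrect, 16L)
  }
})

test_that("null samples classify near the majority rate", {
  out <- simulateConnectomes(generatorConfig(
    nNodes = 10, nSubjectsA = 12, nSubjectsB = 12, seed = 16))
  fe <- cbind(1:4, 5:8)
  rep <- classifyLOOCV(out$sample, fe, kernel = "radial")
  expect_lt(rep@accuracy, 0.8)
})

test_that("LOOCV accuracy is invariant to a common affine feature transform", {
  out <- simulateConnectomes(generatorConfig(
    nNodes = 8, nSubjectsA = 7, nSubjectsB = 7,
    planted = list(plantedClique(1:3, 0.8)), seed = 18))
  s <- out$sample
  fe <- affectedEdges(out$truth)
  a1 <- classifyLOOCV(s, fe, kernel = "linear")@accuracy
  mats <- lapply(seq_len(ncol(s)), function(i) {
    M <- 2.5 * subjectMatrix(s, i) + 0.7
    diag(M) <- 0
    M
  })
  names(mats) <- subjectIds(s)
  s2 <- ConnectomeSample(mats, subjectGroups(s), nodeTable = nodeTable(s),
                         subjectIds = subjectIds(s))
  a2 <- classifyLOOCV(s2, fe, kernel = "linear")@accuracy
  expect_equal(a1, a2)
})

test_that("strong planted cliques classify well from their own edges", {
  acc <- vapply(1:5, function(seed) {
    out <- simulateConnectomes(generatorConfig(
      nNodes = 20, nSubjectsA = 40, nSubjectsB = 40,
      planted = list(plantedClique(1:8, 0.6)), seed = seed))
    classifyLOOCV(out$sample, affectedEdges(out$truth),
                  kernel = "radial")@accuracy
  }, numeric(1))
  expect_gt(mean(acc), 0.8)
})

test_that("nested LOOCV re-detects features inside each fold", {
  out <- simulateConnectomes(generatorConfig(
    nNodes = 12, nSubjectsA = 10, nSubjectsB = 10,
    planted = list(plantedClique(1:4, 1.5)), seed = 44))
  rep <- classifyLOOCV(out$sample, kernel = "linear", nested = TRUE)
  expect_true(rep@details$nested)
  expect_gt(rep@accuracy, 0.8)   # strong signal survives honest selection
})
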