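test_that("FS-Weight is symmetric and 1 on complete graphs", {
  pairs <- t(combn(paste0("n", 1:6), 2))
  net <- ppiNetwork(pairs[, 1], pairs[, 2], kind = "dynamic")
  ctx <- fsWeightContext(net)
  for (i in c("n1", "n3")) {
    for (j in c("n2", "n5")) {
      expect_equal(fsWeight(ctx, i, j), fsWeight(ctx, j, i))
      expect_equal(fsWeight(ctx, i, j), 1)
    }
  }
  expect_error(fsWeight(ctx, "n1", "zz"), "not in")
  expect_error(fsWeight(ctx, "n1", "n1"), "distinct")
})

test_that("FS-Weight on a path endpoint pair matches the hand-computed value", {
  net <- ppiNetwork(c("A", "B"), c("B", "C"), kind = "dynamic")
  ctx <- fsWeightContext(net)
  # closed nbhds {A,B} and {B,C}: common 1, exclusive 1 each side,
  # N_avg = 4/3 so both small-degree penalties vanish: (2/3)^2 = 4/9
  expect_equal(fsWeight(ctx, "A", "C"), 4 / 9, tolerance = 1e-15)
  # nonadjacent pairs are legal inputs, and disjoint neighbourhoods give 0
  net2 <- ppiNetwork(c("A", "C"), c("B", "D"), kind = "dynamic")
  expect_equal(fsWeight(fsWeightContext(net2), "A", "C"), 0)
})

test_that("FS-Weight agrees with the brute-force oracle on random graphs", {
  set.seed(505)
  for (rep in 1:50) {
    g <- rGraph(sample(4:30, 1), stats::runif(1, 0.1, 0.6))
    if (length(g$u) == 0) next
    net <- ppiNetwork(g$u, g$v, kind = "dynamic")
    ctx <- fsWeightContext(net)
    nodes <- networkNodes(net)
    edges <- networkEdges(net)
    idx <- t(combn(length(nodes), 2))
    for (r in seq_len(nrow(idx))) {
      i <- nodes[idx[r, 1]]; j <- nodes[idx[r, 2]]
      got <- fsWeight(ctx, i, j)
      expect_equal(got, bfFsWeight(edges, nodes, i, j), tolerance = 1e-12)
      expect_gte(got, 0)
      expect_lte(got, 1)
    }
  }
})

test_that("strong-similarity threshold is inclusive", {
  expect_true(isStrong(0.25, 0.25))
  expect_false(isStrong(0.24, 0.25))
  expect_true(isStrong(0, 0))
  expect_error(isStrong(0.5, 1.5))
})

test_that("cluster density behaves as 2m/(n(n-1)) over an enumerated table", {
  # complete clusters of any size score 1
  pairs <- t(combn(paste0("x", 1:6), 2))
  kAll <- ppiNetwork(pairs[, 1], pairs[, 2], kind = "dynamic")
  expect_equal(clusterCoefficient(paste0("x", 1:3), kAll)$value,
               clusterCoefficient(paste0("x", 1:4), kAll)$value)
  expect_equal(clusterCoefficient(paste0("x", 1:4), kAll)$value, 1)

  # hand-enumerated (n, m) values
  net <- ppiNetwork(c("a", "a", "b"), c("b", "c", "c"), kind = "dynamic")
  expect_equal(clusterCoefficient(c("a", "b"), net)$value, 1)
  expect_equal(clusterCoefficient(c("a", "d"), net)$value, 0)
  expect_equal(clusterCoefficient(c("a", "b", "d"), net)$value, 1 / 3)
  expect_equal(clusterCoefficient(c("a", "b", "c", "d"), net)$value, 1 / 2)
  cc5 <- clusterCoefficient(c("a", "b", "c", "d", "e"), net)
  expect_equal(cc5$m, 3L)
  expect_equal(cc5$n, 5L)
  expect_equal(cc5$value, 3 / 10)

  # increasing in m at fixed n; adding an isolated node strictly decreases
  withEdge <- clusterCoefficient(c("a", "b"), net)$value
  without <- clusterCoefficient(c("a", "d"), net)$value
  expect_gt(withEdge, without)
  expect_gt(clusterCoefficient(c("a", "b", "c"), net)$value,
            clusterCoefficient(c("a", "b", "c", "z"), net)$value)

  expect_error(clusterCoefficient("a", net), "at least 2")

  # m counts edges of whichever graph is supplied (combined networks too)
  ann <- annotationMap(list(a = "t", d = "t"))
  dnet <- net; dnet@nodes <- c("a", "b", "c", "d")
  cmb <- buildCombined(dnet, buildGOProteinSets(ann, dnet))
  expect_equal(clusterCoefficient(c("a", "d"), cmb)$value, 1)

  # brute-force m on random clusters
  set.seed(77)
  for (rep in 1:10) {
    g <- rGraph(12, 0.3)
    if (length(g$u) == 0) next
    net <- ppiNetwork(g$u, g$v, kind = "dynamic")
    cl <- sample(networkNodes(net), 5)
    cc <- clusterCoefficient(cl, net)
    m <- bfInternalEdges(cl, networkEdges(net))
    expect_equal(cc$m, m)
    expect_equal(cc$value, 2 * m / (5 * 4))
  }
})
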