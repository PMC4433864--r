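makeSeries <- function(values, tps = paste0("t", seq_len(ncol(values)))) {
  expressionSeries(values, tps)
}

test_that("activity compares each time point against the gene's own mean (inclusive)", {
  v <- rbind(up = c(1, 2, 3, 4), flat = c(5, 5, 5, 5), down = c(4, 2, 0, 0))
  # strictly decreasing example uses only 3 time points
  es <- makeSeries(rbind(up = c(1, 2, 3, 4)))
  act <- computeActivity(es)
  expect_equal(unname(geneMeans(act)), 2.5)
  expect_equal(unname(activityFlags(act)["up", ]),
               c(FALSE, FALSE, TRUE, TRUE))

  es2 <- makeSeries(rbind(flat = c(5, 5, 5)))
  expect_true(all(activityFlags(computeActivity(es2))))

  es3 <- makeSeries(rbind(down = c(4, 2, 0)))
  act3 <- computeActivity(es3)
  expect_equal(unname(geneMeans(act3)), 2)
  expect_equal(unname(activityFlags(act3)["down", ]),
               c(TRUE, TRUE, FALSE))
})

test_that("dynamic construction keeps only edges between active proteins", {
  static <- ppiNetwork(c("A", "A", "B"), c("B", "C", "C"))  # K3
  v <- rbind(A = c(9, 1), B = c(9, 1), C = c(1, 9))
  act <- computeActivity(makeSeries(v))
  dyn <- buildDynamic(static, act, selection = "t1")
  expect_setequal(networkNodes(dyn), c("A", "B"))
  expect_equal(edgeCount(dyn), 1L)
  expect_equal(provenance(dyn)$inactive, 1L)

  # all proteins inactive at a time point -> empty network, not an error
  v2 <- rbind(A = c(1, 9), B = c(1, 9), C = c(1, 9))
  dyn2 <- buildDynamic(static, computeActivity(makeSeries(v2)),
                       selection = "t1")
  expect_equal(nodeCount(dyn2), 0L)
  expect_equal(edgeCount(dyn2), 0L)

  expect_error(buildDynamic(static, act, selection = "t9"),
               "unknown time-point")
})

test_that("constant genes over the full selection reproduce the measured part of the static network", {
  set.seed(3)
  g <- rGraph(12, 0.3)
  static <- ppiNetwork(g$u, g$v)
  measured <- networkNodes(static)[1:9]
  v <- matrix(4, nrow = length(measured), ncol = 3,
              dimnames = list(measured, NULL))
  dyn <- buildDynamic(static, computeActivity(makeSeries(v)), mode = "any")
  e <- networkEdges(static)
  keep <- e[, 1] %in% measured & e[, 2] %in% measured
  expect_identical(unname(networkEdges(dyn)), unname(e[keep, , drop = FALSE]))
})

test_that("dynamic networks are subsets, monotone in the selection, and deterministic", {
  set.seed(11)
  g <- rGraph(20, 0.2)
  static <- ppiNetwork(g$u, g$v)
  nodes <- networkNodes(static)
  v <- matrix(stats::runif(length(nodes) * 4, 0, 10), nrow = length(nodes),
              dimnames = list(nodes, NULL))
  act <- computeActivity(makeSeries(v))

  key <- function(net) apply(networkEdges(net), 1, paste, collapse = "|")
  staticKey <- key(static)
  prev <- character(0)
  for (k in 1:4) {
    sel <- paste0("t", 1:k)
    dyn <- buildDynamic(static, act, selection = sel, mode = "any")
    expect_true(all(key(dyn) %in% staticKey))
    expect_true(all(prev %in% key(dyn)))  # monotone under growing selection
    prev <- key(dyn)
  }

  d1 <- buildDynamic(static, act, selection = c("t1", "t2"))
  d2 <- buildDynamic(static, act, selection = c("t1", "t2"))
  expect_identical(networkEdges(d1), networkEdges(d2))

  # mode=all is at most as permissive as mode=any
  dAll <- buildDynamic(static, act, selection = c("t1", "t2"), mode = "all")
  expect_true(all(key(dAll) %in% key(d1)))
})
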