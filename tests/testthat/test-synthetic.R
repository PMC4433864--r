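test_that("degenerate deterministic limit: disjoint cliques plus silent background", {
  spec <- syntheticSpec(nComplexes = 2L, sizeRange = c(4L, 4L),
                        nBackground = 10L, pIn = 1, pOut = 0,
                        fidelity = 1, seed = 5L)
  sim <- generateSynthetic(spec)
  expect_equal(length(sim$truth), 2L)
  expect_true(all(lengths(complexes(sim$truth)) == 4L))
  # static network = exactly the two K4s (background has no edges and is
  # therefore absent from the edge-derived node set)
  expect_equal(edgeCount(sim$static), 2L * choose(4, 2))
  expect_setequal(networkNodes(sim$static),
                  unlist(complexes(sim$truth)))
  # every member carries its complex's private term
  ann <- annotationList(sim$annotations)
  for (i in 1:2) {
    terms <- unique(unlist(ann[sim$truth[[i]]]))
    expect_length(terms, 1L)
  }
})

test_that("regeneration under a fixed seed is byte-identical", {
  spec <- syntheticSpec(nComplexes = 5L, nBackground = 30L, seed = 123L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSyntheticFixtures(generateSynthetic(spec), d1)
  writeSyntheticFixtures(generateSynthetic(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("scheduled stages drive activity exactly as constructed", {
  spec <- syntheticSpec(nComplexes = 3L, sizeRange = c(4L, 4L),
                        nBackground = 20L, nStages = 3L,
                        schedule = list(2L, c(1L, 3L), 1:3), seed = 9L)
  sim <- generateSynthetic(spec)
  act <- computeActivity(readBack(sim))
  flags <- activityFlags(act)
  m1 <- sim$truth[[1]]  # active only at stage 2
  expect_true(all(flags[m1, "t2"]))
  expect_false(any(flags[m1, c("t1", "t3")]))
  m2 <- sim$truth[[2]]
  expect_true(all(flags[m2, c("t1", "t3")]))
  expect_false(any(flags[m2, "t2"]))
  m3 <- sim$truth[[3]]  # constant high: active everywhere under >=
  expect_true(all(flags[m3, ]))

  # single-stage dynamic network removes every member of complexes
  # scheduled inactive at that stage
  dyn1 <- buildDynamic(sim$static, act, selection = "t1")
  expect_length(intersect(networkNodes(dyn1), m1), 0L)
  dyn2 <- buildDynamic(sim$static, act, selection = "t2")
  expect_length(intersect(networkNodes(dyn2), m2), 0L)
})

test_that("infeasible and inconsistent specs are rejected", {
  expect_error(syntheticSpec(sizeRange = c(2L, 5L)))
  expect_error(syntheticSpec(pIn = 0.3, pOut = 0.5))
  expect_error(syntheticSpec(schedule = list(1L)))  # wrong length
  expect_error(syntheticSpec(nComplexes = 1L, schedule = list(integer(0))))
})

test_that("noiseless ground truth is recovered exactly end to end", {
  spec <- syntheticSpec(pIn = 1, pOut = 0, fidelity = 1, seed = 21L)
  sim <- generateSynthetic(spec)
  res <- runPipeline(sim$static, sim$expression, sim$annotations,
                     reference = sim$truth)
  expect_equal(res$evaluation$f1, 1)
  expect_setequal(
    vapply(complexes(res$predicted), paste, character(1), collapse = ","),
    vapply(complexes(sim$truth), paste, character(1), collapse = ","))
})
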