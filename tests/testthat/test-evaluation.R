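test_that("matching score: identity 1, disjoint 0, overlap-squared otherwise", {
  expect_equal(mScore(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_equal(mScore(c("A", "B"), c("X", "Y")), 0)
  # |A| = 4, |B| = 5, overlap 2: 2^2 / 20 = 0.2
  expect_equal(mScore(paste0("p", 1:4), c("p1", "p2", paste0("q", 1:3))),
               0.2)
  expect_equal(mScore(c("A", "B"), c("B", "C")),
               mScore(c("B", "C"), c("A", "B")))
  expect_error(mScore(character(0), "A"), "non-empty")
})

test_that("matching counts distinct complexes, not pairs", {
  cs <- complexSet(list(c("A", "B", "C"), c("D", "E", "F"),
                        c("G", "H", "I")))
  mr <- matchComplexSets(cs, cs, 0.2)
  expect_equal(mr@nmc, 3L)
  expect_equal(mr@nmp, 3L)

  mrEmpty <- matchComplexSets(cs, complexSet(list()), 0.2)
  expect_equal(mrEmpty@nmc, 0L)
  expect_equal(mrEmpty@nmp, 0L)
})

test_that("matching equals the brute-force double loop on random instances", {
  set.seed(808)
  universe <- sprintf("u%02d", 1:30)
  for (rep in 1:100) {
    refL <- rComplexList(5, universe)
    predL <- rComplexList(7, universe)
    thres <- sample(c(0.1, 0.2, 0.5), 1)
    mr <- matchComplexSets(complexSet(refL), complexSet(predL), thres)
    bf <- bfMatchCounts(refL, predL, thres)
    expect_equal(mr@nmc, bf$nmc)
    expect_equal(mr@nmp, bf$nmp)
    expect_equal(nrow(mr@pairs), bf$pairs)
  }
})

test_that("recall, precision and F1 follow their definitions and boundaries", {
  cs <- complexSet(list(c("A", "B", "C"), c("D", "E", "F")))
  mr <- matchComplexSets(cs, cs, 0.2)
  r <- complexRecall(mr); p <- complexPrecision(mr)
  expect_equal(r, 1)
  expect_equal(p, 1)
  expect_equal(complexF1(r, p), 1)
  expect_equal(complexF1(0, 0.7), 0)
  expect_equal(complexF1(0.6, 0.6), 0.6)  # r = p implies f1 = r
  expect_equal(complexF1(0.5, 0.25), 2 * 0.5 * 0.25 / 0.75)

  mrNone <- matchComplexSets(cs, complexSet(list()), 0.2)
  expect_warning(p0 <- complexPrecision(mrNone), "empty prediction")
  expect_equal(p0, 0)
})

test_that("curation restricts complexes to network nodes and never increases N_c", {
  ref <- complexSet(list(c("A", "B", "C"), c("C", "D", "E"),
                         c("X", "Y", "Z")))
  net <- ppiNetwork(c("A", "A", "C", "D"), c("B", "C", "D", "E"),
                    kind = "dynamic")
  cur <- curateComplexSet(ref, net, minSize = 3L)
  expect_lte(length(cur), length(ref))
  expect_equal(complexes(cur), list(c("A", "B", "C"), c("C", "D", "E")))
  # every curated complex is a subset of the original
  cur2 <- curateComplexSet(ref, c("A", "B", "C", "X"), minSize = 2L)
  expect_equal(complexes(cur2), list(c("A", "B", "C")))
})

test_that("network statistics match enumeration on canonical small graphs", {
  k3 <- ppiNetwork(c("A", "A", "B"), c("B", "C", "C"))
  s <- networkStats(k3)
  expect_equal(s@clusteringCoefficient, 1)
  expect_equal(s@diameter, 1)
  expect_equal(s@characteristicPathLength, 1)

  path <- ppiNetwork(c("A", "B"), c("B", "C"))
  sp <- networkStats(path)
  expect_equal(sp@clusteringCoefficient, 0)
  expect_equal(sp@diameter, 2)
  expect_equal(sp@characteristicPathLength, 4 / 3)

  star <- ppiNetwork(rep("hub", 3), c("a", "b", "c"))
  expect_equal(networkStats(star)@diameter, 2)

  # histograms conserve counts; disconnected networks report components
  two <- ppiNetwork(c("A", "C"), c("B", "D"))
  st <- networkStats(two)
  expect_equal(st@componentCount, 2L)
  expect_equal(sum(st@degreeHistogram), st@nodeCount)
  expect_equal(sum(st@pathLengthHistogram), 2)  # only connected pairs
  expect_equal(st@characteristicPathLength, 1)
})
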