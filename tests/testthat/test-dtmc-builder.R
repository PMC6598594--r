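# small attractor set over 5 genes used across the merging tests
fiveGeneAttractors <- function(states, counts) {
  new("AttractorSet", nodeIds = sprintf("m%d", 1:5), states = states,
      counts = as.integer(counts), nConverged = sum(as.integer(counts)),
      nTotal = sum(as.integer(counts)))
}

test_that("attractors merge by signature pattern with summed basins", {
  # two full states differing only outside the signature collapse
  a <- fiveGeneAttractors(c("11000", "11011", "00110"), c(5, 4, 2))
  st <- mergeAttractors(a, c("m1", "m2", "m3"))
  expect_equal(numPhenotypes(st), 2)
  expect_equal(phenotypePatterns(st), c("110", "001"))
  expect_equal(st@basinWeights, c(9, 2))
  expect_setequal(st@representatives[[1]], c("11000", "11011"))
  # states differing in one signature gene stay distinct
  b <- fiveGeneAttractors(c("10000", "11000"), c(1, 1))
  expect_equal(numPhenotypes(mergeAttractors(b, c("m1", "m2"))), 2)
  expect_error(mergeAttractors(fiveGeneAttractors(character(), integer()),
                               c("m1")), "no attractors")
  expect_error(mergeAttractors(a, c("m1", "nope")), "absent")
})

test_that("group counts match a hash-set oracle on random projections", {
  set.seed(121)
  keys <- vapply(1:100, function(i)
    paste(sample(0:1, 8, replace = TRUE), collapse = ""), "")
  keys <- keys[!duplicated(keys)]
  a <- new("AttractorSet", nodeIds = sprintf("m%d", 1:8), states = keys,
           counts = rep(1L, length(keys)),
           nConverged = length(keys), nTotal = length(keys))
  sig <- sprintf("m%d", 1:5)
  st <- mergeAttractors(a, sig)
  oracle <- unique(substr(keys, 1, 5))
  expect_equal(numPhenotypes(st), length(oracle))
  expect_setequal(phenotypePatterns(st), oracle)
})

test_that("snapping picks the closest known pattern with stable ties", {
  a <- fiveGeneAttractors(c("00000", "11000", "01000"), c(5, 3, 2))
  st <- mergeAttractors(a, c("m1", "m2"))  # patterns 00(5), 11(3), 01(2)
  expect_equal(phenotypePatterns(st), c("00", "11", "01"))
  # exact pattern: no change
  expect_equal(snapToKnown("11", st), list(stateId = 2, nChanged = 0))
  # full states are projected first
  expect_equal(snapToKnown("11011", st)$stateId, 2)
  # one bit away from a unique nearest pattern
  expect_equal(snapToKnown("10", st),
               list(stateId = 1, nChanged = 1))  # ties 00/11 -> larger basin
  # named full state input
  s <- setNames(c(0L, 1L, 0L, 0L, 0L), sprintf("m%d", 1:5))
  expect_equal(snapToKnown(s, st), list(stateId = 3, nChanged = 0))
  # snapping a known representative is idempotent
  for (i in seq_len(numPhenotypes(st)))
    expect_equal(snapToKnown(st@representatives[[i]][1], st),
                 list(stateId = i, nChanged = 0))
})

test_that("the worked transition-matrix example reproduces by hand", {
  # source pattern 00; destinations 11 (distance 2) and 01 (distance 1);
  # 10 recorded runs each, mean length 5 sweeps
  a <- fiveGeneAttractors(c("00000", "11000", "01000"), c(5, 3, 2))
  st <- mergeAttractors(a, c("m1", "m2"))
  recs <- data.frame(source = 1, dest = rep(c(2, 3), each = 10),
                     iterations = 5, escalations = 0,
                     snapped = FALSE, snapDistance = 0L, failed = FALSE)
  dtmc <- buildTransitionMatrix(recs, st)
  # raw weights (0.5/(2*5), 0.5/(1*5)) = (0.05, 0.1) -> normalized (1/3, 2/3)
  expect_equal(dtmc@P[1, ], c(0, 1 / 3, 2 / 3))
  # rows without exits are explicit absorbing self-loops
  expect_equal(dtmc@P[2, ], c(0, 1, 0))
  expect_true(all(dtmc@absorbing[2:3]))
  expect_equal(rowSums(dtmc@P), rep(1, 3), tolerance = 1e-12)
  # distances recorded on the signature patterns
  expect_equal(dtmc@dist[1, ], c(0, 2, 1))
})

test_that("uniform counts with equal distance and length give a uniform row", {
  a <- fiveGeneAttractors(c("00000", "10000", "01000"), c(3, 2, 1))
  st <- mergeAttractors(a, c("m1", "m2"))  # 00, 10, 01: d(1,2)=d(1,3)=1
  recs <- data.frame(source = 1, dest = rep(c(2, 3), each = 7),
                     iterations = 4, escalations = 0,
                     snapped = FALSE, snapDistance = 0L, failed = FALSE)
  dtmc <- buildTransitionMatrix(recs, st)
  expect_equal(dtmc@P[1, 2:3], c(0.5, 0.5))
})

test_that("larger distance or longer runs never gain relative probability", {
  a <- fiveGeneAttractors(c("00000", "11000", "01000"), c(5, 3, 2))
  st <- mergeAttractors(a, c("m1", "m2"))
  base <- data.frame(source = 1, dest = rep(c(2, 3), each = 10),
                     iterations = 5, escalations = 0,
                     snapped = FALSE, snapDistance = 0L, failed = FALSE)
  p0 <- buildTransitionMatrix(base, st)@P[1, 2]
  slower <- base
  slower$iterations[slower$dest == 2] <- 20  # same counts, longer i->2 runs
  p1 <- buildTransitionMatrix(slower, st)@P[1, 2]
  expect_lt(p1, p0)
})

test_that("a lone known phenotype makes every campaign run fail (absorbing)", {
  pl <- plantedAttractorNetwork(1)
  set.seed(131)
  a <- attractorCampaign(pl$net, 200, maxIter = 100)
  keep <- match("111", a@states)
  lone <- new("AttractorSet", nodeIds = a@nodeIds, states = a@states[keep],
              counts = a@counts[keep], nConverged = a@counts[keep],
              nTotal = a@counts[keep])
  st <- mergeAttractors(lone, nodeIds(pl$net))
  set.seed(132)
  recs <- transitionCampaign(pl$net, st, 30, maxIter = 100)
  expect_true(all(recs$failed))
  dtmc <- buildTransitionMatrix(recs, st)
  expect_true(dtmc@absorbing[1])
  expect_equal(dtmc@P, matrix(1, 1, 1))
})

test_that("two-basin toys yield transitions in both directions", {
  pl <- plantedAttractorNetwork(2)
  set.seed(141)
  a <- attractorCampaign(pl$net, 1500, maxIter = 100)
  st <- mergeAttractors(a, nodeIds(pl$net))
  set.seed(142)
  recs <- transitionCampaign(pl$net, st, 400, maxIter = 100)
  ok <- recs[!recs$failed, ]
  expect_gt(nrow(ok), 0)
  # some pair of phenotypes is connected in both directions
  pairs <- unique(paste(ok$source, ok$dest))
  rev <- paste(ok$dest, ok$source)
  expect_true(any(paste(ok$source, ok$dest) %in% rev))
  dtmc <- buildTransitionMatrix(recs, st)
  expect_equal(rowSums(dtmc@P), rep(1, numPhenotypes(st)), tolerance = 1e-12)
  expect_true(all(dtmc@P >= 0))
  # campaign reproducibility under seed
  set.seed(142)
  recs2 <- transitionCampaign(pl$net, st, 400, maxIter = 100)
  expect_identical(recs, recs2)
})
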