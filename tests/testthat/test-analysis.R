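test_that("Jaccard-Needham distance matches hand counts on published patterns", {
  a549 <- mesenchymalReference("A549")
  expect_equal(unname(a549),c(1, 0, 1, 0, 1, 1, 1))
  # identical patterns are at distance zero
  expect_equal(jaccardNeedham(a549, a549), 0)
  # the all-off high-efficiency phenotype sits at the maximal distance:
  # 5 reference-only genes over a union of 5
  pats <- highEfficiencyPhenotypes()
  p7 <- unlist(pats["7", names(a549)])
  expect_equal(sum(p7), 0)
  expect_equal(jaccardNeedham(p7, a549), 1)
  # all-ones test pattern: 2 test-only genes over a union of 7
  allOn <- setNames(rep(1, 7), names(a549))
  expect_equal(jaccardNeedham(allOn, a549), 2 / 7)
  # both-empty convention
  z <- setNames(rep(0, 3), c("a", "b", "c"))
  expect_equal(jaccardNeedham(z, z), 0)
  expect_error(jaccardNeedham(c(1, 0), c(1, 0, 1)), "length")
})

test_that("standard mode is a [0,1] symmetric distance equal to 1 - Jaccard", {
  set.seed(211)
  pairs <- lapply(1:10000, function(i) {
    n <- sample(3:9, 1)
    list(x = sample(0:1, n, replace = TRUE), y = sample(0:1, n, replace = TRUE))
  })
  d <- vapply(pairs, function(p) jaccardNeedham(p$x, p$y), 0)
  dRev <- vapply(pairs, function(p) jaccardNeedham(p$y, p$x), 0)
  oracle <- vapply(pairs, function(p) {
    un <- sum(p$x | p$y)
    if (un == 0) 0 else 1 - sum(p$x & p$y) / un
  }, 0)
  expect_true(all(d >= 0 & d <= 1))
  expect_identical(d, dRev)
  expect_equal(d, oracle)
})

test_that("the literal TF-counting mode differs as documented", {
  # a pattern with zero bits is at nonzero literal distance from itself
  x <- c(1, 0, 1, 0)
  expect_gt(jaccardNeedham(x, x, mode = "literal"), 0)
  expect_equal(jaccardNeedham(x, x, mode = "literal"), 2 / 4)
  # with no zero agreement the two modes coincide in the numerator's FT part
  expect_equal(jaccardNeedham(c(1, 1), c(1, 1), mode = "literal"), 0)
})

test_that("reference masking ignores genes outside the reference", {
  ref <- c(A = 1, B = NA, C = 0)
  # gene B never enters the count: (a01+a10)/(union) over A, C only
  expect_equal(jaccardNeedham(c(A = 1, B = 0, C = 0), ref), 0)
  expect_equal(jaccardNeedham(c(A = 0, B = 1, C = 0), ref), 1)
})

test_that("prevalence weighting of the distance follows the direct sum", {
  genes <- c("A", "B")
  traj <- new("PopulationTrajectory",
              prevalence = rbind(c(1, 0, 0), c(0.2, 0.5, 0.3)),
              converged = TRUE, patterns = c("11", "10", "00"),
              signatureGenes = genes)
  ref <- c(A = 1, B = 1)
  # all mass on the reference pattern -> 0
  expect_equal(weightedJND(traj, ref)[1], 0)
  # direct-sum oracle at the second iteration
  d <- c(0, 1 / 2, 1)
  expect_equal(weightedJND(traj, ref)[2], sum(c(0.2, 0.5, 0.3) * d))
  # uniform mass over distances 0 and 1 -> 0.5
  traj2 <- new("PopulationTrajectory",
               prevalence = rbind(c(0.5, 0.5)), converged = TRUE,
               patterns = c("11", "00"), signatureGenes = genes)
  expect_equal(weightedJND(traj2, ref)[1], 0.5)
  # top-fraction restriction keeps only the most prevalent states
  traj3 <- new("PopulationTrajectory",
               prevalence = rbind(c(0.6, 0.3, 0.1)), converged = TRUE,
               patterns = c("11", "10", "00"), signatureGenes = genes)
  expect_equal(weightedJND(traj3, ref, topFraction = 1 / 3)[1], 0)
  # random trajectories match the direct summation oracle
  set.seed(221)
  for (rep in 1:20) {
    w <- rgamma(3, 1); w <- w / sum(w)
    tr <- new("PopulationTrajectory", prevalence = matrix(w, nrow = 1),
              converged = TRUE, patterns = c("11", "10", "00"),
              signatureGenes = genes)
    expect_equal(weightedJND(tr, ref)[1], sum(w * d))
  }
})

test_that("averaging across populations pads to steady state and adds SE", {
  genes <- c("A", "B")
  mk <- function(rows) new("PopulationTrajectory", prevalence = rows,
                           converged = TRUE, patterns = c("11", "00"),
                           signatureGenes = genes)
  t1 <- mk(rbind(c(1, 0), c(0.5, 0.5)))
  t2 <- mk(rbind(c(0, 1)))
  out <- averageJND(list(t1, t2), c(A = 1, B = 1))
  expect_equal(out$iteration, c(0, 1))
  expect_equal(out$mean, c(0.5, 0.75))  # t2 padded with its final value 1
  expect_true(all(out$se >= 0))
})

test_that("fold changes compare endpoint marginals on the log2 scale", {
  genes <- c("A", "B", "C")
  traj <- new("PopulationTrajectory",
              prevalence = rbind(c(0.25, 0.5, 0.25, 0),
                                 c(0.5, 0, 0.25, 0.25)),
              converged = TRUE,
              patterns = c("100", "110", "000", "010"),
              signatureGenes = genes)
  fc <- log2FoldChanges(traj)
  # A: 0.75 -> 0.5; B: 0.5 -> 0.25 (halves, -1); C initial 0 -> excluded
  expect_equal(fc$log2FC[fc$gene == "A"], log2(0.5 / 0.75))
  expect_equal(fc$log2FC[fc$gene == "B"], -1)
  expect_false("C" %in% fc$gene)
  expect_equal(attr(fc, "excluded"), "C")
  # unchanged marginal gives zero
  trajFlat <- new("PopulationTrajectory",
                  prevalence = rbind(c(0.5, 0.5), c(0.5, 0.5)),
                  converged = TRUE, patterns = c("1", "0"),
                  signatureGenes = "A")
  expect_equal(log2FoldChanges(trajFlat)$log2FC, 0)
})

test_that("concordance counts matching variation signs", {
  expect_equal(concordanceIndex(c(1, 2, -3), c(0.5, 4, -1)), 1)
  expect_equal(concordanceIndex(c(1, -1), c(-2, 3)), 0)
  expect_equal(concordanceIndex(c(1, 1, 1, 1, 1, -1, -1),
                                c(2, 3, 1, 5, 0.1, 4, 2)), 5 / 7)
  # zero only concordant with zero
  expect_equal(concordanceIndex(c(0, 1), c(0.0001, 1)), 0.5)
  # gene order does not matter when named
  m <- c(A = 1, B = -1); e <- c(B = -2, A = 3)
  expect_equal(concordanceIndex(m, e), 1)
})

test_that("Bland-Altman limits follow bias +/- 1.96 sd of |differences|", {
  # identical vectors: bias 0, degenerate limits
  ba <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loaLow, ba$loaHigh), c(0, 0))
  # constant |difference|: sd 0, limits collapse on the bias
  ba2 <- blandAltman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ba2$bias, 1)
  expect_equal(c(ba2$loaLow, ba2$loaHigh), c(1, 1))
  # random pairs against the direct formula
  set.seed(231)
  m <- rnorm(9); e <- rnorm(9)
  ba3 <- blandAltman(m, e)
  d <- abs(m - e)
  expect_equal(ba3$bias, mean(d))
  expect_equal(ba3$loaLow, mean(d) - 1.96 * sd(d))
  expect_equal(ba3$loaHigh, mean(d) + 1.96 * sd(d))
  expect_equal(ba3$table$outside, d < ba3$loaLow | d > ba3$loaHigh)
  # permutation invariance of the summary numbers
  p <- sample(9)
  ba4 <- blandAltman(m[p], e[p])
  expect_equal(ba4$bias, ba3$bias)
  expect_equal(ba4$loaHigh, ba3$loaHigh)
})

test_that("transformation efficiency is the drop in weighted distance", {
  # 2-state chain absorbing into the reference pattern from distance 1
  P <- matrix(c(0, 1, 0, 1), 2, byrow = TRUE)
  ch <- phenotypeDTMC(c("01", "10"), P, genes = c("A", "B"))
  ref <- c(A = 1, B = 0)
  expect_equal(transformationEfficiency(ch, 1, ref), 1)
  # absorbing start state goes nowhere
  expect_equal(transformationEfficiency(ch, 2, ref), 0)
  # efficiency never exceeds the initial distance
  set.seed(241)
  for (rep in 1:10) {
    ch2 <- randomChain(4, seed = 241 + rep)
    ref2 <- setNames(c(1, 0, 1), sprintf("m%d", 1:3))
    for (i in 1:4) {
      eff <- transformationEfficiency(ch2, i, ref2)
      init <- jaccardNeedham(
        setNames(as.integer(strsplit(phenotypePatterns(dtmcStates(ch2))[i],
                                     "")[[1]]), sprintf("m%d", 1:3)), ref2)
      expect_lte(eff, init + 1e-12)
    }
  }
})

test_that("the efficiency screen flags engineered high-efficiency states", {
  # state 1 absorbs into the reference (efficiency 1), state 3 stays put
  P <- matrix(c(0, 1, 0,
                0, 1, 0,
                0, 0, 1), 3, byrow = TRUE)
  ch <- phenotypeDTMC(c("11", "10", "01"), P, genes = c("A", "B"))
  ref <- c(A = 1, B = 0)
  sc <- screenHighEfficiency(ch, ref, threshold = 0.4)
  expect_equal(sc$stateId[sc$high], 1L)
  # threshold above every efficiency empties the flag
  expect_false(any(screenHighEfficiency(ch, ref, threshold = 2)$high))
  # constraint restricts the screened states
  scA <- screenHighEfficiency(ch, ref, requireActive = "A")
  expect_setequal(scA$stateId, c(1L, 2L))
})

test_that("single-gene couples match the published FOXO6 pairing", {
  pats <- highEfficiencyPhenotypes()
  m <- as.matrix(pats[, -(1:2)])
  couples <- findSingleGeneCouples(m, "FOXO6")
  expect_equal(nrow(couples), 4)
  expect_equal(couples$first, c("7", "13", "24", "77"))
  expect_equal(couples$second, c("248", "291", "348", "343"))
  # patterns differing at two positions are excluded
  two <- rbind(a = c(0, 0), b = c(1, 1))
  colnames(two) <- c("g", "h")
  expect_equal(nrow(findSingleGeneCouples(two, "g")), 0)
})

test_that("couple detection agrees with the all-pairs scan oracle", {
  set.seed(251)
  genes <- sprintf("x%d", 1:5)
  for (rep in 1:20) {
    m <- randomPatternMatrix(12, genes)
    g <- sample(genes, 1)
    got <- findSingleGeneCouples(m, g)
    cnt <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      diffs <- which(m[i, ] != m[j, ])
      if (length(diffs) == 1 && genes[diffs] == g) cnt <- cnt + 1
    }
    expect_equal(nrow(got), cnt)
  }
})
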