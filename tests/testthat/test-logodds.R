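## frequency table with a known joint over a few residues, built by hand
handTable <- function(p24) {
  new("FrequencyTable", probs = p24,
      marginals = submat:::extendedMarginals(p24),
      mode = "total-pairs", nGroups = 1L)
}

emptyP <- function() matrix(0, 24, 24, dimnames = list(ALPH24, ALPH24))

test_that("marginals follow the ordered-symmetric reading", {
  p <- matrix(c(.5, .2, .2, .1), 2, 2,
              dimnames = list(c("A", "C"), c("A", "C")))
  expect_equal(marginalsFromJoint(p), c(A = .6, C = .2))
  # joint concentrated on one conserved residue
  p2 <- matrix(c(1, 0, 0, 0), 2, 2,
               dimnames = list(c("A", "C"), c("A", "C")))
  expect_equal(marginalsFromJoint(p2), c(A = 1, C = 0))
})

test_that("marginals match the brute-force summation oracle", {
  set.seed(421)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    p <- matrix(runif(k * k), k, k)
    p <- p + t(p)
    dimnames(p) <- list(letters[1:k], letters[1:k])
    expect_equal(marginalsFromJoint(p), oracleMarginals(p),
                 tolerance = 1e-12)
  }
})

test_that("an independent joint scores zero everywhere with H = E = 0", {
  # build unordered p whose ordered reading is outer(m, m)
  m20 <- rep(1 / 20, 20)
  p <- emptyP()
  po <- outer(m20, m20)
  p[1:20, 1:20] <- 2 * po
  diag(p)[1:20] <- diag(po)
  f <- handTable(p)
  s <- scoreMatrix(f)
  expect_equal(max(abs(rawScores(s)[1:20, 1:20])), 0, tolerance = 1e-12)
  expect_true(all(scores(s)[1:20, 1:20] == 0))
  expect_equal(relEntropy(s), 0, tolerance = 1e-12)
  expect_equal(expScore(s), 0, tolerance = 1e-12)
})

test_that("scores follow the log-odds formula on a concentrated toy joint", {
  # mass 0.5 on conserved A, the rest uniform over the other 189 distinct
  # canonical pairs not involving conservation of A
  p <- emptyP()
  pcn <- matrix(0, 20, 20)
  fill <- upper.tri(pcn, diag = TRUE)
  fill[1, 1] <- FALSE
  pcn[fill] <- 0.5 / sum(fill)
  pcn <- pcn + t(pcn) - diag(diag(pcn))
  pcn[1, 1] <- 0.5
  p[1:20, 1:20] <- pcn
  f <- handTable(p)
  s <- scoreMatrix(f)
  marg <- marginalsFromJoint(pcn)
  expect_equal(rawScores(s)["A", "A"],
               log2(0.5) - 2 * log2(marg[[1]]), tolerance = 1e-12)
  offVal <- 0.5 / sum(fill)
  expect_equal(rawScores(s)["R", "N"],
               log2(offVal / 2) - log2(marg[[2]] * marg[[3]]),
               tolerance = 1e-12)
})

test_that("relative entropy equals an independent KL oracle", {
  set.seed(422)
  for (rep in 1:10) {
    raw <- matrix(rgamma(400, 1), 20, 20)
    raw <- raw + t(raw)
    pcn <- raw / sum(raw[upper.tri(raw, diag = TRUE)])
    p <- emptyP()
    p[1:20, 1:20] <- pcn
    f <- handTable(p)
    s <- scoreMatrix(f)
    po <- pcn / 2; diag(po) <- diag(pcn)
    marg <- marginalsFromJoint(pcn)
    expect_equal(relEntropy(s), oracleKL(po, marg), tolerance = 1e-10)
    expect_equal(relativeEntropy(f, s), relEntropy(s), tolerance = 1e-12)
    expect_gte(relEntropy(s), 0)
    # expected score by brute-force double sum; negative unless independent
    eOracle <- sum(outer(marg, marg) * (log2(po) - log2(outer(marg, marg))))
    expect_equal(expScore(s), eOracle, tolerance = 1e-10)
    expect_lt(expScore(s), 0)
    expect_equal(expectedScore(f, s), expScore(s), tolerance = 1e-12)
  }
})

test_that("integer scores round half away from zero within 0.5 of raw", {
  expect_equal(submat:::roundHalfAway(c(0.5, -0.5, 1.5, -1.5, 0.49, -2.51)),
               c(1, -1, 2, -2, 0, -3))
  cfg <- simConfig(nGroups = 15, seqsPerGroup = 6, L = 40, seed = 5)
  s <- buildSubstitutionMatrix(simulateGroups(cfg), t = 62,
                               pseudocount = 1e-6)
  expect_true(all(abs(scores(s) - rawScores(s)) <= 0.5 + 1e-12))
  expect_identical(unname(scores(s)), unname(t(scores(s))))
})

test_that("zero canonical cells are a hard error naming the pairs", {
  g <- GroupAlignment("tiny", c(a = "ACDE", b = "ACDF"))
  expect_error(buildSubstitutionMatrix(g, t = 100),
               "unobserved canonical substitution")
  # with a pseudocount the same input scores
  s <- buildSubstitutionMatrix(g, t = 100, pseudocount = 1e-6)
  expect_true(is(s, "SubstitutionMatrix"))
})

test_that("doubling all counts upstream changes nothing downstream", {
  g <- GroupAlignment("g", c(a = "ACDEFG", b = "ACDEFW", c = "MCDEFG"))
  pc <- countGroupPairs(g, clusterGroup(g, 100))
  pc2 <- new("PairCounts", groupId = "g", counts = 2 * pairCounts(pc),
             totalPairs = 2 * totalPairs(pc), nSeq = pc@nSeq)
  f1 <- accumulateFrequencies(list(groupFrequencies(pc)))
  f2 <- accumulateFrequencies(list(groupFrequencies(pc2)))
  expect_equal(pairFreqs(f1), pairFreqs(f2), tolerance = 1e-12)
})

test_that("ambiguity rows score from their own cells with averaging fallback", {
  cfg <- simConfig(nGroups = 30, seqsPerGroup = 6, L = 40,
                   ambigRate = 0.02, seed = 6)
  f <- buildFrequencyTable(simulateGroups(cfg), t = 62)
  s <- scoreMatrix(f, pseudocount = 1e-6)
  expect_false(any(is.na(scores(s))))
  marg <- marginalFreqs(f)
  expect_equal(marg[["B"]], marg[["N"]] + marg[["D"]], tolerance = 1e-12)
  expect_equal(marg[["X"]], 1, tolerance = 1e-12)
  # half-bit output doubles the integer scale but not H
  s2 <- scoreMatrix(f, pseudocount = 1e-6, halfBits = TRUE)
  expect_equal(relEntropy(s2), relEntropy(s), tolerance = 1e-12)
  expect_equal(rawScores(s2), 2 * rawScores(s), tolerance = 1e-12)
})
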