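## two superfamilies, sizes 3 and 2; hand-ordered hit list
toyHits <- function() {
  sf <- c(a1 = "SF1", a2 = "SF1", a3 = "SF1", b1 = "SF2", b2 = "SF2")
  ## ascending E-values; positions 3 and 6 are cross-superfamily errors
  hits <- data.frame(
    query  = c("a1", "a2", "a1", "a3", "b1", "b2", "a2"),
    target = c("a2", "a3", "b1", "a1", "b2", "a1", "a1"),
    evalue = c(1e-10, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 1e-3),
    stringsAsFactors = FALSE)
  list(hits = hits, sf = sf)
}

test_that("perfect retrieval gives Q = 1", {
  sf <- c(a1 = "S1", a2 = "S1", b1 = "S2", b2 = "S2")
  ## all ordered same-superfamily relations, then one FP at the tail
  hits <- data.frame(
    query  = c("a1", "a2", "b1", "b2", "a1"),
    target = c("a2", "a1", "b2", "b1", "b1"),
    evalue = c(1e-9, 1e-8, 1e-7, 1e-6, 1))
  r <- coverageAtEPQ(hits, sf, epq = 0.5)
  expect_equal(r$Q, 1)
})

test_that("the error budget truncates the E-value-ordered list", {
  x <- toyHits()
  # 5 queries at 0.01 epq: budget < 1, cut before the first FP (position 3)
  r <- coverageAtEPQ(x$hits, x$sf, epq = 0.01)
  expect_equal(r$cutoffIndex, 2L)
  expect_equal(unname(r$t), c(2, 0))
  expect_equal(r$Q, mean(c(2 / 6, 0 / 2)))
  # budget of one FP: keep through position 5, drop at the second FP
  r2 <- coverageAtEPQ(x$hits, x$sf, epq = 0.2, nQueries = 5)
  expect_equal(r2$cutoffIndex, 5L)
  expect_equal(r2$Q, mean(c(3 / 6, 1 / 2)))
})

test_that("coverage equals the exhaustive-prefix oracle on random lists", {
  set.seed(431)
  for (rep in 1:15) {
    nSf <- sample(2:4, 1)
    sizes <- sample(2:6, nSf, replace = TRUE)
    ids <- unlist(lapply(seq_len(nSf), function(i)
      paste0("f", i, "_", seq_len(sizes[i]))))
    sf <- setNames(rep(paste0("SF", seq_len(nSf)), sizes), ids)
    n <- sample(20:200, 1)
    hits <- data.frame(query = sample(ids, n, TRUE),
                       target = sample(ids, n, TRUE),
                       evalue = signif(10^runif(n, -12, 1), 3))
    hits <- hits[hits$query != hits$target, , drop = FALSE]
    if (nrow(hits) == 0L) next
    epq <- sample(c(0.01, 0.1, 0.5), 1)
    expect_equal(coverageAtEPQ(hits, sf, epq)$Q,
                 oracleCoverage(hits, sf, epq),
                 tolerance = 1e-12)
  }
})

test_that("coverage requires labels and non-trivial superfamilies", {
  x <- toyHits()
  expect_error(coverageAtEPQ(x$hits, x$sf[-1], epq = 0.01), "without superfamily")
  sfSingletons <- setNames(paste0("S", 1:5), names(x$sf))
  expect_error(coverageAtEPQ(x$hits, sfSingletons, epq = 0.01),
               "at least two sequences")
})

test_that("equal-weight bootstrap collapses to the unweighted coverage", {
  x <- toyHits()
  b <- bootstrapCoverage(x$hits, x$sf, epq = 0.25, reps = 10, seed = 1,
                         nQueries = 4, equalWeights = TRUE)
  expect_equal(b$mean, b$Q)
  expect_equal(b$variance, 0)
})

test_that("bootstrap is reproducible and consistent with unweighted Q", {
  x <- toyHits()
  b1 <- bootstrapCoverage(x$hits, x$sf, epq = 0.25, reps = 200, seed = 99,
                          nQueries = 4)
  b2 <- bootstrapCoverage(x$hits, x$sf, epq = 0.25, reps = 200, seed = 99,
                          nQueries = 4)
  expect_identical(b1, b2)
  expect_gt(b1$variance, 0)
  # law of large numbers: mean within 3 standard errors of unweighted Q
  b3 <- bootstrapCoverage(x$hits, x$sf, epq = 0.25, reps = 2000, seed = 7,
                          nQueries = 4)
  se <- sqrt(b3$variance / b3$reps)
  expect_lt(abs(b3$mean - b3$Q), max(3 * se, 0.05))
})

test_that("the Z-score follows the stated formula", {
  expect_equal(zScore(0.5, 0.1, 0.5, 0.2, 100)$Z, 0)
  z <- zScore(0.5, 0.125, 0.4, 0.125, 500)
  expect_equal(z$Z, 0.1 / sqrt(0.25 / 500), tolerance = 1e-12)
  expect_true(z$significant)
  expect_warning(zi <- zScore(0.4, 0, 0.3, 0, 500), "infinite")
  expect_identical(zi$Z, Inf)
})

test_that("q-score is 1 for identical alignments and 0 for disjoint ones", {
  ref <- GroupAlignment("r", c(x = "ACD-", y = "ACED"))
  expect_equal(qScore(ref, ref), 1)
  # same residues, but no column shared by both sequences
  disjoint <- GroupAlignment("t", c(x = "ACD-----", y = "----ACED"))
  expect_equal(qScore(disjoint, ref), 0)
  # mismatched residue content is rejected
  expect_error(
    qScore(GroupAlignment("t", c(x = "ACDW", y = "ACED")), ref),
    "residues")
})

test_that("q-score matches exhaustive pair enumeration on a 3-sequence toy", {
  ref <- GroupAlignment("r", c(a = "AC-DE", b = "ACFDE", c = "AC-DE"))
  # reference pairs: cols 1, 2, 4, 5 each pair all three sequences -> 12
  # widening b's insert column preserves every pair
  test <- GroupAlignment("t", c(a = "AC--DE", b = "AC-FDE", c = "AC--DE"))
  expect_equal(qScore(test, ref), 1)
  # shifting b out of register leaves only the 4 a-c column pairs
  test2 <- GroupAlignment("t2",
    c(a = "ACDE----", b = "---ACFDE", c = "ACDE----"))
  expect_equal(qScore(test2, ref), 4 / 12)
})

test_that("hit lists and superfamily maps read from TSV", {
  hp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query\ttarget\tevalue", "a1\ta2\t1e-9", "a1\tb1\t0.2"), hp)
  writeLines(c("id\tsuperfamily", "a1\tS1", "a2\tS1", "b1\tS2", "b2\tS2"), mp)
  x <- readHitList(hp, mp)
  expect_equal(nrow(x$hits), 2L)
  expect_equal(x$superfamilies[["b1"]], "S2")
  r <- coverageAtEPQ(x$hits, x$superfamilies, epq = 1, nQueries = 1)
  expect_true(r$Q >= 0 && r$Q <= 1)
})
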