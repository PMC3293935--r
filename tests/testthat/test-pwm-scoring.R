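test_that("boundedLog equals log2 above the junction and its tangent below", {
  for (c in c(-3, -2, -5)) {
    x0 <- exp(2 * c)
    hi <- seq(x0 * 1.001, 10, length.out = 200)
    expect_equal(boundedLog(hi, c), log2(hi))
    # tangent line at x0, finite at 0
    lo <- seq(0, x0, length.out = 50)
    expect_equal(boundedLog(lo, c),
                 2 * c * log2(exp(1)) + (lo - x0) / (x0 * log(2)))
    # continuity at the junction
    expect_equal(boundedLog(x0, c), 2 * c * log2(exp(1)), tolerance = 1e-12)
    expect_lt(abs(boundedLog(x0 + 1e-9, c) - boundedLog(x0 - 1e-9, c)),
              3e-9 / (x0 * log(2)))   # slope-scaled two-sided step
    # monotone non-decreasing on a dense grid spanning the junction
    grid <- boundedLog(seq(0, 5, length.out = 2000), c)
    expect_true(all(diff(grid) >= 0))
  }
  expect_equal(boundedLog(1, -3), 0)
  expect_equal(boundedLog(0, -3), -7 / log(2))   # about -10.10
  expect_error(boundedLog(-0.1), "x >= 0")
})

test_that("MotifMatrix validates and normalizes counts without pseudocounts", {
  counts <- matrix(c(8, 0, 0, 0,
                     0, 4, 4, 0), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- MotifMatrix(counts, id = "T1")
  expect_equal(colSums(motifProbs(m)), c(1, 1))
  expect_equal(unname(motifProbs(m)["A", 1]), 1)       # no pseudocount smoothing
  mp <- MotifMatrix(counts, id = "T1", pseudocount = 1)
  expect_equal(unname(motifProbs(mp)["A", 1]), 9 / 12)
  expect_error(MotifMatrix(counts[1:3, ], id = "bad"), "4 rows")
})

test_that("lodScore hits ymax at consensus, ymin at anti-consensus", {
  m <- fixtureMotif()
  lom <- buildLogOddsMatrix(m)
  cons <- consensusSeq(m)
  anti <- paste(c("A", "C", "G", "T")[apply(motifProbs(m), 2, which.min)],
                collapse = "")
  expect_equal(lodScore(cons, lom), lomMax(lom))
  expect_equal(lodScore(anti, lom), lomMin(lom))
  expect_equal(nlodScore(cons, lom), 1)
  expect_equal(nlodScore(anti, lom), 0)
  expect_error(lodScore("ACGT", lom), "length")
  expect_true(is.na(lodScore(paste0("N", substr(cons, 2, 12)), lom)))
})

test_that("a uniform-column matrix scores 0 everywhere and is uninformative", {
  u <- MotifMatrix(matrix(0.25, 4, 2,
                          dimnames = list(c("A", "C", "G", "T"), NULL)),
                   id = "UNI")
  lom <- buildLogOddsMatrix(u)
  for (s in c("AA", "CG", "TT")) expect_equal(lodScore(s, lom), 0)
  expect_error(nlodScore("AC", lom), "uninformative")
})

test_that("NLOD stays in [0,1] over random matrices and sequences", {
  set.seed(42)
  for (trial in 1:20) {
    L <- sample(6:14, 1)
    probs <- matrix(rexp(4 * L), 4, dimnames = list(c("A", "C", "G", "T"),
                                                    NULL))
    m <- MotifMatrix(probs, id = "R")
    bg <- rexp(4); bg <- bg / sum(bg)
    lom <- buildLogOddsMatrix(m, bg)
    for (r in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      nl <- nlodScore(s, lom)
      expect_gte(nl, 0); expect_lte(nl, 1)
    }
  }
})

test_that("calibrateZ is seed-reproducible and matches exhaustive moments", {
  m <- fixtureMotif()
  lom <- buildLogOddsMatrix(m)
  g <- simulateReference(10000, seed = 21)
  cal1 <- calibrateZ(lom, g, nSamples = 20000, seed = 9)
  cal2 <- calibrateZ(lom, g, nSamples = 20000, seed = 9)
  expect_identical(cal1@mu, cal2@mu)
  expect_identical(cal1@sigma, cal2@sigma)
  # population moments from every window of both strands
  s <- as.character(g)[[1]]
  L <- motifLength(m)
  nl <- c(vapply(seq_len(nchar(s) - L + 1), function(i)
            nlodScore(substr(s, i, i + L - 1), lom), numeric(1)),
          vapply(seq_len(nchar(s) - L + 1), function(i)
            nlodScore(revcompChar(substr(s, i, i + L - 1)), lom),
            numeric(1)))
  se <- sd(nl) / sqrt(cal1@nSamples)
  expect_lt(abs(cal1@mu - mean(nl)), 3 * se)
  expect_lt(abs(cal1@sigma - sd(nl)), 0.01)
  expect_error(calibrateZ(lom, g, nSamples = 100, seed = 1), ">= 1000")
})

test_that("a planted consensus scores far above background for a strong motif", {
  m <- fixtureMotif()
  lom <- buildLogOddsMatrix(m)
  g <- simulateReference(20000, seed = 33)
  cal <- calibrateZ(lom, g, nSamples = 100000, seed = 4)
  expect_gt(zScore(1, cal), 4)
})

test_that("z standardization and the normal-quantile pair are exact", {
  cal <- new("ZCalibration", matrixId = "x", mu = 0.6, sigma = 0.05,
             nSamples = 1000L, seed = 1L)
  expect_equal(zScore(0.6, cal), 0)
  expect_equal(zScore(0.65, cal), 1)
  expect_equal(zScore(0.85, cal), 5)
  expect_equal(pValueForZ(0), 0.5)
  ps <- c(1e-6, 1e-5, 1e-4, 0.005, 0.05, 0.5, 0.9)
  expect_equal(pValueForZ(zThresholdForP(ps)), ps, tolerance = 1e-9)
  expect_error(zThresholdForP(0), "in \\(0, 1\\)")
})

test_that("JASPAR, TRANSFAC and TSV readers round-trip matrices", {
  jaspar <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001 TFA",
               "A [ 8 0 2 ]",
               "C [ 0 8 2 ]",
               "G [ 0 0 2 ]",
               "T [ 0 0 2 ]",
               ">MA0002 TFB",
               "4 0", "0 4", "4 0", "0 4"), jaspar)
  ms <- readJASPAR(jaspar)
  expect_named(ms, c("MA0001", "MA0002"))
  expect_equal(motifProbs(ms$MA0001)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(motifProbs(ms$MA0001)[, 3], c(A = .25, C = .25, G = .25,
                                             T = .25))
  expect_equal(tfName(ms$MA0002), "TFB")

  transfac <- tempfile(fileext = ".dat")
  writeLines(c("AC M00001", "ID M00001", "NA TFC",
               "P0      A      C      G      T",
               "01      8      0      0      0",
               "02      0      0      8      0",
               "//"), transfac)
  mt <- readTRANSFAC(transfac)
  expect_equal(unname(motifProbs(mt$M00001)["G", 2]), 1)
  expect_equal(tfName(mt$M00001), "TFC")

  tsv <- tempfile(fileext = ".tsv")
  writeMatrixTSV(c(ms, mt), tsv)
  back <- readMatrixTSV(tsv)
  expect_equal(length(back), 3L)
  expect_equal(motifProbs(back$MA0001), motifProbs(ms$MA0001))
})
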