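test_that("the seed is guide positions 2-8", {
  expect_equal(seedOf("UACGGAUCAAU"), "ACGGAUC")
  expect_equal(seedOf("UACGGAUC"), "ACGGAUC")  # 8-mer guide
  expect_error(seedOf("UACGGAU"), "at least 8")
})

test_that("SM classification is exact reverse-complement matching", {
  ## seed ACGGAUC -> DNA target GATCCGT
  expect_true(classifySM("AAGATCCGTAA", "ACGGAUC"))
  expect_false(classifySM("AAGATCCGAAA", "ACGGAUC"))  # 1 mismatch
  expect_false(classifySM("", "ACGGAUC"))
  ## U/T re-encoding changes nothing on either side
  utrs <- c("AAGATCCGTAA", "GGGGGGG", "TTTGATCCGT")
  expect_equal(classifySM(utrs, "ACGGAUC"),
               classifySM(chartr("T", "U", utrs), "ACGGATC"))
  expect_error(classifySM("ACGT", "ACGGA"), "7 nt")
})

test_that("QC filtering applies all six flags and the id pattern", {
  rec <- data.frame(transcript_id = sprintf("NM_%03d", 1:10),
                    ControlType = 0L, gIsPosAndSignif = 1L,
                    gIsFeatNonUnifOL = 0L, gIsWellAboveBG = 1L,
                    gIsSaturated = 0L, gIsFeatPopnOL = 0L)
  expect_equal(nrow(qcFilter(rec)), 10L)
  rec$gIsSaturated[2] <- 1L
  rec$gIsWellAboveBG[5] <- 0L
  rec$ControlType[9] <- 1L
  expect_equal(nrow(qcFilter(rec)), 7L)
  rec$transcript_id[1] <- "XR_001"   # non-mRNA systematic name
  expect_equal(nrow(qcFilter(rec)), 6L)
  expect_error(qcFilter(rec[, -3]), "gIsPosAndSignif")
})

test_that("quantile normalisation forces a common distribution", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  q <- quantileNormalize(m)
  expect_equal(unname(q[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, "b"]), c(2.5, 3.5, 4.5))
  set.seed(8)
  big <- matrix(rlnorm(600), ncol = 3)
  qb <- quantileNormalize(big)
  ## sorted columns identical, ranks preserved, idempotent
  expect_equal(sort(qb[, 1]), sort(qb[, 2]))
  expect_equal(unname(colMeans(qb)), rep(mean(colMeans(qb)), 3))
  expect_equal(order(qb[, 2]), order(big[, 2]))
  expect_equal(quantileNormalize(qb), qb, tolerance = 1e-12)
  expect_error(quantileNormalize(cbind(c(1, -2), c(3, 4))), "positive")
})

test_that("the group shift statistic matches its construction", {
  ## treated == mock: zero difference, all M zero
  m <- cbind(mock = c(10, 20, 30, 40), treated = c(10, 20, 30, 40))
  rownames(m) <- paste0("t", 1:4)
  r <- offtargetMagnitude(m, c(TRUE, TRUE, FALSE, FALSE),
                          "treated", "mock")
  expect_equal(r@difference, 0)
  expect_true(all(r@ma$M == 0))
  ## a uniform -1 log2 shift of the SM group is recovered exactly
  sm <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  mock <- c(8, 16, 32, 64, 128)
  treated <- mock * ifelse(sm, 0.5, 1)
  m2 <- cbind(mock = mock, treated = treated)
  r2 <- offtargetMagnitude(m2, sm, "treated", "mock")
  expect_equal(r2@difference, -1)
  expect_equal(r2@meanL2fcNonSM, 0)
  expect_equal(r2@nSM, 2L)
  ## invariant under transcript reordering
  perm <- c(3, 1, 5, 2, 4)
  r3 <- offtargetMagnitude(m2[perm, ], sm[perm], "treated", "mock")
  expect_equal(r3@difference, r2@difference)
  expect_equal(r3@pWilcoxon, r2@pWilcoxon)
  expect_error(offtargetMagnitude(m2, rep(TRUE, 5), "treated", "mock"),
               "non-seed-matched")
})

test_that("small-sample Wilcoxon p equals exact enumeration", {
  for (seed in 1:5) {
    set.seed(seed)
    M <- rnorm(10)
    sm <- rep(c(TRUE, FALSE), each = 5)
    mat <- cbind(mock = rep(1, 10), treated = 2^M)
    rownames(mat) <- paste0("t", 1:10)
    r <- offtargetMagnitude(mat, sm, "treated", "mock")
    expect_equal(r@pWilcoxon, wilcoxExactOracle(M[sm], M[!sm]),
                 tolerance = 1e-12)
  }
})

test_that("cumulative and MA tables are coherent", {
  sim <- simulateExpression(nTranscripts = 300, effectL2fc = -1,
                            utrLength = 60, seed = 5)
  r <- offtargetMagnitude(quantileNormalize(sim$matrix), sim$smTruth,
                          "treated", "mock")
  expect_equal(nrow(r@ma), 300L)
  cs <- r@cumulative[r@cumulative$group == "SM", ]
  expect_equal(nrow(cs), r@nSM)
  expect_false(is.unsorted(cs$l2fc))
  expect_equal(cs$fraction[nrow(cs)], 1)
})

test_that("the expression generator plants a recoverable truth", {
  sim <- simulateExpression(nTranscripts = 500, smFraction = 0.1,
                            effectL2fc = -1, noiseSd = 0.25,
                            utrLength = 120, seed = 17)
  ## sequence-based classification reproduces the planted flags exactly
  called <- classifySM(sim$utr3, sim$seed7)
  expect_equal(called, sim$smTruth)
  ## QC flags all pass and ids match the systematic-name pattern
  expect_equal(nrow(qcFilter(sim$flags)), 500L)
  ## effect recovery through the full pipeline
  r <- offtargetMagnitude(quantileNormalize(sim$matrix), called,
                          "treated", "mock")
  se <- sqrt(2) * 0.25 * sqrt(1 / r@nSM + 1 / r@nNonSM)
  expect_lt(abs(r@difference - (-1)), 3 * se)
  ## null effect gives a null-consistent difference
  null <- simulateExpression(nTranscripts = 500, effectL2fc = 0,
                             makeUtrs = FALSE, seed = 18)
  r0 <- offtargetMagnitude(null$matrix, null$smTruth, "treated", "mock")
  expect_lt(abs(r0@difference), 3 * se)
  expect_gt(r0@pWilcoxon, 0.001)
})
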