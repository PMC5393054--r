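test_that("Fisher's exact test reproduces hand-enumerated tables", {
  # full enumeration of margins (4,4) in an 8-item universe
  r <- fisherExact(c(3, 1, 1, 3))
  expect_equal(r@pValue, 34 / 70, tolerance = 1e-12)
  expect_equal(r@log2OddsRatio, log2(9))
  expect_false(r@correctionApplied)
  # symmetric table
  r <- fisherExact(c(5, 5, 5, 5))
  expect_equal(r@pValue, 1)
  expect_equal(r@log2OddsRatio, 0)
  # zero cell -> Haldane-Anscombe correction on the OR
  r <- fisherExact(c(10, 0, 5, 5))
  expect_true(r@correctionApplied)
  expect_equal(2^r@log2OddsRatio, (10.5 * 5.5) / (0.5 * 5.5))
  # zero margin is undefined
  expect_error(fisherExact(c(0, 0, 3, 4)),
               class = "polycre_undefined_test")
})

test_that("Fisher p-values agree with stats::fisher.test", {
  set.seed(2)
  for (i in 1:50) {
    tab <- matrix(sample.int(30, 4, replace = TRUE), 2, 2)
    expect_equal(fisherExact(tab)@pValue,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("exact Mann-Whitney matches brute-force enumeration", {
  # non-overlapping samples: U = 0, both extreme tails have mass 0.05
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1)
  # identical multisets -> p = 1 by symmetry
  r <- mannWhitneyU(c(1, 2, 2), c(1, 2, 2), mode = "exact")
  expect_equal(r$p.value, 1)
  # interleaved samples against the oracle
  r <- mannWhitneyU(c(1, 3, 5, 7), c(2, 4, 6, 8), mode = "exact")
  expect_equal(r$U, 6)
  expect_equal(r$p.value, mwuOracleP(c(1, 3, 5, 7), c(2, 4, 6, 8)))
  # randomized cases incl. ties, n + m <= 12
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample.int(6, n, replace = TRUE)
    y <- sample.int(6, m, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    expect_equal(mannWhitneyU(x, y, mode = "exact")$p.value,
                 mwuOracleP(x, y))
  }
  # degenerate data
  expect_warning(r <- mannWhitneyU(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(r$p.value, 1)
})

test_that("U + U' = n*m and normal mode tracks exact mode", {
  set.seed(4)
  diffs <- replicate(100, {
    x <- rnorm(10); y <- rnorm(10)
    u <- mannWhitneyU(x, y, mode = "normal")$U
    uPrime <- mannWhitneyU(y, x, mode = "normal")$U
    expect_equal(u + uPrime, 100)
    NULL
  })
  # |exact - normal| <= 0.01 without ties at n = m = 10; the full exact
  # enumeration at C(20,10) is heavy, so check on n = m = 5 exactly and
  # n = m = 10 against wilcox.test's corrected normal approximation
  for (i in 1:100) {
    x <- rnorm(5); y <- rnorm(5)
    pe <- mannWhitneyU(x, y, mode = "exact")$p.value
    pn <- mannWhitneyU(x, y, mode = "normal")$p.value
    expect_lte(abs(pe - pn), 0.06)
  }
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    pn <- mannWhitneyU(x, y, mode = "normal")$p.value
    pw <- suppressWarnings(stats::wilcox.test(
      x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(pn, pw, tolerance = 1e-9)
    pe <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    expect_lte(abs(pn - pe), 0.01)
  }
})

test_that("matched background preserves length, chromosome and distance
           decile", {
  set.seed(12)
  genes <- mkGenes("chr1", seq(50000L, 950000L, 50000L),
                   seq(56000L, 956000L, 50000L), rep("+", 19))
  widths <- sample(300:900, 15)
  starts <- seq(52000L, 900000L, length.out = 15)
  peaks <- gr0("chr1", as.integer(starts), as.integer(starts) + widths)
  bg <- sampleMatchedBackground(peaks, c(chr1 = 1000000L), genes,
                                nPerPeak = 5L, seed = 3)
  expect_equal(length(bg), 15L * 5L)
  # exact length and chromosome matching
  expect_equal(GenomicRanges::width(bg),
               rep(GenomicRanges::width(peaks), each = 5L))
  # never overlaps an input peak
  expect_equal(sum(IRanges::overlapsAny(bg, peaks)), 0L)
  # TSS distances fall in the source peak's decile
  d <- distanceToTss(peaks, genes)$tss_distance
  edges <- quantile(d, probs = seq(0, 1, 0.1), names = FALSE)
  dec <- findInterval(d, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  dBg <- distanceToTss(bg, genes)$tss_distance
  for (i in seq_along(peaks)) {
    dI <- dBg[bg$source_peak == i]
    expect_true(all(dI >= edges[dec[i]] - 1e-9 &
                    dI <= edges[dec[i] + 1L] + 1e-9))
  }
  # determinism under the seed
  bg2 <- sampleMatchedBackground(peaks, c(chr1 = 1000000L), genes,
                                 nPerPeak = 5L, seed = 3)
  expect_identical(GenomicRanges::start(bg), GenomicRanges::start(bg2))
})

test_that("overlap enrichment recovers a planted odds ratio", {
  # features planted on query blocks at rate 0.5 and on background
  # blocks at rate 0.05; the analytic odds ratio of the planting rates
  # is (0.5/0.5) / (0.05/0.95) = 19
  set.seed(21)
  B <- 2000L
  nb <- 5000L
  units <- sample.int(nb, 400L)
  qb <- units[1:200]; bb <- units[201:400]
  hasF <- c(runif(200) < 0.5, runif(200) < 0.05)
  fb <- c(qb, bb)[hasF]
  blockIv <- function(blocks) gr0("chr1", (blocks - 1L) * B,
                                  blocks * B)
  unitIv <- function(blocks) gr0("chr1", (blocks - 1L) * B + 900L,
                                 (blocks - 1L) * B + 1100L)
  r <- overlapEnrichment(unitIv(qb), blockIv(fb), unitIv(bb))
  expect_lte(abs(r@log2OddsRatio - log2(19)), 0.5)
  expect_lt(r@pValue, 1e-10)
  # query fully inside features, background fully outside
  r <- overlapEnrichment(unitIv(qb[1:5]), blockIv(qb[1:5]),
                         unitIv(bb[1:5]))
  expect_true(r@correctionApplied)
  expect_lt(r@pValue, 0.05)
})
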