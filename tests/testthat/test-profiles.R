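test_that("meta-profiles rebin exactly and flag chromosome edges", {
  # constant track -> every entry c, flat mean curve
  tr <- mkTrack(rep(3, 400), binWidth = 25L)
  mp <- buildMetaProfile(gr0("chr1", 4000L, 4400L), tr,
                         windowHalfwidth = 1000L, binWidth = 100L)
  expect_equal(dim(profileMatrix(mp)), c(1L, 20L))
  expect_true(all(profileMatrix(mp) == 3))
  expect_true(all(summaryCurve(mp) == 3))
  # triangular signal peaked at the midpoint -> symmetric, max at center
  L <- 10000L
  mid <- 5000L
  vals <- pmax(0, 1 - abs(seq(12.5, L, 25) - mid) / 2000)
  tr <- mkTrack(vals, binWidth = 25L)
  mp <- buildMetaProfile(gr0("chr1", mid - 200L, mid + 200L), tr,
                         windowHalfwidth = 1000L, binWidth = 100L)
  curve <- summaryCurve(mp)
  peakBins <- which(curve == max(curve))
  expect_true(all(abs(peakBins - 10.5) <= 1))
  expect_equal(curve[1:9], rev(curve[12:20]), tolerance = 1e-9)
  # region at the chromosome start: left columns NA, not zero
  mp <- buildMetaProfile(gr0("chr1", 100L, 300L), tr,
                         windowHalfwidth = 1000L, binWidth = 100L)
  expect_true(all(is.na(profileMatrix(mp)[1, 1:8])))
  expect_false(anyNA(profileMatrix(mp)[1, 9:20]))
  # summary curve equals column means of the matrix
  regions <- gr0("chr1", c(3000L, 5000L, 7000L), c(3400L, 5400L, 7400L))
  mp <- buildMetaProfile(regions, tr, 1000L, 100L)
  expect_equal(summaryCurve(mp),
               colMeans(profileMatrix(mp), na.rm = TRUE))
  expect_error(buildMetaProfile(regions[0], tr, 1000L, 100L),
               class = "polycre_validation_error")
})

test_that("bootstrap bands are deterministic, degenerate-safe and
           cover the mean", {
  mkProfile <- function(mat) new("MetaProfile", matrix = mat,
                                 windowHalfwidth = ncol(mat) * 50L,
                                 binWidth = 100L,
                                 summary = colMeans(mat),
                                 ciLower = numeric(0),
                                 ciUpper = numeric(0), label = "t")
  # identical rows -> zero-width CI
  mat <- matrix(2, nrow = 10, ncol = 6)
  ci <- confidenceBands(bootstrapMeanCi(mkProfile(mat), nBoot = 100,
                                        seed = 1))
  expect_true(all(ci$lower == 2 & ci$upper == 2))
  # same seed -> identical bands
  set.seed(8)
  mat <- matrix(rnorm(600, 5), nrow = 100)
  b1 <- bootstrapMeanCi(mkProfile(mat), nBoot = 200, seed = 7)
  b2 <- bootstrapMeanCi(mkProfile(mat), nBoot = 200, seed = 7)
  expect_identical(confidenceBands(b1), confidenceBands(b2))
  # single row warns and degenerates to the point value
  expect_warning(b <- bootstrapMeanCi(mkProfile(mat[1, , drop = FALSE])),
                 "single")
  expect_equal(confidenceBands(b)$lower, summaryCurve(b))
  # nominal coverage: N(5, 1) rows, n = 200 -> 95% CI covers 5 in >= 90%
  # of 100 repeats
  set.seed(33)
  covered <- vapply(1:100, function(i) {
    mat <- matrix(rnorm(200 * 5, mean = 5), nrow = 200)
    ci <- confidenceBands(bootstrapMeanCi(mkProfile(mat), nBoot = 200,
                                          seed = i))
    mean(ci$lower <= 5 & ci$upper >= 5)
  }, numeric(1))
  expect_gte(mean(covered), 0.9)
})

test_that("NDR detection follows the dip-ratio rule", {
  mkCurve <- function(center, flank, n = 21) {
    cv <- rep(flank, n); cv[11] <- center; cv
  }
  r <- detectNdr(mkCurve(1, 4), binWidth = 100L)
  expect_true(r$called)
  expect_equal(r$depth, 0.75)
  # flat curve: no dip
  r <- detectNdr(rep(2, 21), binWidth = 100L)
  expect_false(r$called)
  expect_equal(r$depth, 0)
  # zero flanks are not callable
  r <- detectNdr(rep(0, 21), binWidth = 100L)
  expect_false(r$callable)
  # curve must span the flank window
  expect_error(detectNdr(rep(1, 5), binWidth = 100L),
               class = "polycre_validation_error")
})

test_that("promoter classifier separates planted focused and broad
           states and ignores input order", {
  cfg <- smallConfig(seed = 3L)
  g <- generateGenome(cfg)
  ls <- plantRegulatoryLandscape(g, cfg)
  sig <- synthesizeSignalTracks(g, ls, cfg)
  k27 <- subtractTracks(sig$tracks$H3K27me3, sig$tracks$H3)
  tr <- ls$truth
  cobound <- tr$peaks[tr$peaks$factor == "both", ]
  promRows <- tr$promoters$peak_index
  proms <- gr0(cobound$chrom[promRows], cobound$start0[promRows],
               cobound$end0[promRows])
  cl <- classifyPromoters(proms, k27, seed = 2)
  expect_gte(mean(cl$calls$label == tr$promoters$label), 0.95)
  # permutation invariance of the labels
  perm <- sample(length(proms))
  cl2 <- classifyPromoters(proms[perm], k27, seed = 2)
  expect_equal(cl2$calls$label, cl$calls$label[perm])
  # the broad class is well separated from the focused class on the
  # broad-window level (the exact noiseless 3x amplitude ratio is
  # checked on the raw H3K27me3 track in the generator tests; the
  # H3-subtracted track used here shifts both levels down by ~1)
  featB <- cl$calls$level_broad[tr$promoters$label == "broad"]
  featF <- cl$calls$level_broad[tr$promoters$label == "focused"]
  expect_gt(min(featB), 2 * max(featF))
  expect_error(classifyPromoters(proms[1], k27),
               class = "polycre_validation_error")
})

test_that("element-class comparison flags planted chromatin differences", {
  cfg <- smallConfig(seed = 4L)
  g <- generateGenome(cfg)
  ls <- plantRegulatoryLandscape(g, cfg)
  sig <- synthesizeSignalTracks(g, ls, cfg)
  enh <- ls$truth$enhancers
  bound <- gr0(enh$chrom[enh$phorc_bound], enh$start0[enh$phorc_bound],
               enh$end0[enh$phorc_bound])
  tf <- enh$activity == "tf_bound"
  unbound <- gr0(enh$chrom[tf], enh$start0[tf], enh$end0[tf])
  cmp <- compareElementClasses(
    bound, unbound,
    list(H3K27me3 = subtractTracks(sig$tracks$H3K27me3, sig$tracks$H3),
         H3K27ac = sig$tracks$H3K27ac),
    seed = 5)
  # bound elements high K27me3, TF-bound high K27ac
  expect_lt(cmp$H3K27me3$test$p.value, 0.01)
  expect_lt(cmp$H3K27ac$test$p.value, 0.01)
  bc <- summaryCurve(cmp$H3K27me3$boundProfile)
  uc <- summaryCurve(cmp$H3K27me3$unboundProfile)
  expect_gt(mean(bc), mean(uc))
  ci <- confidenceBands(cmp$H3K27me3$boundProfile)
  expect_true(all(ci$lower <= summaryCurve(cmp$H3K27me3$boundProfile) +
                    1e-9))
  expect_error(compareElementClasses(bound[0], unbound, list()),
               class = "polycre_validation_error")
})
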