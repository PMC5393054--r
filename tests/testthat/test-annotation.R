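test_that("TSS distances are midpoint-based, signed and tie-broken", {
  genes <- mkGenes("chr1", 1000L, 3000L, "+")
  # peak [1400, 1600): midpoint 1500, unsigned 500, signed +500
  d <- distanceToTss(gr0("chr1", 1400L, 1600L), genes)
  expect_equal(d$tss_distance, 500L)
  expect_equal(d$tss_signed, 500L)
  # midpoint exactly at the TSS
  d <- distanceToTss(gr0("chr1", 950L, 1050L), genes)
  expect_equal(d$tss_distance, 0L)
  # nearest of two TSSs: 900 and 2200 around midpoint 1500
  genes2 <- mkGenes("chr1", c(900L, 2200L), c(1900L, 3100L),
                    c("+", "+"), ids = c("gB", "gA"))
  d <- distanceToTss(gr0("chr1", 1400L, 1600L), genes2)
  expect_equal(d$tss_distance, 600L)
  expect_equal(d$nearest_gene, "gB")
  # upstream of a minus-strand gene is negative
  gm <- mkGenes("chr1", 1000L, 3000L, "-")
  d <- distanceToTss(gr0("chr1", 3400L, 3600L), gm)  # beyond the TSS
  expect_equal(d$tss_signed, -501L)
  # equidistant tie breaks to the lexicographically smaller id
  g3 <- mkGenes("chr1", c(1000L, 2000L), c(1900L, 2900L), c("+", "+"),
                ids = c("gZ", "gA"))
  d <- distanceToTss(gr0("chr1", 1450L, 1550L), g3)
  expect_equal(d$nearest_gene, "gA")
  # no gene on the chromosome -> unannotatable
  d <- distanceToTss(gr0("chr9", 0L, 100L), genes)
  expect_false(d$annotatable)
})

test_that("categorisation is exclusive with promoter-first precedence", {
  genes <- mkGenes("chr1", c(1000L, 50000L), c(9000L, 60000L),
                   c("+", "+"))
  enhChar <- gr0("chr1", 1100L, 1500L)
  enhChip <- gr0("chr1", 20000L, 22000L)
  peaks <- gr0("chr1",
               c(1200L, 20500L, 30000L, 52000L),
               c(1400L, 21500L, 30400L, 52400L))
  ann <- annotatePeaks(peaks, genes, enhChar, enhChip)
  # 300 bp from TSS AND inside a characterized enhancer -> promoter wins
  expect_equal(as.character(ann$category),
               c("promoter", "enhancer_chip", "intergenic", "intragenic"))
  # 501 bp from TSS inside a gene body, no enhancer -> intragenic
  p <- gr0("chr1", 1451L, 1551L)  # midpoint 1501 -> distance 501
  ann <- annotatePeaks(p, genes, gr0("chr1", 0L, 10L), gr0("chr1", 0L, 10L))
  expect_equal(as.character(ann$category), "intragenic")
  # boundary: exactly 500 is still a promoter (inclusive rule)
  p <- gr0("chr1", 1450L, 1550L)
  ann <- annotatePeaks(p, genes, gr0("chr1", 0L, 10L), gr0("chr1", 0L, 10L))
  expect_equal(as.character(ann$category), "promoter")
})

test_that("category assignment ignores catalog file order", {
  set.seed(5)
  genes <- mkGenes("chr1", seq(10000L, 90000L, 20000L),
                   seq(15000L, 95000L, 20000L), rep("+", 5))
  enhChar <- gr0("chr1", c(2000L, 42000L), c(4000L, 44000L))
  enhChip <- gr0("chr1", c(6000L, 82000L), c(8000L, 84000L))
  peaks <- gr0("chr1", seq(1000L, 96000L, 5000L),
               seq(1400L, 96400L, 5000L))
  a1 <- annotatePeaks(peaks, genes, enhChar, enhChip)
  a2 <- annotatePeaks(peaks, genes, rev(enhChar), rev(enhChip))
  expect_equal(as.character(a1$category), as.character(a2$category))
})

test_that("category summaries count exhaustively and sum to ~100%", {
  genes <- mkGenes("chr1", 1000L, 9000L, "+")
  peaks <- gr0("chr1", c(900L, 30000L, 31000L), c(1100L, 30400L, 31400L))
  ann <- annotatePeaks(peaks, genes, gr0("chr1", 0L, 1L),
                       gr0("chr1", 0L, 1L))
  s <- categorySummary(ann)
  expect_equal(sum(s$count), length(peaks))
  expect_lte(abs(sum(s$percent) - 100), 0.3)
  # all peaks in one category
  ann1 <- annotatePeaks(gr0("chr1", 900L, 1100L), genes,
                        gr0("chr1", 0L, 1L), gr0("chr1", 0L, 1L))
  s1 <- categorySummary(ann1)
  expect_equal(s1$percent[s1$category == "promoter"], 100)
  expect_error(categorySummary(ann1[0]),
               class = "polycre_validation_error")
})

test_that("TSS-distance histograms bin correctly and medians are exact", {
  h <- tssDistanceHistogram(c(0, 100, 2000), c(0, 500, 5000))
  expect_equal(h$counts, c(2L, 1L))
  expect_equal(sum(h$counts), h$n)
  expect_equal(tssDistanceHistogram(42, c(0, 100))$median, 42)
  expect_equal(tssDistanceHistogram(c(97, 97, 1890), c(0, 1e5))$median, 97)
  expect_error(tssDistanceHistogram(1, c(10, 10)),
               class = "polycre_validation_error")
})
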