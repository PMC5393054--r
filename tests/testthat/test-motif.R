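test_that("PWM scanning matches the brute-force window oracle", {
  # near-point-mass motif on GCCAT over a uniform background
  pm <- matrix(0, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  pm[cbind(match(strsplit("GCCAT", "")[[1]], rownames(pm)), 1:5)] <- 1
  motif <- MotifModel(pm)
  p <- (1 + 0.01 * 0.25) / (1 + 0.01)  # post-pseudocount match prob
  hits <- scanPwm("AAGCCATAA", motif, scoreThreshold = 4)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 3L)  # 1-based window start
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, 5 * log2(4 * p), tolerance = 1e-9)
  # reverse complement of the sequence gives a minus-strand hit with the
  # identical score
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("AAGCCATAA")))
  hitsR <- scanPwm(rc, motif, scoreThreshold = 4)
  expect_equal(hitsR$strand, "-")
  expect_equal(hitsR$score, hits$score)
  # windows containing N are skipped; unattainable threshold -> no hits
  expect_equal(nrow(scanPwm("AANCCATAA", motif, 0)), 0L)
  expect_equal(nrow(scanPwm("AAGCCATAA", motif, 100)), 0L)
  # random sequences against the oracle
  set.seed(14)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    got <- scanPwm(s, motif, scoreThreshold = -20)
    want <- scanOracle(s, motif, -20)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("motif reverse-complement scanning is consistent", {
  set.seed(3)
  pm <- matrix(runif(32) + 0.1, 4, 8,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  motif <- MotifModel(sweep(pm, 2, colSums(pm), "/"),
                      background = c(0.3, 0.2, 0.2, 0.3))
  s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  rcMotif <- reverseComplementMotif(motif)
  rcSeq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  h1 <- scanPwm(s, motif, -50)
  h2 <- scanPwm(rcSeq, rcMotif, -50)
  # a hit at position p maps to position n - w + 2 - p with the SAME
  # strand: reverse-complementing both sequence and motif turns a
  # forward match into a forward match of the flipped pair
  map <- data.frame(position = 50 - 8 + 2 - h1$position,
                    strand = h1$strand,
                    score = h1$score)
  map <- map[order(map$position, map$strand), ]
  expect_equal(h2$position, map$position)
  expect_equal(h2$strand, map$strand)
  expect_equal(h2$score, map$score, tolerance = 1e-9)
})

test_that("ZOOPS-EM discovery recovers a planted motif and is
           deterministic", {
  seqs <- randomSequences(50, 200, plant = "GCCATTGT", seed = 101)
  d <- discoverMotif(seqs, width = 8, seed = 2)
  cons <- motifConsensus(d$motif)
  expect_gte(consensusMatchCount(cons, "GCCATTGT"), 6)
  # positions aligned to the planted consensus reach high per-position
  # confidence (the model may be registered +/- 1 position, leaving at
  # most two background-like flank columns)
  maxProb <- apply(motifMatrix(d$motif), 2, max)
  expect_gte(sum(maxProb >= 0.8), 6)
  # determinism under seed
  d2 <- discoverMotif(seqs, width = 8, seed = 2)
  expect_identical(motifMatrix(d2$motif), motifMatrix(d$motif))
  # validation errors
  expect_error(discoverMotif(seqs[1:5]), class = "polycre_validation_error")
  expect_error(discoverMotif(c(seqs[1:9], "ACGT")),
               class = "polycre_validation_error")
})

test_that("motif enrichment contrasts planted and empty sets", {
  fg <- randomSequences(30, 120, plant = "GCCATTGT", seed = 55)
  bg <- randomSequences(30, 120, seed = 56)
  pm <- matrix(0, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  pm[cbind(match(strsplit("GCCATTGT", "")[[1]], rownames(pm)), 1:8)] <- 1
  motif <- MotifModel(pm)
  r <- motifEnrichment(fg, bg, motif, scoreThreshold = 14)
  expect_equal(r$fgFraction, 1)
  expect_lte(r$bgFraction, 0.1)
  expect_lt(r$enrichment@pValue, 1e-6)
  # identical sets with mixed hit status -> OR 1, p 1
  mixed <- c(fg, bg)
  r <- motifEnrichment(mixed, mixed, motif, scoreThreshold = 14)
  expect_equal(r$enrichment@log2OddsRatio, 0)
  expect_equal(r$enrichment@pValue, 1)
  # unattainable threshold -> degenerate zero-margin table, no test
  r <- motifEnrichment(fg, bg, motif, scoreThreshold = 1000)
  expect_equal(r$fgFraction, 0)
  expect_null(r$enrichment)
})

test_that("MEME-minimal output round-trips the probability matrix", {
  seqs <- randomSequences(12, 60, plant = "GCCATTGT", seed = 77)
  d <- discoverMotif(seqs, width = 8, seed = 1)
  path <- tempfile(fileext = ".meme")
  writeMemeMotif(d$motif, path, name = "pho")
  lines <- readLines(path)
  expect_true(any(grepl("^MOTIF pho", lines)))
  matLines <- lines[(grep("letter-probability", lines) + 1):length(lines)]
  mat <- do.call(cbind, lapply(strsplit(trimws(matLines), "\\s+"),
                               as.numeric))
  expect_equal(unname(mat), unname(motifMatrix(d$motif)),
               tolerance = 1e-5)
})
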