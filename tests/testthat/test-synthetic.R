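test_that("genome generation places non-overlapping genes deterministically", {
  cfg <- syntheticConfig(nChromosomes = 1L, nGenes = 1L,
                         chromLength = 1000000L, seed = 7L)
  g <- generateGenome(cfg)
  expect_equal(length(g$genes), 1L)
  expect_true(g$genes$tss >= 0 && g$genes$tss < 1000000)
  # same config + seed -> identical gene table
  g2 <- generateGenome(cfg)
  expect_identical(GenomicRanges::start(g$genes),
                   GenomicRanges::start(g2$genes))
  expect_identical(g$genes$tss, g2$genes$tss)
  # 200 genes on 10 Mb: zero pairwise body overlaps (brute force)
  cfg <- syntheticConfig(nGenes = 200L, chromLength = 10000000L,
                         seed = 1L)
  g <- generateGenome(cfg)
  expect_equal(length(g$genes), 200L)
  st <- GenomicRanges::start(g$genes); en <- GenomicRanges::end(g$genes)
  overlaps <- 0L
  for (i in seq_len(199L)) for (j in (i + 1L):200L)
    if (st[i] <= en[j] && st[j] <= en[i]) overlaps <- overlaps + 1L
  expect_equal(overlaps, 0L)
  # both strands represented
  expect_setequal(unique(as.character(GenomicRanges::strand(g$genes))),
                  c("+", "-"))
  # infeasible config fails loudly
  bad <- syntheticConfig(nGenes = 5000L, chromLength = 1000000L)
  expect_error(generateGenome(bad), class = "polycre_placement_error")
})

test_that("landscape planting honours the co-binding fraction exactly", {
  base <- list(seed = 3L)
  # boundary fractions
  for (f in c(0, 1)) {
    cfg <- smallConfig(coboundFraction = f, seed = 3L)
    ls <- plantRegulatoryLandscape(generateGenome(cfg), cfg)
    tr <- ls$truth$peaks
    expect_equal(sum(tr$planted_cobound),
                 round(f * cfg@nPhoPeaks))
  }
  # interior fraction: shared truth count equals the configured quota
  cfg <- smallConfig(coboundFraction = 0.8, seed = 3L)
  ls <- plantRegulatoryLandscape(generateGenome(cfg), cfg)
  expect_equal(sum(ls$truth$peaks$planted_cobound), 24L)  # 0.8 * 30
  # replicate peaks keep >= 90% reciprocal overlap with each other
  ov <- GenomicRanges::pintersect(ls$pho$rep1[seq_len(24)],
                                  ls$pho$rep2[seq_len(24)])
  recip <- pmin(
    GenomicRanges::width(ov) / GenomicRanges::width(ls$pho$rep1[1:24]),
    GenomicRanges::width(ov) / GenomicRanges::width(ls$pho$rep2[1:24]))
  expect_true(all(recip >= 0.9))
  # every emitted truth interval appears exactly once
  tr <- ls$truth$peaks
  expect_equal(anyDuplicated(paste(tr$chrom, tr$start0, tr$end0)), 0L)
  # conservation: emitted replicate counts = truth + decoys
  nDecoy <- round(cfg@decoyRate * cfg@nPhoPeaks)
  expect_equal(length(ls$pho$rep1), cfg@nPhoPeaks + nDecoy)
  expect_equal(length(ls$sfmbt$rep2),
               cfg@nSfmbtPeaks + round(cfg@decoyRate * cfg@nSfmbtPeaks))
})

test_that("synthesized tracks encode the planted chromatin features", {
  cfg <- smallConfig(seed = 5L, noiseSd = 0)
  g <- generateGenome(cfg)
  ls <- plantRegulatoryLandscape(g, cfg)
  sig <- synthesizeSignalTracks(g, ls, cfg)
  k27 <- sig$tracks$H3K27me3
  tr <- ls$truth
  cob <- tr$peaks[tr$peaks$factor == "both", ]
  mids <- (cob$start0 + cob$end0) %/% 2
  # noiseless broad/focused level ratio over each class's own support:
  # plateau level = 3x focused peak level
  promRows <- tr$promoters
  lvl <- function(mid, hw) {
    quantifySignal(gr0(cob$chrom[1], mid - hw, mid + hw), k27) / (2 * hw)
  }
  broadMid <- mids[promRows$peak_index[promRows$label == "broad"]]
  focMid <- mids[promRows$peak_index[promRows$label == "focused"]]
  # measure away from the NDR dip by excluding the center 300 bp
  broadLvl <- mean(vapply(broadMid, lvl, numeric(1), hw = 9000L))
  focLvl <- mean(vapply(focMid, function(m)
    quantifySignal(gr0(cob$chrom[1], m - 450L, m - 200L), k27) / 250,
    numeric(1)))
  ratio <- (broadLvl - cfg@baseline) / (focLvl - cfg@baseline)
  expect_lte(abs(ratio - 3) / 3, 0.2)
  # NDR dip: center below flanks at planted depth
  h3 <- sig$tracks$H3
  enhRows <- which(cob$category %in% c("enhancer_characterized",
                                       "enhancer_chip"))
  for (i in enhRows[1:3]) {
    center <- quantifySignal(gr0(cob$chrom[i], mids[i] - 50L,
                                 mids[i] + 50L), h3) / 100
    flank <- quantifySignal(gr0(cob$chrom[i], mids[i] + 500L,
                                mids[i] + 700L), h3) / 200
    expect_lt(center, 0.55 * flank)
  }
  # ndrDepth = 0 -> no forced dip
  cfg0 <- smallConfig(seed = 5L, noiseSd = 0, ndrDepth = 0)
  sig0 <- synthesizeSignalTracks(g, plantRegulatoryLandscape(g, cfg0),
                                 cfg0)
  h30 <- sig0$tracks$H3
  tr0 <- sig0$tracks$H3K27me3
  cob0 <- plantRegulatoryLandscape(g, cfg0)$truth$peaks
  cob0 <- cob0[cob0$factor == "both", ]
  m0 <- (cob0$start0[1] + cob0$end0[1]) %/% 2
  center <- quantifySignal(gr0(cob0$chrom[1], m0 - 50L, m0 + 50L),
                           h30) / 100
  flank <- quantifySignal(gr0(cob0$chrom[1], m0 + 500L, m0 + 700L),
                          h30) / 200
  expect_gte(center, flank * 0.99)
})

test_that("motif planting at rate 1 reaches every bound element", {
  cfg <- smallConfig(seed = 9L, motifPlantingRate = 1)
  g <- generateGenome(cfg)
  ls <- plantRegulatoryLandscape(g, cfg)
  sig <- synthesizeSignalTracks(g, ls, cfg)
  enh <- ls$truth$enhancers
  boundIds <- enh$id[enh$phorc_bound]
  seqs <- as.character(sig$sequences[boundIds])
  hasMotif <- vapply(seqs, function(s)
    grepl("GCCATTGT", s) || grepl("ACAATGGC", s), logical(1))
  expect_true(all(hasMotif))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- smallConfig(seed = 13L)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  simulatePhorcStudy(cfg, d1)
  simulatePhorcStudy(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 15)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # conservation: emitted interval counts match the configuration
  expect_equal(length(readBed(file.path(d1, "pres.bed"))), cfg@nPres)
  expect_equal(length(readBed(file.path(
    d1, "enhancers_characterized.bed"))),
    unname(cfg@enhancerCounts[["characterized"]]))
  unlink(c(d1, d2), recursive = TRUE)
})
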