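# Synthetic regulatory landscape with planted ground truth.  The
# generator emulates the processed products of a PhoRC BiTS-ChIP study:
# two-replicate peak sets per factor with a controllable co-binding
# fraction, enhancer catalogs in two tiers, focused vs broad H3K27me3
# promoter domains, nucleosome-depleted regions at bound elements,
# motif-embedded element sequences, and class-structured expression
# counts.

#' Synthetic study configuration
#'
#' All sizes in bp.  The defaults are the package's reference study
#' conditions (see the vignette): one 10-Mb chromosome, 200 genes, 100
#' Pho and 200 dSfmbt peaks with an 0.8 co-binding fraction, 46.6%
#' repressed (broad-H3K27me3) promoters, and a GCCAT-core motif planted
#' in 80% of bound-element sequences.
#'
#' @param nChromosomes number of chromosomes
#' @param chromLength length of each chromosome (bp)
#' @param nGenes total number of genes
#' @param nPhoPeaks,nSfmbtPeaks true peak counts per factor
#' @param coboundFraction fraction of Pho peaks co-bound by dSfmbt
#' @param fracRepressedPromoters fraction of PhoRC-bound promoters
#'   carrying a broad (repressed) H3K27me3 domain
#' @param categoryProps genomic category mix of co-bound peaks
#'   (promoter, characterized enhancer, ChIP enhancer, intergenic,
#'   intragenic)
#' @param enhancerCounts named counts of the two enhancer tiers
#' @param nPres,nPresBound size of the reference PRE catalog and how
#'   many of its elements coincide with co-bound regions
#' @param peakWidthMean,peakWidthSd,peakWidthRange peak width model
#' @param jitter uniform end jitter (bp) between factors and replicates
#' @param decoyRate replicate-specific decoy peaks per true peak
#' @param broadDomainHalfwidth,focusedHalfwidth H3K27me3 domain
#'   half-widths for the broad and focused promoter classes
#' @param broadLevelMultiplier broad domain level relative to the
#'   focused peak level
#' @param focusedLevel focused H3K27me3 peak amplitude (signal units)
#' @param ndrDepth relative depth of the nucleosome-depleted dip at
#'   bound elements (0 disables it)
#' @param ndrHalfwidth dip half-width (bp)
#' @param motifConsensus planted DNA consensus
#' @param motifPlantingRate fraction of bound-element sequences with a
#'   planted motif
#' @param expressionClassMedians named RPKM medians per gene class
#' @param noiseSd standard deviation of the additive Gaussian noise on
#'   log-signal
#' @param baseline additive signal floor before noise
#' @param binWidth signal track bin width (bp)
#' @param seed master RNG seed
#' @return a \linkS4class{SyntheticConfig}
#' @export
syntheticConfig <- function(nChromosomes = 1L,
                            chromLength = 10000000L,
                            nGenes = 200L,
                            nPhoPeaks = 100L,
                            nSfmbtPeaks = 200L,
                            coboundFraction = 0.8,
                            fracRepressedPromoters = 0.466,
                            categoryProps = c(promoter = 0.47,
                                              enhancer_characterized = 0.052,
                                              enhancer_chip = 0.174,
                                              intergenic = 0.162,
                                              intragenic = 0.142),
                            enhancerCounts = c(characterized = 40L,
                                               chip_defined = 80L),
                            nPres = 30L,
                            nPresBound = 28L,
                            peakWidthMean = 1400,
                            peakWidthSd = 200,
                            peakWidthRange = c(1000, 2000),
                            jitter = 25L,
                            decoyRate = 0.1,
                            broadDomainHalfwidth = 10000L,
                            focusedHalfwidth = 500L,
                            broadLevelMultiplier = 3,
                            focusedLevel = 2,
                            ndrDepth = 0.6,
                            ndrHalfwidth = 150L,
                            motifConsensus = "GCCATTGT",
                            motifPlantingRate = 0.8,
                            expressionClassMedians = c(
                              ubiquitous = 60, meso = 40, non_meso = 2,
                              phorc_repressed_promoter = 1.5,
                              phorc_dev_enhancer = 2,
                              tf_bound_enhancer = 25,
                              nonbound_enhancer = 8),
                            noiseSd = 0.2,
                            baseline = 0.05,
                            binWidth = 25L,
                            seed = 1L) {
  new("SyntheticConfig",
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength),
      nGenes = as.integer(nGenes),
      nPhoPeaks = as.integer(nPhoPeaks),
      nSfmbtPeaks = as.integer(nSfmbtPeaks),
      coboundFraction = coboundFraction,
      fracRepressedPromoters = fracRepressedPromoters,
      categoryProps = categoryProps,
      enhancerCounts = setNames(as.integer(enhancerCounts),
                                names(enhancerCounts)),
      nPres = as.integer(nPres),
      nPresBound = as.integer(nPresBound),
      peakWidthMean = peakWidthMean,
      peakWidthSd = peakWidthSd,
      peakWidthRange = peakWidthRange,
      jitter = as.integer(jitter),
      decoyRate = decoyRate,
      broadDomainHalfwidth = as.integer(broadDomainHalfwidth),
      focusedHalfwidth = as.integer(focusedHalfwidth),
      broadLevelMultiplier = broadLevelMultiplier,
      focusedLevel = focusedLevel,
      ndrDepth = ndrDepth,
      ndrHalfwidth = as.integer(ndrHalfwidth),
      motifConsensus = motifConsensus,
      motifPlantingRate = motifPlantingRate,
      expressionClassMedians = expressionClassMedians,
      noiseSd = noiseSd,
      baseline = baseline,
      binWidth = as.integer(binWidth),
      seed = as.integer(seed))
}

GENOME_EDGE_MARGIN <- 60000L
GENE_MIN_GAP <- 3000L

#' Generate a toy genome with non-overlapping gene models
#'
#' Genes get log-normal lengths (clipped to 2-20 kb), are placed left to
#' right with randomized gaps of at least 3 kb, keep a 60-kb margin from
#' chromosome ends (so meta-profile windows never truncate), and carry a
#' random strand with both strands guaranteed whenever there are at
#' least two genes.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param seed RNG seed (defaults to the config seed)
#' @return list with \code{genes} (GRanges with gene_id, tss) and
#'   \code{chromSizes}
#' @export
generateGenome <- function(config, seed = config@seed) {
  chroms <- sprintf("chrS%d", seq_len(config@nChromosomes))
  chromSizes <- setNames(rep(config@chromLength, length(chroms)), chroms)
  perChrom <- apportion(config@nGenes, rep(1, length(chroms)))
  withSeed(seed, {
    parts <- lapply(seq_along(chroms), function(ci) {
      n <- perChrom[ci]
      if (n == 0) return(NULL)
      L <- config@chromLength
      len <- pmin(pmax(round(rlnorm(n, log(6000), 0.35)), 2000L), 20000L)
      avail <- L - 2L * GENOME_EDGE_MARGIN - sum(len)
      extra <- avail - (n + 1L) * GENE_MIN_GAP
      if (extra < 0)
        polycreStop("polycre_placement_error",
                    "cannot place %d genes on a %d-bp chromosome", n, L)
      gw <- runif(n + 1L)
      gaps <- GENE_MIN_GAP + floor(extra * gw / sum(gw))
      starts0 <- GENOME_EDGE_MARGIN +
        cumsum(gaps)[seq_len(n)] + c(0L, cumsum(len)[-n])
      strand <- sample(c("+", "-"), n, replace = TRUE)
      if (n >= 2 && length(unique(strand)) == 1L)
        strand[n] <- setdiff(c("+", "-"), strand[1])
      data.frame(chrom = chroms[ci], start0 = starts0,
                 end0 = starts0 + len, strand = strand)
    })
    df <- do.call(rbind, parts)
    genes <- granges0(df$chrom, df$start0, df$end0, strand = df$strand,
                      seqlengths = chromSizes)
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(df)))
    genes$tss <- tss0(genes)
    list(genes = genes, chromSizes = chromSizes)
  })
}

# --- placement registry -------------------------------------------------

newRegistry <- function(chroms) {
  env <- new.env(parent = emptyenv())
  for (chrom in chroms) assign(chrom, IRanges::IRanges(), envir = env)
  env
}

regFree <- function(reg, chrom, start0, end0, gap = 0L) {
  occ <- get(chrom, envir = reg)
  if (!length(occ)) return(TRUE)
  cand <- IRanges::IRanges(start0 + 1L - gap, end0 + gap)
  IRanges::countOverlaps(cand, occ) == 0
}

regAdd <- function(reg, chrom, start0, end0) {
  occ <- get(chrom, envir = reg)
  assign(chrom, c(occ, IRanges::IRanges(start0 + 1L, end0)), envir = reg)
}

# draw a truncated-normal peak width
drawWidth <- function(config, n = 1L) {
  pmin(pmax(round(rnorm(n, config@peakWidthMean, config@peakWidthSd)),
            config@peakWidthRange[1]), config@peakWidthRange[2])
}

# jitter both ends by uniform integers in [-j, j]
jitterEnds <- function(df, j) {
  n <- nrow(df)
  data.frame(chrom = df$chrom,
             start0 = df$start0 + sample(seq(-j, j), n, replace = TRUE),
             end0 = df$end0 + sample(seq(-j, j), n, replace = TRUE))
}

df2granges <- function(df, chromSizes, ...) {
  granges0(df$chrom, df$start0, df$end0, seqlengths = chromSizes, ...)
}

#' Plant peaks, enhancer catalogs and a PRE catalog with ground truth
#'
#' Co-bound base intervals are planted across the five genomic
#' categories according to \code{categoryProps} (exact largest-remainder
#' quotas); each base interval yields a Pho and a dSfmbt truth interval
#' (end jitter +/- jitter bp) and each truth interval two replicate
#' intervals (again jittered, keeping >= 90\% reciprocal overlap at the
#' configured widths).  Factor-only peaks and replicate-specific decoys
#' are placed in free space.  Enhancer elements that receive a co-bound
#' peak are flagged bound; bound elements get motif-planting flags at
#' \code{motifPlantingRate}, and a PRE catalog is planted with
#' \code{nPresBound} of its elements on co-bound regions.
#'
#' @param genome output of \code{\link{generateGenome}}
#' @param config a \linkS4class{SyntheticConfig}
#' @param seed RNG seed (defaults to config seed + 1)
#' @return list with replicate peak sets, enhancer catalogs, the PRE
#'   catalog, and a \code{truth} list of data.frames
#' @export
plantRegulatoryLandscape <- function(genome, config,
                                     seed = config@seed + 1L) {
  genes <- genome$genes
  chromSizes <- genome$chromSizes
  chroms <- names(chromSizes)
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  tssByChrom <- split(genes$tss, gchrom)
  L <- config@chromLength
  minTssDist <- function(chrom, pos) {
    t <- tssByChrom[[chrom]]
    if (is.null(t)) Inf else min(abs(pos - t))
  }
  nCob <- round(config@coboundFraction * config@nPhoPeaks)
  if (nCob > config@nSfmbtPeaks)
    polycreStop("polycre_placement_error",
                "coboundFraction requires more dSfmbt peaks than configured")
  quota <- apportion(nCob, config@categoryProps)
  names(quota) <- names(config@categoryProps)
  if (quota[["enhancer_characterized"]] >
      config@enhancerCounts[["characterized"]] ||
      quota[["enhancer_chip"]] > config@enhancerCounts[["chip_defined"]])
    polycreStop("polycre_placement_error",
                "enhancer-category quota exceeds enhancer catalog size")
  withSeed(seed, {
    reg <- newRegistry(chroms)
    tries <- function(what, maxTries, fn) {
      for (k in seq_len(maxTries)) {
        out <- fn()
        if (!is.null(out)) return(out)
      }
      polycreStop("polycre_placement_error", "cannot place %s", what)
    }
    randChrom <- function() sample(chroms, 1L)
    # -- enhancer catalogs (placed first; >= 1.5 kb clear of any TSS) --
    placeEnhancer <- function(id, tier) {
      tries(paste("enhancer", id), 2000L, function() {
        chrom <- randChrom()
        w <- round(runif(1, 1500, 3000))
        s0 <- round(runif(1, GENOME_EDGE_MARGIN,
                          L - GENOME_EDGE_MARGIN - w))
        if (minTssDist(chrom, s0) < 1500 ||
            minTssDist(chrom, s0 + w) < 1500) return(NULL)
        if (!regFree(reg, chrom, s0, s0 + w, gap = 1000L)) return(NULL)
        regAdd(reg, chrom, s0, s0 + w)
        data.frame(id = id, tier = tier, chrom = chrom, start0 = s0,
                   end0 = s0 + w)
      })
    }
    nChar <- config@enhancerCounts[["characterized"]]
    nChip <- config@enhancerCounts[["chip_defined"]]
    enh <- rbind(
      do.call(rbind, lapply(seq_len(nChar), function(i)
        placeEnhancer(sprintf("enhC%03d", i), "characterized"))),
      do.call(rbind, lapply(seq_len(nChip), function(i)
        placeEnhancer(sprintf("enhT%03d", i), "chip_defined"))))
    # -- co-bound base intervals, category by category --
    peakRows <- list()
    boundEnhIdx <- integer(0)
    # enhancer categories first: midpoint inside a sampled catalog
    # element (their broad H3K27me3 domains constrain where promoter
    # peaks may go, so they are planted before promoters)
    for (tier in c("characterized", "chip_defined")) {
      catName <- if (tier == "characterized") "enhancer_characterized"
                 else "enhancer_chip"
      nq <- quota[[catName]]
      if (nq == 0) next
      cand <- which(enh$tier == tier)
      sel <- resample(cand, nq)
      boundEnhIdx <- c(boundEnhIdx, sel)
      for (ei in sel) {
        row <- tries("enhancer peak", 500L, function() {
          w <- drawWidth(config)
          center <- (enh$start0[ei] + enh$end0[ei]) %/% 2L
          mid <- center + sample(seq(-200L, 200L), 1L)
          s0 <- mid - w %/% 2L
          if (s0 < 0 || s0 + w > L) return(NULL)
          # enhancer elements are already registered; require freedom
          # from everything except the host element
          occ <- get(enh$chrom[ei], envir = reg)
          candR <- IRanges::IRanges(s0 + 1L - 300L, s0 + w + 300L)
          hits <- IRanges::findOverlaps(candR, occ)
          host <- IRanges::IRanges(enh$start0[ei] + 1L, enh$end0[ei])
          other <- occ[S4Vectors::subjectHits(hits)]
          clash <- any(IRanges::start(other) != IRanges::start(host) |
                       IRanges::end(other) != IRanges::end(host))
          if (clash) return(NULL)
          regAdd(reg, enh$chrom[ei], s0, s0 + w)
          data.frame(chrom = enh$chrom[ei], start0 = s0, end0 = s0 + w,
                     category = catName, host_gene = NA_character_,
                     enhancer_id = enh$id[ei])
        })
        peakRows[[length(peakRows) + 1L]] <- row
      }
    }
    # promoters: midpoint within 500 bp of a sampled gene's TSS.  Hosts
    # are kept >= 21 kb from each other and from bound-enhancer peak
    # centers so each promoter's H3K27me3 state reflects only its own
    # planted label (broad domains span +/- 10 kb).
    promGenes <- integer(0)
    if (quota[["promoter"]] > 0) {
      enhPeakRows <- do.call(rbind, peakRows)
      domainMids <- if (!is.null(enhPeakRows))
        split((enhPeakRows$start0 + enhPeakRows$end0) %/% 2L,
              enhPeakRows$chrom) else list()
      minSep <- 2L * config@broadDomainHalfwidth + 1000L
      chosenTss <- list()
      for (gi in resample(seq_along(genes))) {
        if (length(promGenes) >= quota[["promoter"]]) break
        chrom <- gchrom[gi]
        t <- genes$tss[gi]
        if (length(domainMids[[chrom]]) &&
            min(abs(t - domainMids[[chrom]])) < minSep) next
        if (length(chosenTss[[chrom]]) &&
            min(abs(t - chosenTss[[chrom]])) < minSep) next
        promGenes <- c(promGenes, gi)
        chosenTss[[chrom]] <- c(chosenTss[[chrom]], t)
      }
      if (length(promGenes) < quota[["promoter"]])
        polycreStop("polycre_placement_error",
                    "cannot select %d well-separated promoter hosts",
                    quota[["promoter"]])
      for (gi in promGenes) {
        chrom <- gchrom[gi]
        row <- tries("promoter peak", 500L, function() {
          w <- drawWidth(config)
          mid <- genes$tss[gi] + sample(seq(-350L, 350L), 1L)
          s0 <- mid - w %/% 2L
          if (s0 < 0 || s0 + w > L) return(NULL)
          if (!regFree(reg, chrom, s0, s0 + w, gap = 300L)) return(NULL)
          regAdd(reg, chrom, s0, s0 + w)
          data.frame(chrom = chrom, start0 = s0, end0 = s0 + w,
                     category = "promoter", host_gene = genes$gene_id[gi],
                     enhancer_id = NA_character_)
        })
        peakRows[[length(peakRows) + 1L]] <- row
      }
    }
    # intergenic / intragenic / factor-only / decoy placement
    geneIR <- split(IRanges::IRanges(GenomicRanges::start(genes),
                                     GenomicRanges::end(genes)), gchrom)
    placeFree <- function(category, wantInGene) {
      tries(category, 4000L, function() {
        chrom <- randChrom()
        w <- drawWidth(config)
        s0 <- round(runif(1, GENOME_EDGE_MARGIN,
                          L - GENOME_EDGE_MARGIN - w))
        mid <- s0 + w %/% 2L
        if (minTssDist(chrom, mid) < 1500) return(NULL)
        gi <- geneIR[[chrom]]
        inGene <- !is.null(gi) &&
          any(IRanges::start(gi) <= mid + 1L & IRanges::end(gi) >= mid + 1L)
        if (!is.na(wantInGene) && inGene != wantInGene) return(NULL)
        if (!regFree(reg, chrom, s0, s0 + w, gap = 300L)) return(NULL)
        regAdd(reg, chrom, s0, s0 + w)
        data.frame(chrom = chrom, start0 = s0, end0 = s0 + w,
                   category = category, host_gene = NA_character_,
                   enhancer_id = NA_character_)
      })
    }
    for (i in seq_len(quota[["intergenic"]]))
      peakRows[[length(peakRows) + 1L]] <- placeFree("intergenic", FALSE)
    for (i in seq_len(quota[["intragenic"]]))
      peakRows[[length(peakRows) + 1L]] <- placeFree("intragenic", TRUE)
    cobound <- if (length(peakRows)) do.call(rbind, peakRows) else
      data.frame(chrom = character(0), start0 = integer(0),
                 end0 = integer(0), category = character(0),
                 host_gene = character(0), enhancer_id = character(0))
    nPhoOnly <- config@nPhoPeaks - nCob
    nSfOnly <- config@nSfmbtPeaks - nCob
    phoOnlyDf <- do.call(rbind, lapply(seq_len(nPhoOnly), function(i)
      placeFree("factor_only", NA)[, 1:3]))
    sfOnlyDf <- do.call(rbind, lapply(seq_len(nSfOnly), function(i)
      placeFree("factor_only", NA)[, 1:3]))
    emptyDf <- data.frame(chrom = character(0), start0 = integer(0),
                          end0 = integer(0))
    if (is.null(phoOnlyDf)) phoOnlyDf <- emptyDf
    if (is.null(sfOnlyDf)) sfOnlyDf <- emptyDf
    j <- config@jitter
    cobBase <- cobound[, c("chrom", "start0", "end0")]
    phoTruth <- rbind(jitterEnds(cobBase, j), phoOnlyDf)
    sfTruth <- rbind(jitterEnds(cobBase, j), sfOnlyDf)
    mkReps <- function(truthDf, factorLabel) {
      nDecoy <- round(config@decoyRate * nrow(truthDf))
      decoys <- lapply(seq_len(2L * nDecoy), function(i)
        placeFree("decoy", NA)[, 1:3])
      rep1 <- rbind(jitterEnds(truthDf, j),
                    if (nDecoy) do.call(rbind, decoys[seq_len(nDecoy)])
                    else NULL)
      rep2 <- rbind(jitterEnds(truthDf, j),
                    if (nDecoy) do.call(rbind,
                                        decoys[nDecoy + seq_len(nDecoy)])
                    else NULL)
      list(rep1 = rep1, rep2 = rep2)
    }
    phoReps <- mkReps(phoTruth, "pho")
    sfReps <- mkReps(sfTruth, "sfmbt")
    # -- PRE catalog: nPresBound on co-bound bases, the rest free --
    nOnPeaks <- min(config@nPresBound, nrow(cobBase))
    preRows <- list()
    if (nOnPeaks > 0) {
      sel <- sample(seq_len(nrow(cobBase)), nOnPeaks)
      for (i in sel)
        preRows[[length(preRows) + 1L]] <- data.frame(
          chrom = cobBase$chrom[i],
          start0 = pmax(0L, cobBase$start0[i] - 100L),
          end0 = cobBase$end0[i] + 100L)
    }
    for (i in seq_len(config@nPres - nOnPeaks))
      preRows[[length(preRows) + 1L]] <- placeFree("pre", NA)[, 1:3]
    pres <- do.call(rbind, preRows)
    # -- enhancer truth: bound flags, motif planting, activity --
    enh$phorc_bound <- seq_len(nrow(enh)) %in% boundEnhIdx
    enh$motif_planted <- FALSE
    bIdx <- which(enh$phorc_bound)
    nPlant <- round(config@motifPlantingRate * length(bIdx))
    if (nPlant > 0)
      enh$motif_planted[resample(bIdx, nPlant)] <- TRUE
    enh$activity <- "phorc_bound"
    ubIdx <- which(!enh$phorc_bound)
    ubShuffled <- resample(ubIdx)
    half <- length(ubIdx) %/% 2L
    enh$activity[ubShuffled[seq_len(half)]] <- "tf_bound"
    enh$activity[ubShuffled[setdiff(seq_along(ubIdx), seq_len(half))]] <-
      "inactive"
    # -- promoter truth: broad (repressed) vs focused labels --
    promoterTruth <- if (length(promGenes)) {
      nBroad <- round(config@fracRepressedPromoters * length(promGenes))
      lab <- rep("focused", length(promGenes))
      if (nBroad > 0) lab[sample(length(promGenes), nBroad)] <- "broad"
      data.frame(gene_id = genes$gene_id[promGenes], label = lab,
                 peak_index = which(cobound$category == "promoter"))
    } else data.frame(gene_id = character(0), label = character(0),
                      peak_index = integer(0))
    # -- expression truth: class per gene --
    exprClass <- rep(NA_character_, length(genes))
    names(exprClass) <- genes$gene_id
    enhGr <- df2granges(enh, chromSizes)
    nearest <- assignRegionsToGenes(enhGr, genes)
    for (k in seq_len(nrow(enh))) {
      g <- nearest$gene_id[k]
      if (is.na(g)) next
      cls <- switch(enh$activity[k],
                    phorc_bound = "phorc_dev_enhancer",
                    tf_bound = "tf_bound_enhancer",
                    inactive = "nonbound_enhancer")
      cur <- exprClass[[g]]
      rank <- c(phorc_dev_enhancer = 1, tf_bound_enhancer = 2,
                nonbound_enhancer = 3)
      if (is.na(cur) || rank[[cls]] < rank[[cur]])
        exprClass[[g]] <- cls
    }
    # promoter evidence is direct: the repressed-promoter label wins
    broadGenes <- promoterTruth$gene_id[promoterTruth$label == "broad"]
    exprClass[broadGenes] <- "phorc_repressed_promoter"
    rest <- which(is.na(exprClass))
    refLabels <- rep(c("ubiquitous", "meso", "non_meso"),
                     length.out = length(rest))
    exprClass[rest[sample(length(rest))]] <- refLabels
    expressionTruth <- data.frame(gene_id = genes$gene_id,
                                  class = unname(exprClass[genes$gene_id]))
    peaksTruth <- rbind(
      if (nrow(cobound)) data.frame(
        chrom = cobound$chrom, start0 = cobound$start0,
        end0 = cobound$end0, factor = "both", planted_cobound = TRUE,
        category = cobound$category, host_gene = cobound$host_gene,
        enhancer_id = cobound$enhancer_id) else NULL,
      if (nrow(phoOnlyDf)) data.frame(
        chrom = phoOnlyDf$chrom, start0 = phoOnlyDf$start0,
        end0 = phoOnlyDf$end0, factor = "pho", planted_cobound = FALSE,
        category = NA_character_, host_gene = NA_character_,
        enhancer_id = NA_character_) else NULL,
      if (nrow(sfOnlyDf)) data.frame(
        chrom = sfOnlyDf$chrom, start0 = sfOnlyDf$start0,
        end0 = sfOnlyDf$end0, factor = "sfmbt", planted_cobound = FALSE,
        category = NA_character_, host_gene = NA_character_,
        enhancer_id = NA_character_) else NULL)
    list(
      pho = list(rep1 = df2granges(phoReps$rep1, chromSizes),
                 rep2 = df2granges(phoReps$rep2, chromSizes)),
      sfmbt = list(rep1 = df2granges(sfReps$rep1, chromSizes),
                   rep2 = df2granges(sfReps$rep2, chromSizes)),
      enhancers = enh,
      enhChar = df2granges(enh[enh$tier == "characterized", ], chromSizes,
                           name = enh$id[enh$tier == "characterized"]),
      enhChip = df2granges(enh[enh$tier == "chip_defined", ], chromSizes,
                           name = enh$id[enh$tier == "chip_defined"]),
      pres = df2granges(pres, chromSizes),
      truth = list(peaks = peaksTruth,
                   promoters = promoterTruth,
                   enhancers = enh,
                   expression = expressionTruth))
  })
}

# add `level` per-bp over 0-based [a, b) to a binned vector (fractional
# bins proportional)
addRect <- function(v, bw, a, b, level) {
  if (b <= a) return(v)
  i0 <- floor(a / bw); i1 <- ceiling(b / bw) - 1
  idx <- i0:i1
  binStarts <- idx * bw
  ov <- pmin(b, binStarts + bw) - pmax(a, binStarts)
  keep <- idx + 1 <= length(v)
  v[idx[keep] + 1] <- v[idx[keep] + 1] + level * ov[keep] / bw
  v
}

# multiply bins over [a, b) by factor (whole bins whose center is inside)
mulRect <- function(v, bw, a, b, factor) {
  i0 <- max(0, floor(a / bw)); i1 <- min(length(v) - 1, ceiling(b / bw) - 1)
  if (i1 < i0) return(v)
  v[(i0:i1) + 1] <- v[(i0:i1) + 1] * factor
  v
}

#' Synthesize signal tracks, element sequences and expression counts
#'
#' H3K27me3: focused promoters get a rectangular peak of
#' \code{focusedLevel} over +/- focusedHalfwidth of the TSS; broad
#' (repressed) promoters and PhoRC-bound enhancers get a plateau of
#' \code{broadLevelMultiplier x focusedLevel} over
#' +/- broadDomainHalfwidth of the bound peak midpoint.  H3 is flat at 1
#' and, like H3K27me3, carries a multiplicative nucleosome-depleted dip
#' of relative depth \code{ndrDepth} over +/- ndrHalfwidth at every
#' co-bound peak midpoint.  H3K27ac marks TF-bound (PhoRC-nonbound)
#' enhancers, H3K4me1 all enhancers, input is flat.  All tracks then get
#' a \code{baseline} floor and multiplicative log-normal noise
#' (additive Gaussian on log-signal, sd \code{noiseSd}).
#'
#' Element sequences are i.i.d. uniform ACGT with the motif consensus
#' embedded once (random position and strand) in flagged bound
#' elements.  Expression counts are drawn per gene around the class
#' median RPKM (log-normal, sd 0.4) and scaled to a 2M-read library.
#'
#' @param genome output of \code{\link{generateGenome}}
#' @param landscape output of \code{\link{plantRegulatoryLandscape}}
#' @param config a \linkS4class{SyntheticConfig}
#' @param seed RNG seed (defaults to config seed + 2)
#' @return list with \code{tracks} (named SignalTracks), \code{sequences}
#'   (DNAStringSet named by enhancer id), \code{expression} (data.frame
#'   gene_id, count, length), \code{librarySize}
#' @export
synthesizeSignalTracks <- function(genome, landscape, config,
                                   seed = config@seed + 2L) {
  chromSizes <- genome$chromSizes
  bw <- config@binWidth
  genes <- genome$genes
  truth <- landscape$truth
  enh <- landscape$enhancers
  h <- config@focusedLevel
  hBroad <- config@broadLevelMultiplier * h
  W <- config@broadDomainHalfwidth
  wF <- config@focusedHalfwidth
  zero <- lapply(chromSizes, function(L) numeric(ceiling(L / bw)))
  k27me3 <- zero; k27ac <- zero; k4me1 <- zero
  h3 <- lapply(chromSizes, function(L) rep(1, ceiling(L / bw)))
  input <- lapply(chromSizes, function(L) rep(0.5, ceiling(L / bw)))
  cob <- truth$peaks[truth$peaks$factor == "both", , drop = FALSE]
  cobMid <- (cob$start0 + cob$end0) %/% 2
  # promoter H3K27me3 domains, centered on the bound peak midpoint
  prom <- truth$promoters
  if (nrow(prom)) {
    for (r in seq_len(nrow(prom))) {
      pk <- prom$peak_index[r]
      chrom <- cob$chrom[pk]
      mid <- cobMid[pk]
      if (prom$label[r] == "broad")
        k27me3[[chrom]] <- addRect(k27me3[[chrom]], bw, mid - W, mid + W,
                                   hBroad)
      else
        k27me3[[chrom]] <- addRect(k27me3[[chrom]], bw, mid - wF,
                                   mid + wF, h)
    }
  }
  # bound enhancers: broad repressive domain around the bound peak
  enhPeak <- which(cob$category %in% c("enhancer_characterized",
                                       "enhancer_chip"))
  for (pk in enhPeak) {
    chrom <- cob$chrom[pk]
    mid <- cobMid[pk]
    k27me3[[chrom]] <- addRect(k27me3[[chrom]], bw, mid - W, mid + W,
                               hBroad)
  }
  # NDR dips at every co-bound peak midpoint (repressed promoters keep
  # theirs; focused promoters model stalled promoters without a dip)
  if (config@ndrDepth > 0 && nrow(cob)) {
    focusedPk <- prom$peak_index[prom$label == "focused"]
    for (pk in setdiff(seq_len(nrow(cob)), focusedPk)) {
      chrom <- cob$chrom[pk]
      a <- cobMid[pk] - config@ndrHalfwidth
      b <- cobMid[pk] + config@ndrHalfwidth
      k27me3[[chrom]] <- mulRect(k27me3[[chrom]], bw, a, b,
                                 1 - config@ndrDepth)
      h3[[chrom]] <- mulRect(h3[[chrom]], bw, a, b, 1 - config@ndrDepth)
    }
  }
  # enhancer activity marks
  for (k in seq_len(nrow(enh))) {
    chrom <- enh$chrom[k]
    k4me1[[chrom]] <- addRect(k4me1[[chrom]], bw, enh$start0[k] - 1000,
                              enh$end0[k] + 1000, 1)
    if (enh$activity[k] == "tf_bound")
      k27ac[[chrom]] <- addRect(k27ac[[chrom]], bw, enh$start0[k] - 500,
                                enh$end0[k] + 500, 1.5)
  }
  withSeed(seed, {
    noisy <- function(values, label) {
      out <- lapply(values, function(v)
        (v + config@baseline) * exp(rnorm(length(v), 0, config@noiseSd)))
      SignalTrack(out, bw, chromSizes, label)
    }
    tracks <- list(
      H3K27me3 = noisy(k27me3, "H3K27me3"),
      H3K27ac = noisy(k27ac, "H3K27ac"),
      H3K4me1 = noisy(k4me1, "H3K4me1"),
      H3 = noisy(h3, "H3"),
      input = noisy(input, "input"))
    # element sequences with planted motifs
    cons <- config@motifConsensus
    seqs <- vapply(seq_len(nrow(enh)), function(k) {
      w <- enh$end0[k] - enh$start0[k]
      s <- sample(BASES, w, replace = TRUE)
      if (enh$motif_planted[k]) {
        ins <- if (runif(1) < 0.5) cons else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cons)))
        pos <- sample.int(w - nchar(ins) + 1L, 1L)
        s[pos:(pos + nchar(ins) - 1L)] <- strsplit(ins, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
    sequences <- Biostrings::DNAStringSet(setNames(seqs, enh$id))
    # expression counts around class medians, ~2M-read library
    med <- config@expressionClassMedians
    cls <- truth$expression$class[match(genes$gene_id,
                                       truth$expression$gene_id)]
    targetRpkm <- med[cls] * exp(rnorm(length(genes), 0, 0.4))
    # counts consistent with a declared 2M-read library (the library
    # total includes reads outside these gene models, as in real data)
    L0 <- 2e6
    raw <- targetRpkm * (GenomicRanges::width(genes) / 1000) * (L0 / 1e6)
    counts <- as.integer(round(raw))
    expression <- data.frame(gene_id = genes$gene_id, count = counts,
                             length = GenomicRanges::width(genes),
                             library_size = as.integer(L0))
    list(tracks = tracks, sequences = sequences,
         expression = expression, librarySize = L0)
  })
}

#' Simulate a full synthetic study and write its files
#'
#' Runs \code{\link{generateGenome}},
#' \code{\link{plantRegulatoryLandscape}} and
#' \code{\link{synthesizeSignalTracks}} under the config seed and writes
#' every product in plain-text formats: chrom.sizes, gene models (TSV),
#' two replicate BEDs per factor, the two enhancer catalogs and the PRE
#' catalog (BED6), five bedGraph tracks, element sequences (FASTA),
#' expression counts (TSV), and ground truth + config echo (JSON).
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param dir output directory (created if needed)
#' @return (invisibly) list with file paths and the in-memory objects
#' @export
simulatePhorcStudy <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generateGenome(config)
  landscape <- plantRegulatoryLandscape(genome, config)
  signals <- synthesizeSignalTracks(genome, landscape, config)
  p <- function(f) file.path(dir, f)
  writeChromSizes(genome$chromSizes, p("chrom.sizes"))
  writeGeneModels(genome$genes, p("genes.tsv"))
  writeBed(landscape$pho$rep1, p("pho_rep1.bed"))
  writeBed(landscape$pho$rep2, p("pho_rep2.bed"))
  writeBed(landscape$sfmbt$rep1, p("sfmbt_rep1.bed"))
  writeBed(landscape$sfmbt$rep2, p("sfmbt_rep2.bed"))
  writeBed(landscape$enhChar, p("enhancers_characterized.bed"))
  writeBed(landscape$enhChip, p("enhancers_chip.bed"))
  writeBed(landscape$pres, p("pres.bed"))
  for (nm in names(signals$tracks))
    writeBedGraph(signals$tracks[[nm]],
                  p(sprintf("%s.bedgraph", tolower(nm))))
  Biostrings::writeXStringSet(signals$sequences,
                              p("enhancer_sequences.fasta"))
  writeExpressionCounts(signals$expression, p("expression.tsv"))
  # reference gene classes are study inputs (expression references and
  # TF-occupancy-derived enhancer classes); the PhoRC classes are what
  # the analysis itself derives, so they are withheld here
  ref <- landscape$truth$expression
  ref <- ref[!ref$class %in% c("phorc_repressed_promoter",
                               "phorc_dev_enhancer"), ]
  write.table(ref, p("gene_classes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    landscape$truth, p("truth.json"),
    dataframe = "columns", na = "null", digits = NA)
  jsonlite::write_json(configAsList(config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, genome = genome, landscape = landscape,
                 signals = signals))
}

# config echo as a plain list for JSON provenance
configAsList <- function(config) {
  nms <- slotNames("SyntheticConfig")
  out <- lapply(nms, function(nm) methods::slot(config, nm))
  names(out) <- nms
  out
}
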