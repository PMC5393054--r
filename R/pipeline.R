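# Pipeline orchestration: run the full analysis from a config, emit a
# structured report, and reproduce the printed summary arithmetic.

#' Format a count pair as a percentage
#'
#' \code{100 * numerator / denominator}, rounded to \code{digits}
#' decimals (reporting convention: one decimal for category fractions,
#' integers for coarse overlap fractions).
#'
#' @param numerator,denominator counts (denominator > 0)
#' @param digits decimal places (0 or 1 in the standard reports)
#' @return numeric percentage
#' @export
summarizeFractions <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0))
    polycreStop("polycre_validation_error", "denominator must be > 0")
  round(100 * numerator / denominator, digits)
}

requiredSyntheticFields <- c("mode", "outdir", "seed")
requiredFileFields <- c("mode", "outdir", "pho_rep1", "pho_rep2",
                        "sfmbt_rep1", "sfmbt_rep2", "genes",
                        "chrom_sizes", "enh_characterized", "enh_chip",
                        "pres", "h3k27me3", "h3", "sequences",
                        "expression", "seed")

validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$mode) || !cfg$mode %in% c("synthetic", "files"))
    polycreStop("polycre_config_error",
                "config field 'mode' must be 'synthetic' or 'files'")
  required <- if (cfg$mode == "synthetic") requiredSyntheticFields
              else requiredFileFields
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    polycreStop("polycre_config_error",
                "config missing required field(s): %s",
                paste(miss, collapse = ", "))
  if (cfg$mode == "files") {
    paths <- unlist(cfg[setdiff(requiredFileFields,
                                c("mode", "outdir", "seed"))])
    gone <- paths[!file.exists(paths)]
    if (length(gone))
      polycreStop("polycre_config_error", "input file(s) not found: %s",
                  paste(gone, collapse = ", "))
  }
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Stages run in order: co-occupancy, annotation, enrichment, chromatin
#' profiles, motif, expression, PRE-catalog overlap.  A stage failure
#' aborts with the stage name.  The config is a YAML file (or an
#' equivalent named list) with either \code{mode: synthetic} plus
#' optional synthetic parameter overrides, or \code{mode: files} plus
#' explicit input paths.  All seeds derive from the mandatory
#' \code{seed} field; reruns with the same config produce identical
#' reports.
#'
#' @param config path to a YAML config file, or a named list
#' @param force overwrite an existing report in outdir
#' @return the report (list), invisibly written as JSON and TSV under
#'   \code{outdir}
#' @export
runPipeline <- function(config, force = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validatePipelineConfig(cfg)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reportPath <- file.path(outdir, "report.json")
  if (file.exists(reportPath) && !force)
    polycreStop("polycre_config_error",
                "report already exists in %s (use force = TRUE)", outdir)
  seed <- as.integer(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      polycreStop("polycre_stage_error", "stage '%s' failed: %s",
                  name, conditionMessage(e)))
  }
  # ---- inputs -----------------------------------------------------------
  if (cfg$mode == "synthetic") {
    dataDir <- file.path(outdir, "data")
    scfgArgs <- cfg$synthetic
    scfg <- do.call(syntheticConfig,
                    c(scfgArgs, list(seed = seed)))
    stage("simulate", simulatePhorcStudy(scfg, dataDir))
    paths <- list(
      pho_rep1 = file.path(dataDir, "pho_rep1.bed"),
      pho_rep2 = file.path(dataDir, "pho_rep2.bed"),
      sfmbt_rep1 = file.path(dataDir, "sfmbt_rep1.bed"),
      sfmbt_rep2 = file.path(dataDir, "sfmbt_rep2.bed"),
      genes = file.path(dataDir, "genes.tsv"),
      chrom_sizes = file.path(dataDir, "chrom.sizes"),
      enh_characterized = file.path(dataDir,
                                    "enhancers_characterized.bed"),
      enh_chip = file.path(dataDir, "enhancers_chip.bed"),
      pres = file.path(dataDir, "pres.bed"),
      h3k27me3 = file.path(dataDir, "h3k27me3.bedgraph"),
      h3k27ac = file.path(dataDir, "h3k27ac.bedgraph"),
      h3 = file.path(dataDir, "h3.bedgraph"),
      sequences = file.path(dataDir, "enhancer_sequences.fasta"),
      expression = file.path(dataDir, "expression.tsv"),
      gene_classes = file.path(dataDir, "gene_classes.tsv"))
    binW <- scfg@binWidth
  } else {
    paths <- cfg
    binW <- if (!is.null(cfg$bin_width)) as.integer(cfg$bin_width) else 25L
  }
  chromSizes <- readChromSizes(paths$chrom_sizes)
  genes <- readGeneModels(paths$genes, chromSizes)
  inputFiles <- unlist(paths[vapply(paths, is.character, logical(1))])
  inputFiles <- inputFiles[file.exists(inputFiles)]
  inputHashes <- setNames(
    vapply(inputFiles, function(p) unname(tools::md5sum(p)),
           character(1)),
    basename(inputFiles))
  # ---- co-occupancy -----------------------------------------------------
  minRepOverlap <- if (!is.null(cfg$min_rep_overlap))
    cfg$min_rep_overlap else 0.25
  co <- stage("cooccupancy", {
    phoHC <- reconcileReplicates(readBed(paths$pho_rep1, chromSizes),
                                 readBed(paths$pho_rep2, chromSizes),
                                 minRepOverlap)
    sfHC <- reconcileReplicates(readBed(paths$sfmbt_rep1, chromSizes),
                                readBed(paths$sfmbt_rep2, chromSizes),
                                minRepOverlap)
    cb <- callCobound(phoHC, sfHC)
    list(phoHC = phoHC, sfHC = sfHC, cobound = cb)
  })
  ct <- coboundCounts(co$cobound)
  # ---- annotation -------------------------------------------------------
  enhChar <- readBed(paths$enh_characterized, chromSizes)
  enhChip <- readBed(paths$enh_chip, chromSizes)
  annotated <- stage("annotation",
    annotatePeaks(coboundRegions(co$cobound), genes, enhChar, enhChip))
  catSum <- categorySummary(annotated)
  hist <- tssDistanceHistogram(
    annotated, c(0, 250, 500, 1000, 2000, 5000, 10000, Inf))
  # ---- enrichment: co-bound regions vs enhancers over matched bg --------
  enr <- stage("enrichment", {
    bg <- sampleMatchedBackground(coboundRegions(co$cobound), chromSizes,
                                  genes, nPerPeak = 10L,
                                  seed = seed + 11L)
    overlapEnrichment(coboundRegions(co$cobound),
                      c(GenomicRanges::granges(enhChar),
                        GenomicRanges::granges(enhChip)), bg)
  })
  # ---- chromatin profiles ----------------------------------------------
  prof <- stage("profiles", {
    k27me3 <- readBedGraph(paths$h3k27me3, binW, chromSizes, "H3K27me3")
    h3 <- readBedGraph(paths$h3, binW, chromSizes, "H3")
    k27 <- subtractTracks(k27me3, h3, floorAtZero = TRUE)
    promPeaks <- annotated[annotated$category == "promoter"]
    cls <- if (length(promPeaks) >= 2)
      classifyPromoters(promPeaks, k27, seed = seed + 21L) else NULL
    enhPeaks <- annotated[annotated$category %in%
                          c("enhancer_characterized", "enhancer_chip")]
    ndr <- if (length(enhPeaks)) {
      mp <- buildMetaProfile(enhPeaks, h3, windowHalfwidth = 2000L,
                             binWidth = 100L)
      calls <- apply(profileMatrix(mp), 1, function(row)
        detectNdr(row, binWidth = 100L)$called)
      mean(calls)
    } else NA_real_
    comparison <- if (length(enhPeaks) >= 2) {
      allEnhG <- c(GenomicRanges::granges(enhChar),
                   GenomicRanges::granges(enhChip))
      boundMask <- IRanges::overlapsAny(allEnhG,
                                              coboundRegions(co$cobound))
      boundEnh <- allEnhG[boundMask]
      unboundEnh <- allEnhG[!boundMask]
      k27acPath <- paths$h3k27ac
      tracks <- list(H3K27me3 = k27)
      if (!is.null(k27acPath) && file.exists(k27acPath))
        tracks$H3K27ac <- readBedGraph(k27acPath, binW, chromSizes,
                                       "H3K27ac")
      cmp <- compareElementClasses(boundEnh, unboundEnh, tracks,
                                   seed = seed + 31L)
      lapply(cmp, function(x) x$test$p.value)
    } else NULL
    list(classes = cls, ndrFraction = ndr, elementTests = comparison)
  })
  # ---- motif ------------------------------------------------------------
  mot <- stage("motif", {
    seqs <- Biostrings::readDNAStringSet(paths$sequences)
    allEnh <- c(GenomicRanges::granges(enhChar),
                GenomicRanges::granges(enhChip))
    boundMask <- IRanges::overlapsAny(allEnh,
                                            coboundRegions(co$cobound))
    fg <- seqs[boundMask]
    bgSeqs <- seqs[!boundMask]
    if (length(fg) >= 10) {
      disc <- discoverMotif(fg, width = 8L, seed = seed + 41L)
      enrMot <- if (length(bgSeqs))
        motifEnrichment(fg, bgSeqs, disc$motif, scoreThreshold = 12)
      else NULL
      list(consensus = motifConsensus(disc$motif),
           ic = informationContent(disc$motif),
           enrichment = enrMot)
    } else NULL
  })
  # ---- expression -------------------------------------------------------
  expr <- stage("expression", {
    counts <- readExpressionCounts(paths$expression)
    lib <- if (!is.null(counts$library_size)) counts$library_size[1]
           else sum(counts$count)
    tab <- computeRpkm(counts$count, counts$length, lib,
                       geneIds = counts$gene_id)
    boundEnhAll <- c(GenomicRanges::granges(enhChar),
                     GenomicRanges::granges(enhChip))
    boundMask <- IRanges::overlapsAny(boundEnhAll,
                                            coboundRegions(co$cobound))
    assignEnh <- assignRegionsToGenes(boundEnhAll, genes)
    promPeaks <- annotated[annotated$category == "promoter"]
    cls <- data.frame(gene_id = character(0), class = character(0))
    if (!is.null(prof$classes)) {
      broadIdx <- which(prof$classes$calls$label == "broad")
      cls <- rbind(cls, data.frame(
        gene_id = promPeaks$nearest_gene[broadIdx],
        class = "phorc_repressed_promoter"))
    }
    cls <- rbind(cls, data.frame(
      gene_id = assignEnh$gene_id[boundMask & assignEnh$assigned],
      class = "phorc_dev_enhancer"))
    # reference classes (expression references, TF-occupancy enhancer
    # classes) come from an input table when provided
    if (!is.null(paths$gene_classes) && file.exists(paths$gene_classes)) {
      ref <- read.table(paths$gene_classes, sep = "\t", header = TRUE,
                        colClasses = c("character", "character"))
      cls <- rbind(cls, ref)
    }
    # promoter evidence wins on conflicts; first label per gene wins
    cls <- cls[!duplicated(cls$gene_id), ]
    summary <- expressionByClass(tab, cls)
    summary
  })
  # ---- PRE catalog overlap ---------------------------------------------
  pres <- readBed(paths$pres, chromSizes)
  preHit <- sum(IRanges::overlapsAny(pres,
                                           coboundRegions(co$cobound)))
  report <- list(
    counts = list(
      pho = unname(ct[["pho_total"]]),
      sfmbt = unname(ct[["sfmbt_total"]]),
      cobound_regions = unname(ct[["cobound_regions"]]),
      pho_cobound = unname(ct[["pho_cobound"]]),
      sfmbt_cobound = unname(ct[["sfmbt_cobound"]]),
      pre_catalog = length(pres),
      pre_overlapping = preHit),
    percentages = list(
      cobound_of_pho = summarizeFractions(ct[["pho_cobound"]],
                                          ct[["pho_total"]], 1),
      cobound_of_sfmbt = summarizeFractions(ct[["sfmbt_cobound"]],
                                            ct[["sfmbt_total"]], 0),
      by_category = setNames(as.list(catSum$percent), catSum$category),
      pre_catalog_overlap = summarizeFractions(preHit,
                                               max(length(pres), 1), 0)),
    annotation = list(
      category_counts = setNames(as.list(catSum$count), catSum$category),
      tss_distance_median = hist$median,
      tss_histogram = list(edges = hist$edges[is.finite(hist$edges)],
                           counts = hist$counts)),
    enrichment = list(
      enhancer_overlap_log2_or = enr@log2OddsRatio,
      enhancer_overlap_p = enr@pValue,
      table = as.vector(t(enr@table))),
    promoter_classes = if (!is.null(prof$classes))
      as.list(prof$classes$fractions) else NULL,
    ndr_fraction_at_bound_enhancers = prof$ndrFraction,
    element_class_tests = prof$elementTests,
    motif = if (!is.null(mot)) list(
      consensus = mot$consensus,
      information_content = mot$ic,
      fg_fraction = if (!is.null(mot$enrichment))
        mot$enrichment$fgFraction else NA,
      bg_fraction = if (!is.null(mot$enrichment))
        mot$enrichment$bgFraction else NA) else NULL,
    expression_medians = if (!is.null(expr))
      setNames(as.list(expr$medians$median_rpkm), expr$medians$class)
    else NULL,
    provenance = list(
      package_version = as.character(utils::packageVersion("polycre")),
      seed = seed,
      mode = cfg$mode,
      min_rep_overlap = minRepOverlap,
      input_md5 = as.list(inputHashes)))
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  tsv <- data.frame(
    metric = c("pho_peaks", "sfmbt_peaks", "cobound_regions",
               "pct_cobound_of_pho", "pct_cobound_of_sfmbt",
               "pct_pre_overlap"),
    value = c(report$counts$pho, report$counts$sfmbt,
              report$counts$cobound_regions,
              report$percentages$cobound_of_pho,
              report$percentages$cobound_of_sfmbt,
              report$percentages$pre_catalog_overlap))
  write.table(tsv, file.path(outdir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(report)
}
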