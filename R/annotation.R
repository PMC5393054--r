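# Annotation: nearest TSS, signed distances, and exclusive five-way
# genomic categorisation of co-bound regions.

PEAK_CATEGORIES <- c("promoter", "enhancer_characterized",
                     "enhancer_chip", "intragenic", "intergenic")

#' Distance from peak midpoints to the nearest TSS
#'
#' Distances are measured from the 0-based peak midpoint to the nearest
#' gene TSS; ties are broken by lexicographic gene_id.  The signed
#' distance is strand-aware: negative means upstream of the TSS.
#' Peaks on chromosomes without genes get \code{NA} with an
#' \code{annotatable = FALSE} flag.
#'
#' @param peaks GRanges
#' @param genes GRanges gene models with \code{gene_id} and \code{tss}
#' @return data.frame with nearest_gene, tss_distance (unsigned),
#'   tss_signed, annotatable
#' @export
distanceToTss <- function(peaks, genes) {
  mid <- midpoint0(peaks)
  pchrom <- as.character(GenomicRanges::seqnames(peaks))
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  gtss <- if (!is.null(genes$tss)) genes$tss else tss0(genes)
  gstrand <- as.character(GenomicRanges::strand(genes))
  ord <- order(genes$gene_id)  # lexicographic tie-break: scan in id order
  out <- data.frame(nearest_gene = NA_character_,
                    tss_distance = NA_integer_,
                    tss_signed = NA_integer_,
                    annotatable = FALSE,
                    stringsAsFactors = FALSE)[rep(1, length(peaks)), ]
  rownames(out) <- NULL
  for (chrom in unique(pchrom)) {
    gi <- ord[gchrom[ord] == chrom]
    pi <- which(pchrom == chrom)
    if (!length(gi)) next
    d <- abs(outer(mid[pi], gtss[gi], "-"))
    best <- apply(d, 1, which.min)  # which.min takes first == smallest id
    out$nearest_gene[pi] <- genes$gene_id[gi[best]]
    out$tss_distance[pi] <- d[cbind(seq_along(pi), best)]
    sgn <- ifelse(gstrand[gi[best]] == "-",
                  gtss[gi[best]] - mid[pi],
                  mid[pi] - gtss[gi[best]])
    out$tss_signed[pi] <- sgn
    out$annotatable[pi] <- TRUE
  }
  out
}

#' Exclusive five-way genomic categorisation of peaks
#'
#' Each peak gets exactly one category by midpoint membership with
#' precedence: promoter (unsigned TSS distance <= promoterWindow, both
#' directions, inclusive) > characterized enhancer > ChIP-defined
#' enhancer > intragenic (midpoint inside any gene body) > intergenic.
#'
#' @param peaks GRanges
#' @param genes GRanges gene models
#' @param enhCharacterized,enhChip GRanges enhancer catalogs
#' @param promoterWindow promoter distance rule in bp (default 500)
#' @return GRanges \code{peaks} with added metadata: midpoint (0-based),
#'   nearest_gene, tss_distance, tss_signed, annotatable, category
#' @export
annotatePeaks <- function(peaks, genes, enhCharacterized, enhChip,
                          promoterWindow = 500L) {
  dt <- distanceToTss(peaks, genes)
  mid <- midpoint0(peaks)
  midGr <- granges0(as.character(GenomicRanges::seqnames(peaks)),
                    mid, mid + 1L)
  inChar <- IRanges::overlapsAny(midGr, enhCharacterized)
  inChip <- IRanges::overlapsAny(midGr, enhChip)
  inGene <- IRanges::overlapsAny(midGr, genes, ignore.strand = TRUE)
  category <- ifelse(
    dt$annotatable & dt$tss_distance <= promoterWindow, "promoter",
    ifelse(inChar, "enhancer_characterized",
           ifelse(inChip, "enhancer_chip",
                  ifelse(inGene, "intragenic", "intergenic"))))
  out <- peaks
  out$midpoint <- mid
  out$nearest_gene <- dt$nearest_gene
  out$tss_distance <- dt$tss_distance
  out$tss_signed <- dt$tss_signed
  out$annotatable <- dt$annotatable
  out$category <- factor(category, levels = PEAK_CATEGORIES)
  out
}

#' Category counts and percentages
#'
#' @param annotated GRanges from \code{\link{annotatePeaks}}
#' @param digits decimals for percentages (default 1, the reporting
#'   convention for category fractions)
#' @return data.frame with category, count, percent
#' @export
categorySummary <- function(annotated, digits = 1) {
  if (!length(annotated))
    polycreStop("polycre_validation_error", "empty annotation")
  counts <- table(annotated$category)
  data.frame(category = names(counts),
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / length(annotated),
                             digits))
}

#' TSS-distance histogram and medians
#'
#' Frequencies of unsigned TSS distances over user bin edges plus the
#' median unsigned distance.  Unannotatable peaks (no gene on the
#' chromosome) are excluded and their count reported.
#'
#' @param annotated GRanges from \code{\link{annotatePeaks}}, or a
#'   numeric vector of unsigned distances
#' @param binEdges strictly increasing numeric vector of edges; bin i is
#'   [edge_i, edge_{i+1})
#' @return list with counts, edges, median, n, n_unannotatable
#' @export
tssDistanceHistogram <- function(annotated, binEdges) {
  if (any(diff(binEdges) <= 0))
    polycreStop("polycre_validation_error",
                "bin edges must be strictly increasing")
  if (is.numeric(annotated)) {
    d <- annotated
    nUn <- 0L
  } else {
    d <- annotated$tss_distance[annotated$annotatable]
    nUn <- sum(!annotated$annotatable)
  }
  counts <- vapply(seq_len(length(binEdges) - 1L), function(i)
    sum(d >= binEdges[i] & d < binEdges[i + 1L]), integer(1))
  list(counts = counts, edges = binEdges,
       median = median(d), n = length(d), n_unannotatable = nUn)
}
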