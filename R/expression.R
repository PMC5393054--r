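# Expression: RPKM computation, nearest-gene assignment of regulatory
# regions, and per-class expression comparison.

GENE_CLASSES <- c("ubiquitous", "meso", "non_meso",
                  "phorc_repressed_promoter", "phorc_dev_enhancer",
                  "tf_bound_enhancer", "nonbound_enhancer")

#' Compute RPKM per gene
#'
#' rpkm = counts / (length/1000 * librarySize/1e6); reads per kilobase
#' of gene model per million mapped reads.
#'
#' @param counts integer read counts per gene
#' @param lengths gene lengths in bp (> 0)
#' @param librarySize total mapped reads (> 0)
#' @param geneIds optional gene identifiers
#' @return data.frame with gene_id, count, length, rpkm and a
#'   \code{library_size} attribute
#' @export
computeRpkm <- function(counts, lengths, librarySize,
                        geneIds = NULL) {
  if (any(lengths <= 0))
    polycreStop("polycre_validation_error", "zero-length gene")
  if (librarySize <= 0)
    polycreStop("polycre_validation_error", "library size must be > 0")
  if (is.null(geneIds)) geneIds <- paste0("gene", seq_along(counts))
  out <- data.frame(
    gene_id = geneIds, count = counts, length = lengths,
    rpkm = counts / (lengths / 1000 * librarySize / 1e6))
  attr(out, "library_size") <- librarySize
  out
}

#' Assign regulatory regions to their nearest gene
#'
#' Each region maps to the gene whose TSS is nearest its 0-based
#' midpoint; ties break to the lexicographically smaller gene_id.
#' Regions on chromosomes without genes are flagged unassigned.
#'
#' @param regions GRanges
#' @param genes GRanges gene models
#' @param maxDistance optional cap: assignments farther than this become
#'   unassigned (default NULL, no cap)
#' @return data.frame with region, gene_id, distance, assigned
#' @export
assignRegionsToGenes <- function(regions, genes, maxDistance = NULL) {
  dt <- distanceToTss(regions, genes)
  out <- data.frame(region = seq_along(regions),
                    gene_id = dt$nearest_gene,
                    distance = dt$tss_distance,
                    assigned = dt$annotatable)
  if (!is.null(maxDistance)) {
    far <- out$assigned & out$distance > maxDistance
    out$gene_id[far] <- NA_character_
    out$assigned[far] <- FALSE
  }
  out
}

#' Median RPKM by gene class with pairwise tests
#'
#' Per-class median RPKM plus two-sided Mann-Whitney tests for the
#' contrasts of interest: each PhoRC class (repressed promoter, bound
#' developmental enhancer) against TF-bound enhancers and against
#' mesoderm-expressed genes.
#'
#' @param table data.frame from \code{\link{computeRpkm}}
#' @param assignments data.frame with gene_id, class
#' @return list with \code{medians} (data.frame class, n, median_rpkm)
#'   and \code{tests} (data.frame class_a, class_b, p_value)
#' @export
expressionByClass <- function(table, assignments) {
  merged <- merge(table, assignments, by = "gene_id")
  merged <- merged[!is.na(merged$class), ]
  present <- intersect(GENE_CLASSES, unique(merged$class))
  missing <- setdiff(unique(assignments$class), present)
  if (length(missing))
    warning("classes with no expressed genes excluded: ",
            paste(missing, collapse = ", "))
  med <- do.call(rbind, lapply(present, function(cl) {
    v <- merged$rpkm[merged$class == cl]
    data.frame(class = cl, n = length(v), median_rpkm = median(v))
  }))
  contrasts <- list(
    c("phorc_repressed_promoter", "tf_bound_enhancer"),
    c("phorc_dev_enhancer", "tf_bound_enhancer"),
    c("phorc_repressed_promoter", "meso"),
    c("phorc_dev_enhancer", "meso"))
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    if (!all(ct %in% present)) return(NULL)
    x <- merged$rpkm[merged$class == ct[1]]
    y <- merged$rpkm[merged$class == ct[2]]
    data.frame(class_a = ct[1], class_b = ct[2],
               p_value = mannWhitneyU(x, y, mode = "normal")$p.value)
  }))
  list(medians = med, tests = tests)
}
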