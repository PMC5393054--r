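# Co-occupancy: high-confidence peak sets from replicates and PhoRC
# (Pho + dSfmbt) co-bound region calling.

#' Reconcile two biological replicates into a high-confidence peak set
#'
#' A rep1 peak is retained iff it has at least \code{minOverlapFraction}
#' reciprocal overlap (overlap width / peak width, for both partners)
#' with some rep2 peak; retained peaks are merged with all their
#' qualifying partners (interval union).  Peaks that end up overlapping
#' after merging are themselves merged, so the result is non-overlapping
#' and sorted.
#'
#' @param rep1,rep2 GRanges peak sets for the same factor and condition
#' @param minOverlapFraction reciprocal overlap threshold (default 0.25)
#' @return GRanges of high-confidence peaks
#' @export
reconcileReplicates <- function(rep1, rep2, minOverlapFraction = 0.25) {
  if (length(rep1) == 0 || length(rep2) == 0)
    return(GenomicRanges::sort(rep1[integer(0)]))
  hits <- GenomicRanges::findOverlaps(rep1, rep2)
  if (!length(hits)) return(GenomicRanges::sort(rep1[integer(0)]))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(rep1[q], rep2[s]))
  recip <- pmin(ov / GenomicRanges::width(rep1[q]),
                ov / GenomicRanges::width(rep2[s]))
  keep <- recip >= minOverlapFraction
  if (!any(keep)) return(GenomicRanges::sort(rep1[integer(0)]))
  q <- q[keep]; s <- s[keep]
  # union of each qualifying rep1 peak with all its partners
  merged <- GenomicRanges::punion(
    rep1[q],
    GenomicRanges::GRanges(GenomicRanges::seqnames(rep1[q]),
                           IRanges::IRanges(
                             GenomicRanges::start(rep2[s]),
                             GenomicRanges::end(rep2[s]))),
    fill.gap = TRUE)
  out <- GenomicRanges::reduce(GenomicRanges::sort(merged))
  S4Vectors::mcols(out) <- NULL
  out
}

#' Combine peak sets across time points
#'
#' Interval union across the sets (overlapping peaks merged).  If the
#' inputs carry a \code{score} column, each combined peak gets the
#' maximum score over its contributors.
#'
#' @param sets list of GRanges for the same factor
#' @return GRanges union
#' @export
combineTimepoints <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  all <- do.call(c, lapply(sets, function(g) {
    g2 <- GenomicRanges::granges(g)
    g2$score <- if (!is.null(g$score)) g$score else NA_real_
    g2
  }))
  out <- GenomicRanges::reduce(GenomicRanges::sort(all))
  if (any(!is.na(all$score))) {
    hits <- GenomicRanges::findOverlaps(out, all)
    sc <- tapply(all$score[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits),
                 function(v) if (all(is.na(v))) NA_real_ else
                   max(v, na.rm = TRUE))
    out$score <- as.numeric(sc[as.character(seq_along(out))])
  }
  out
}

#' Call co-bound (PhoRC) regions from two factors' peak sets
#'
#' A first-factor peak is co-bound iff it overlaps a second-factor peak
#' by at least \code{minOverlap} bp (default 1, the most permissive rule
#' consistent with co-occupancy).  Each co-bound region is the union of
#' its transitively overlapping peak group; remaining peaks fall into the
#' factor-only classes.  Counts in source-peak units are retained so
#' percentages of either factor's peaks can be reported.
#'
#' @param pho,sfmbt GRanges high-confidence peak sets
#' @param minOverlap minimum overlap in bp to call co-occupancy
#' @return a \linkS4class{CoboundSet}
#' @export
callCobound <- function(pho, sfmbt, minOverlap = 1L) {
  hits <- GenomicRanges::findOverlaps(pho, sfmbt,
                                      minoverlap = minOverlap)
  phoIdx <- unique(S4Vectors::queryHits(hits))
  sfIdx <- unique(S4Vectors::subjectHits(hits))
  involved <- c(GenomicRanges::granges(pho[phoIdx]),
                GenomicRanges::granges(sfmbt[sfIdx]))
  cobound <- if (length(involved))
    GenomicRanges::reduce(GenomicRanges::sort(involved))
  else GenomicRanges::granges(pho[integer(0)])
  prov <- if (length(cobound)) {
    ph <- GenomicRanges::findOverlaps(cobound, pho[phoIdx])
    sh <- GenomicRanges::findOverlaps(cobound, sfmbt[sfIdx])
    rbind(
      data.frame(region = S4Vectors::queryHits(ph), factor = "pho",
                 source_peak = phoIdx[S4Vectors::subjectHits(ph)]),
      data.frame(region = S4Vectors::queryHits(sh), factor = "sfmbt",
                 source_peak = sfIdx[S4Vectors::subjectHits(sh)]))
  } else data.frame(region = integer(0), factor = character(0),
                    source_peak = integer(0))
  new("CoboundSet",
      cobound = cobound,
      phoOnly = GenomicRanges::granges(
        pho[setdiff(seq_along(pho), phoIdx)]),
      sfmbtOnly = GenomicRanges::granges(
        sfmbt[setdiff(seq_along(sfmbt), sfIdx)]),
      phoCoboundCount = length(phoIdx),
      sfmbtCoboundCount = length(sfIdx),
      provenance = prov)
}

#' Quantify track signal in regions
#'
#' Per-region sum of per-bp signal (bin value x covered bp), with partial
#' bins counted proportionally — a read-count-equivalent total from a
#' binned track.
#'
#' @param regions GRanges
#' @param track a \linkS4class{SignalTrack}
#' @return numeric vector of per-region totals
#' @export
quantifySignal <- function(regions, track) {
  chroms <- as.character(GenomicRanges::seqnames(regions))
  unknown <- setdiff(unique(chroms), names(track@values))
  if (length(unknown))
    polycreStop("polycre_validation_error",
                "chromosome %s not on track", unknown[1])
  if (any(GenomicRanges::end(regions) >
          track@seqlengths[chroms]))
    polycreStop("polycre_validation_error",
                "region beyond chromosome bound")
  out <- numeric(length(regions))
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    out[idx] <- trackIntegral(track, chrom,
                              GenomicRanges::start(regions[idx]) - 1L,
                              GenomicRanges::end(regions[idx]))
  }
  out
}
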