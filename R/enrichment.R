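# Matched-background sampling, Fisher's exact test, and the two-sided
# Mann-Whitney U test used for overlap and signal comparisons.

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of all
#' tables (with the observed margins) that are no more probable than the
#' observed one, with a relative tolerance of 1e-7 on the comparison.
#' The odds ratio is the sample OR (a*d)/(b*c); if any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell for the OR (the
#' p-value is unaffected).
#'
#' @param table 2x2 matrix of counts, or a length-4 vector (a, b, c, d)
#'   in row-major order: rows in-set vs background, columns overlapping
#'   vs not
#' @return an \linkS4class{EnrichmentResult}
#' @export
fisherExact <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    tab <- table
  } else {
    stopifnot(length(table) == 4)
    tab <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  }
  if (any(tab < 0) || any(tab != round(tab)))
    polycreStop("polycre_validation_error",
                "contingency counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  r1 <- a + b; c1 <- a + c_
  if (r1 == 0 || c_ + d == 0 || c1 == 0 || b + d == 0)
    polycreStop("polycre_undefined_test",
                "a table margin is zero; the test is undefined")
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  pObs <- dhyper(a, c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  corr <- any(tab == 0)
  orVal <- if (corr)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else (a * d) / (b * c_)
  new("EnrichmentResult",
      log2OddsRatio = log2(orVal), pValue = p,
      table = tab, correctionApplied = corr)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is reported for the first sample: the number of (x, y) pairs with
#' x > y, counting ties as 1/2.  Exact mode enumerates all assignments of
#' the pooled values to the two groups (feasible for n + m <= 12 or so)
#' and returns P(|U - nm/2| >= |U_obs - nm/2|).  Normal mode uses the
#' tie-corrected normal approximation with a 0.5 continuity correction.
#'
#' @param x,y numeric samples
#' @param mode "exact" or "normal"
#' @return list with U, p.value, mode
#' @export
mannWhitneyU <- function(x, y, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  uStat <- function(xv, yv)
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  u <- uStat(x, y)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(U = u, p.value = 1, mode = mode))
  }
  if (mode == "exact") {
    pooled <- c(x, y)
    idx <- combn(n + m, n)
    mid <- n * m / 2
    devObs <- abs(u - mid)
    devs <- apply(idx, 2, function(ix)
      abs(uStat(pooled[ix], pooled[-ix]) - mid))
    p <- mean(devs >= devObs - 1e-9)
  } else {
    pooled <- c(x, y)
    nTot <- n + m
    ties <- table(pooled)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- n * m / 12 * ((nTot + 1) - tieTerm / (nTot * (nTot - 1)))
    if (sigma2 <= 0) return(list(U = u, p.value = 1, mode = mode))
    mid <- n * m / 2
    z <- (u - mid - sign(u - mid) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = u, p.value = p, mode = mode)
}

#' Sample matched background intervals for a peak set
#'
#' For each peak, \code{nPerPeak} intervals with identical length, the
#' same chromosome, and a nearest-TSS distance falling in the same decile
#' of the peak set's TSS-distance distribution.  Background intervals
#' never overlap any input peak.  Placement is targeted (an offset drawn
#' within the decile bounds around a random TSS) with bounded retries.
#'
#' @param peaks GRanges
#' @param chromSizes named chromosome lengths
#' @param genes GRanges gene models
#' @param nPerPeak intervals per peak (default 10)
#' @param seed RNG seed (local to this call)
#' @param maxTries retries per interval before failing
#' @return GRanges of background intervals with a \code{source_peak}
#'   metadata column
#' @export
sampleMatchedBackground <- function(peaks, chromSizes, genes,
                                    nPerPeak = 10L, seed = NULL,
                                    maxTries = 500L) {
  dt <- distanceToTss(peaks, genes)
  if (any(!dt$annotatable))
    polycreStop("polycre_validation_error",
                "peaks on chromosomes without genes cannot be matched")
  edges <- quantile(dt$tss_distance, probs = seq(0, 1, 0.1), names = FALSE)
  decile <- findInterval(dt$tss_distance, edges,
                         rightmost.closed = TRUE, all.inside = TRUE)
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  gtss <- if (!is.null(genes$tss)) genes$tss else tss0(genes)
  pchrom <- as.character(GenomicRanges::seqnames(peaks))
  widths <- GenomicRanges::width(peaks)
  peakIRByChrom <- lapply(
    split(seq_along(peaks), pchrom),
    function(ix) IRanges::IRanges(GenomicRanges::start(peaks[ix]),
                                  GenomicRanges::end(peaks[ix])))
  tssSorted <- lapply(split(gtss, gchrom), sort)
  withSeed(seed, {
    res <- vector("list", length(peaks))
    for (i in seq_along(peaks)) {
      lo <- edges[decile[i]]; hi <- edges[decile[i] + 1L]
      chrom <- pchrom[i]
      L <- chromSizes[[chrom]]
      tssHere <- tssSorted[[chrom]]
      w <- widths[i]
      starts0 <- integer(0)
      tries <- 0L
      batch <- 4L * nPerPeak
      while (length(starts0) < nPerPeak) {
        tries <- tries + 1L
        if (tries > maxTries)
          polycreStop("polycre_placement_error",
                      "cannot place matched background for peak %d", i)
        t0 <- resample(tssHere, batch, replace = TRUE)
        dist <- runif(batch, lo, hi)
        mid <- round(t0 + sample(c(-1, 1), batch, replace = TRUE) * dist)
        s0 <- as.integer(mid - floor(w / 2))
        ok <- s0 >= 0L & s0 + w <= L
        # no overlap with any input peak
        ok[ok] <- IRanges::countOverlaps(
          IRanges::IRanges(s0[ok] + 1L, s0[ok] + w),
          peakIRByChrom[[chrom]]) == 0
        # nearest-TSS distance must really land in the decile bounds
        cmid <- as.integer(floor((2 * s0 + w) / 2))
        j <- findInterval(cmid, tssHere)
        dLeft <- ifelse(j >= 1, cmid - tssHere[pmax(j, 1)], Inf)
        dRight <- ifelse(j < length(tssHere),
                         tssHere[pmin(j + 1L, length(tssHere))] - cmid,
                         Inf)
        dNew <- pmin(dLeft, dRight)
        ok <- ok & dNew >= lo - 1e-9 & dNew <= hi + 1e-9
        starts0 <- c(starts0, s0[ok])
      }
      starts0 <- starts0[seq_len(nPerPeak)]
      res[[i]] <- granges0(rep(chrom, nPerPeak), starts0, starts0 + w,
                           source_peak = rep(i, nPerPeak))
    }
    out <- do.call(c, res)
    out
  })
}

#' Overlap enrichment of a query set versus a background set
#'
#' Builds the 2x2 table (query overlapping features / not; background
#' overlapping / not; overlap means >= 1 bp) and applies
#' \code{\link{fisherExact}}.
#'
#' @param query,features,background GRanges on the same genome
#' @return an \linkS4class{EnrichmentResult}
#' @export
overlapEnrichment <- function(query, features, background) {
  qHit <- sum(IRanges::overlapsAny(query, features))
  bHit <- sum(IRanges::overlapsAny(background, features))
  fisherExact(matrix(c(qHit, length(query) - qHit,
                       bHit, length(background) - bHit),
                     2, 2, byrow = TRUE))
}

#' Benjamini-Hochberg adjustment for a batch of enrichment results
#'
#' @param results list of \linkS4class{EnrichmentResult}
#' @return numeric vector of BH-adjusted p-values
#' @export
adjustEnrichmentBatch <- function(results) {
  stats::p.adjust(vapply(results, function(r) r@pValue, numeric(1)),
                  method = "BH")
}
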