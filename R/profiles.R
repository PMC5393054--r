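# Meta-profiles, bootstrap bands, the focused/broad promoter classifier,
# and nucleosome-depleted region (NDR) detection.

#' Build a meta-profile of signal centered on region midpoints
#'
#' Row i holds the signal over \code{[mid_i - W, mid_i + W)} rebinned to
#' \code{binWidth}-bp bins (coverage-weighted, partial source bins
#' exact).  Output bins that extend beyond a chromosome edge are NA
#' (missing), not zero, and are excluded from the summary curve.
#'
#' @param regions GRanges (centers are 0-based midpoints)
#' @param track a \linkS4class{SignalTrack}
#' @param windowHalfwidth window half-width W in bp (default 10000)
#' @param binWidth output bin width in bp (default 100; must divide 2W)
#' @return a \linkS4class{MetaProfile}
#' @export
buildMetaProfile <- function(regions, track, windowHalfwidth = 10000L,
                             binWidth = 100L) {
  if (!length(regions))
    polycreStop("polycre_validation_error", "empty region set")
  if ((2L * windowHalfwidth) %% binWidth != 0L)
    polycreStop("polycre_validation_error",
                "window (2 x %d) not a multiple of bin width %d",
                windowHalfwidth, binWidth)
  nbin <- (2L * windowHalfwidth) %/% binWidth
  mid <- midpoint0(regions)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  mat <- matrix(NA_real_, nrow = length(regions), ncol = nbin)
  offsets <- seq(0L, by = binWidth, length.out = nbin)
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    L <- track@seqlengths[[chrom]]
    starts <- rep(mid[idx] - windowHalfwidth, each = nbin) +
      rep(offsets, times = length(idx))
    ends <- starts + binWidth
    ok <- starts >= 0 & ends <= L
    vals <- rep(NA_real_, length(starts))
    if (any(ok))
      vals[ok] <- trackIntegral(track, chrom, starts[ok], ends[ok]) /
        binWidth
    mat[idx, ] <- matrix(vals, ncol = nbin, byrow = TRUE)
  }
  new("MetaProfile",
      matrix = mat,
      windowHalfwidth = as.integer(windowHalfwidth),
      binWidth = as.integer(binWidth),
      summary = colMeans(mat, na.rm = TRUE),
      ciLower = numeric(0), ciUpper = numeric(0),
      label = track@label)
}

#' Percentile bootstrap confidence band for a meta-profile mean curve
#'
#' Resamples profile rows with replacement \code{nBoot} times and takes
#' per-bin percentile bounds of the resampled means.
#'
#' @param profile a \linkS4class{MetaProfile}
#' @param nBoot bootstrap replicates (default 1000)
#' @param alpha two-sided level (default 0.05 for a 95\% band)
#' @param seed RNG seed (local to this call)
#' @return the profile with ciLower/ciUpper filled in
#' @export
bootstrapMeanCi <- function(profile, nBoot = 1000L, alpha = 0.05,
                            seed = NULL) {
  mat <- profile@matrix
  n <- nrow(mat)
  if (n < 2L) {
    warning("single profile row: degenerate CI equal to the point value")
    profile@ciLower <- profile@summary
    profile@ciUpper <- profile@summary
    return(profile)
  }
  withSeed(seed, {
    boots <- matrix(NA_real_, nrow = nBoot, ncol = ncol(mat))
    for (b in seq_len(nBoot)) {
      rows <- sample.int(n, n, replace = TRUE)
      boots[b, ] <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    }
    ci <- apply(boots, 2, quantile,
                probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
    profile@ciLower <- ci[1, ]
    profile@ciUpper <- ci[2, ]
    profile
  })
}

# Per-promoter H3K27me3 features used by the classifier.
promoterStateFeatures <- function(regions, track,
                                  focusedHalfwidth = 500L,
                                  broadHalfwidth = 10000L) {
  mid <- midpoint0(regions)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  levelFocused <- numeric(length(regions))
  levelBroad <- numeric(length(regions))
  breadth <- numeric(length(regions))
  # breadth threshold: genome-wide median of positive track values
  allv <- unlist(track@values, use.names = FALSE)
  tau <- median(allv[allv > 0])
  bw <- track@binWidth
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    L <- track@seqlengths[[chrom]]
    v <- track@values[[chrom]]
    for (i in idx) {
      aF <- max(0, mid[i] - focusedHalfwidth)
      bF <- min(L, mid[i] + focusedHalfwidth)
      aB <- max(0, mid[i] - broadHalfwidth)
      bB <- min(L, mid[i] + broadHalfwidth)
      levelFocused[i] <- trackIntegral(track, chrom, aF, bF) / (bF - aF)
      levelBroad[i] <- trackIntegral(track, chrom, aB, bB) / (bB - aB)
      bins <- (floor(aB / bw) + 1L):ceiling(bB / bw)
      breadth[i] <- mean(v[bins] > tau)
    }
  }
  data.frame(level_focused = levelFocused, level_broad = levelBroad,
             breadth = breadth, tau = tau)
}

#' Classify PhoRC-bound promoters as focused vs broad H3K27me3
#'
#' For each promoter region the classifier computes the mean signal in
#' +/- focusedHalfwidth and +/- broadHalfwidth of the midpoint and the
#' breadth (fraction of bins in the broad window above the genome-wide
#' median of positive track values), then splits the promoters by 2-means
#' (best of 10 seeded restarts) on (log1p(level_broad), breadth).  The
#' cluster with higher mean breadth is labelled "broad" — the
#' Polycomb-repressed class with domain-wide H3K27me3 — and the other
#' "focused" (a narrow peak typical of stalled, nonrepressed promoters).
#'
#' @param regions GRanges of PhoRC-bound promoter peaks
#' @param track H3K27me3 \linkS4class{SignalTrack} (H3-subtracted)
#' @param focusedHalfwidth,broadHalfwidth feature windows (bp)
#' @param seed RNG seed for the k-means restarts
#' @return list with \code{calls} (data.frame: region, features, label)
#'   and \code{fractions} (named numeric)
#' @export
classifyPromoters <- function(regions, track, focusedHalfwidth = 500L,
                              broadHalfwidth = 10000L, seed = 1L) {
  if (length(regions) < 2L)
    polycreStop("polycre_validation_error",
                "need at least 2 promoters to classify")
  feat <- promoterStateFeatures(regions, track, focusedHalfwidth,
                                broadHalfwidth)
  X <- cbind(log1p(feat$level_broad), feat$breadth)
  if (all(apply(X, 2, sd) < 1e-12)) {
    warning("degenerate features: all promoters identical; single class")
    calls <- data.frame(region = seq_along(regions), feat,
                        label = "focused")
    return(list(calls = calls,
                fractions = c(focused = 1, broad = 0)))
  }
  km <- withSeed(seed, kmeans(X, centers = 2L, nstart = 10L))
  broadCluster <- which.max(tapply(feat$breadth, km$cluster, mean))
  label <- ifelse(km$cluster == broadCluster, "broad", "focused")
  calls <- data.frame(region = seq_along(regions), feat, label = label)
  fr <- c(focused = mean(label == "focused"),
          broad = mean(label == "broad"))
  list(calls = calls, fractions = fr)
}

#' Detect a nucleosome-depleted region (NDR) in a profile curve
#'
#' An NDR is called iff the center-bin value is below \code{dipRatio}
#' times the mean of the two flank maxima within +/- flankHalfwidth of
#' the center.  Depth is 1 - center / flank-max mean.
#'
#' @param curve numeric profile curve (center at the middle); NA bins are
#'   ignored in the flank maxima
#' @param binWidth bin width of the curve in bp
#' @param flankHalfwidth flank search half-width in bp (default 1000)
#' @param dipRatio call threshold (default 0.5)
#' @return list with called (logical), depth, callable
#' @export
detectNdr <- function(curve, binWidth, flankHalfwidth = 1000L,
                      dipRatio = 0.5) {
  nbin <- length(curve)
  centerIdx <- floor(nbin / 2) + ifelse(nbin %% 2 == 0, 0L, 1L)
  span <- flankHalfwidth %/% binWidth
  if (centerIdx - span < 1L || centerIdx + span > nbin)
    polycreStop("polycre_validation_error",
                "curve does not cover +/- flankHalfwidth")
  center <- curve[centerIdx]
  left <- curve[(centerIdx - span):(centerIdx - 1L)]
  right <- curve[(centerIdx + 1L):(centerIdx + span)]
  if (all(is.na(left)) || all(is.na(right)) || is.na(center))
    return(list(called = FALSE, depth = NA_real_, callable = FALSE))
  flankMean <- mean(c(max(left, na.rm = TRUE), max(right, na.rm = TRUE)))
  if (flankMean <= 0)
    return(list(called = FALSE, depth = NA_real_, callable = FALSE))
  depth <- 1 - center / flankMean
  list(called = center < dipRatio * flankMean, depth = depth,
       callable = TRUE)
}

#' Compare chromatin state between two element classes
#'
#' For each track, per-class mean curves with bootstrap bands plus a
#' two-sided Mann-Whitney U test on per-region mean signal within
#' +/- 1 kb of the element midpoint.
#'
#' @param bound,unbound GRanges element classes
#' @param tracks named list of \linkS4class{SignalTrack}s
#'   (e.g. H3K27me3, H3K27ac)
#' @param windowHalfwidth meta-profile window (default 2000 bp)
#' @param testHalfwidth window for the per-region test means (default
#'   1000 bp)
#' @param binWidth profile bin width
#' @param nBoot bootstrap replicates for the bands
#' @param seed RNG seed
#' @return named list per track: boundProfile, unboundProfile, test
#' @export
compareElementClasses <- function(bound, unbound, tracks,
                                  windowHalfwidth = 2000L,
                                  testHalfwidth = 1000L,
                                  binWidth = 100L, nBoot = 200L,
                                  seed = 1L) {
  if (!length(bound) || !length(unbound))
    polycreStop("polycre_validation_error", "both classes must be nonempty")
  if (length(bound) < 2L || length(unbound) < 2L)
    warning("a class has a single region: degenerate bands")
  out <- lapply(seq_along(tracks), function(k) {
    track <- tracks[[k]]
    pb <- bootstrapMeanCi(
      buildMetaProfile(bound, track, windowHalfwidth, binWidth),
      nBoot = nBoot, seed = seed + k)
    pu <- bootstrapMeanCi(
      buildMetaProfile(unbound, track, windowHalfwidth, binWidth),
      nBoot = nBoot, seed = seed + 1000L + k)
    mB <- regionWindowMeans(bound, track, testHalfwidth)
    mU <- regionWindowMeans(unbound, track, testHalfwidth)
    list(boundProfile = pb, unboundProfile = pu,
         test = mannWhitneyU(mB, mU, mode = "normal"))
  })
  names(out) <- names(tracks)
  out
}

# Mean per-bp signal in +/- halfwidth of each region midpoint.
regionWindowMeans <- function(regions, track, halfwidth) {
  mid <- midpoint0(regions)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  out <- numeric(length(regions))
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    L <- track@seqlengths[[chrom]]
    a <- pmax(0, mid[idx] - halfwidth)
    b <- pmin(L, mid[idx] + halfwidth)
    out[idx] <- trackIntegral(track, chrom, a, b) / (b - a)
  }
  out
}
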