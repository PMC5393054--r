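#' @import methods
#' @importFrom stats median quantile rnorm runif rlnorm dhyper pnorm
#'   setNames kmeans sd
#' @importFrom utils read.table write.table combn head tail
#' @importClassesFrom GenomicRanges GRanges
NULL

#' SignalTrack: fixed-bin genome-wide signal
#'
#' A per-chromosome vector of signal values at a fixed bin width, the
#' in-memory form of a bedGraph coverage track (ChIP, input, H3, or a
#' subtracted variant).  Bin \code{i} (1-based) covers the 0-based
#' half-open interval \code{[(i-1)*binWidth, i*binWidth)}.
#'
#' @slot values named list of numeric vectors, one per chromosome
#' @slot binWidth bin size in bp
#' @slot seqlengths named integer vector of chromosome lengths (bp)
#' @slot label free-text track label (e.g. "H3K27me3")
#' @export
setClass("SignalTrack",
  representation(
    values = "list",
    binWidth = "integer",
    seqlengths = "integer",
    label = "character"
  )
)

setValidity("SignalTrack", function(object) {
  msgs <- character()
  if (length(object@binWidth) != 1L || object@binWidth < 1L)
    msgs <- c(msgs, "binWidth must be a single positive integer")
  if (is.null(names(object@values)) || is.null(names(object@seqlengths)))
    msgs <- c(msgs, "values and seqlengths must be named by chromosome")
  else if (!setequal(names(object@values), names(object@seqlengths)))
    msgs <- c(msgs, "values and seqlengths name different chromosomes")
  else {
    for (chrom in names(object@values)) {
      v <- object@values[[chrom]]
      expect <- ceiling(object@seqlengths[[chrom]] / object@binWidth)
      if (length(v) != expect)
        msgs <- c(msgs, sprintf(
          "chromosome %s: %d bins, expected ceiling(%d/%d) = %d",
          chrom, length(v), object@seqlengths[[chrom]], object@binWidth,
          expect))
      if (anyNA(v) || any(!is.finite(v)))
        msgs <- c(msgs, sprintf("chromosome %s: non-finite values", chrom))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CoboundSet: partition of two factors' peaks by co-occupancy
#'
#' Result of \code{\link{callCobound}}.  The co-bound regions (candidate
#' PhoRC regions) are unions of transitively overlapping Pho/dSfmbt peak
#' groups; remaining peaks fall into factor-only classes.  Counts in
#' source-peak units are kept so that percentages of either factor's peak
#' set can be reported.
#'
#' @slot cobound GRanges of merged co-bound regions
#' @slot phoOnly GRanges of first-factor-only peaks
#' @slot sfmbtOnly GRanges of second-factor-only peaks
#' @slot phoCoboundCount number of first-factor source peaks in co-bound regions
#' @slot sfmbtCoboundCount number of second-factor source peaks in co-bound regions
#' @slot provenance data.frame mapping source peaks to co-bound regions
#' @export
setClass("CoboundSet",
  representation(
    cobound = "GRanges",
    phoOnly = "GRanges",
    sfmbtOnly = "GRanges",
    phoCoboundCount = "integer",
    sfmbtCoboundCount = "integer",
    provenance = "data.frame"
  )
)

setValidity("CoboundSet", function(object) {
  msgs <- character()
  if (object@phoCoboundCount < 0L || object@sfmbtCoboundCount < 0L)
    msgs <- c(msgs, "co-bound source-peak counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' MetaProfile: signal matrix centered on region midpoints
#'
#' Rows are regions, columns are fixed-width position bins spanning
#' \code{[midpoint - windowHalfwidth, midpoint + windowHalfwidth)}.
#' Bins that fall beyond a chromosome edge are \code{NA} (missing, not
#' zero) and are excluded from the summary curve.
#'
#' @slot matrix numeric matrix, regions x position bins
#' @slot windowHalfwidth half-width of the window in bp
#' @slot binWidth output bin width in bp
#' @slot summary per-bin mean curve (NA-aware)
#' @slot ciLower,ciUpper optional per-bin bootstrap confidence bounds
#' @slot label track label carried over from the source track
#' @export
setClass("MetaProfile",
  representation(
    matrix = "matrix",
    windowHalfwidth = "integer",
    binWidth = "integer",
    summary = "numeric",
    ciLower = "numeric",
    ciUpper = "numeric",
    label = "character"
  )
)

setValidity("MetaProfile", function(object) {
  msgs <- character()
  expect <- (2L * object@windowHalfwidth) %/% object@binWidth
  if (ncol(object@matrix) != expect)
    msgs <- c(msgs, sprintf(
      "matrix has %d columns, expected 2*%d/%d = %d",
      ncol(object@matrix), object@windowHalfwidth, object@binWidth, expect))
  if (length(object@summary) && length(object@summary) != ncol(object@matrix))
    msgs <- c(msgs, "summary curve length differs from bin count")
  if (length(msgs)) msgs else TRUE
})

#' MotifModel: position weight matrix with background
#'
#' @slot matrix 4 x width probability matrix, rows A, C, G, T; each column
#'   sums to 1 and all entries are positive after pseudocount smoothing
#' @slot background length-4 base frequency vector (A, C, G, T), sums to 1
#' @slot pseudocount total pseudocount mass added per column
#' @export
setClass("MotifModel",
  representation(
    matrix = "matrix",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("MotifModel", function(object) {
  msgs <- character()
  m <- object@matrix
  if (nrow(m) != 4L)
    msgs <- c(msgs, "matrix must have 4 rows (A, C, G, T)")
  else {
    if (any(abs(colSums(m) - 1) > 1e-9))
      msgs <- c(msgs, "each motif position must sum to 1 (tolerance 1e-9)")
    if (any(m <= 0))
      msgs <- c(msgs, "all probabilities must be > 0 after pseudocount")
  }
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9)
    msgs <- c(msgs, "background must be 4 frequencies summing to 1")
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentResult: Fisher's exact test on a 2x2 overlap table
#'
#' @slot log2OddsRatio log2 odds ratio; Haldane-Anscombe +0.5 applied to
#'   every cell iff any cell is zero (see \code{correctionApplied})
#' @slot pValue two-sided p-value (sum of tables no more probable than the
#'   observed one under the hypergeometric null)
#' @slot table the 2x2 contingency table (rows: in-set vs background;
#'   columns: overlapping vs not)
#' @slot correctionApplied whether the +0.5 correction was used for the OR
#' @export
setClass("EnrichmentResult",
  representation(
    log2OddsRatio = "numeric",
    pValue = "numeric",
    table = "matrix",
    correctionApplied = "logical"
  )
)

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (any(object@table < 0))
    msgs <- c(msgs, "contingency counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticConfig: parameters of the synthetic regulatory landscape
#'
#' Defaults define the package's reference study conditions: one 10-Mb
#' chromosome, 200 genes, 100 Pho and 200 dSfmbt peaks with 80%
#' co-binding, a 46.6% broad (Polycomb-repressed) promoter fraction,
#' H3K27me3 domains of half-width 500 bp (focused) vs 10 kb at 3x the
#' level (broad), a 0.6-depth nucleosome-depleted region at bound
#' elements, and a GCCAT-core motif planted in 80% of bound-element
#' sequences.  See the package vignette for the rationale behind each
#' default.
#'
#' @export
setClass("SyntheticConfig",
  representation(
    nChromosomes = "integer",
    chromLength = "integer",
    nGenes = "integer",
    nPhoPeaks = "integer",
    nSfmbtPeaks = "integer",
    coboundFraction = "numeric",
    fracRepressedPromoters = "numeric",
    categoryProps = "numeric",
    enhancerCounts = "integer",
    nPres = "integer",
    nPresBound = "integer",
    peakWidthMean = "numeric",
    peakWidthSd = "numeric",
    peakWidthRange = "numeric",
    jitter = "integer",
    decoyRate = "numeric",
    broadDomainHalfwidth = "integer",
    focusedHalfwidth = "integer",
    broadLevelMultiplier = "numeric",
    focusedLevel = "numeric",
    ndrDepth = "numeric",
    ndrHalfwidth = "integer",
    motifConsensus = "character",
    motifPlantingRate = "numeric",
    expressionClassMedians = "numeric",
    noiseSd = "numeric",
    baseline = "numeric",
    binWidth = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  if (object@coboundFraction < 0 || object@coboundFraction > 1)
    msgs <- c(msgs, "coboundFraction must lie in [0, 1]")
  if (object@fracRepressedPromoters < 0 || object@fracRepressedPromoters > 1)
    msgs <- c(msgs, "fracRepressedPromoters must lie in [0, 1]")
  if (object@ndrDepth < 0 || object@ndrDepth >= 1)
    msgs <- c(msgs, "ndrDepth must lie in [0, 1)")
  if (object@motifPlantingRate < 0 || object@motifPlantingRate > 1)
    msgs <- c(msgs, "motifPlantingRate must lie in [0, 1]")
  if (object@nGenes < 1L)
    msgs <- c(msgs, "nGenes must be >= 1")
  if (object@chromLength < 10L * object@broadDomainHalfwidth)
    msgs <- c(msgs, "chromLength must be >= 10 * broadDomainHalfwidth")
  if (abs(sum(object@categoryProps) - 1) > 1e-6)
    msgs <- c(msgs, "categoryProps must sum to 1")
  if (!all(c("characterized", "chip_defined") %in%
           names(object@enhancerCounts)))
    msgs <- c(msgs, "enhancerCounts needs 'characterized' and 'chip_defined'")
  if (!grepl("^[ACGT]+$", object@motifConsensus))
    msgs <- c(msgs, "motifConsensus must be a non-empty ACGT string")
  if (object@nPresBound > object@nPres)
    msgs <- c(msgs, "nPresBound cannot exceed nPres")
  if (length(msgs)) msgs else TRUE
})
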