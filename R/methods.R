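# Accessors and show methods.

#' @rdname SignalTrack-class
#' @export
setMethod("binWidth", "SignalTrack", function(x) x@binWidth)

#' @rdname SignalTrack-class
#' @export
setMethod("trackValues", "SignalTrack", function(x, chrom) {
  if (missing(chrom)) x@values else x@values[[chrom]]
})

#' @rdname SignalTrack-class
#' @export
setMethod("chromLengths", "SignalTrack", function(x) x@seqlengths)

#' @rdname SignalTrack-class
#' @export
setMethod("trackLabel", "SignalTrack", function(x) x@label)

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack '%s': %d chromosome(s), %d-bp bins\n",
              object@label, length(object@values), object@binWidth))
  for (chrom in head(names(object@values), 5)) {
    v <- object@values[[chrom]]
    cat(sprintf("  %s: %d bins, mean %.4g\n", chrom, length(v), mean(v)))
  }
})

#' @rdname CoboundSet-class
#' @export
setMethod("coboundRegions", "CoboundSet", function(x) x@cobound)

#' @rdname CoboundSet-class
#' @export
setMethod("phoOnly", "CoboundSet", function(x) x@phoOnly)

#' @rdname CoboundSet-class
#' @export
setMethod("sfmbtOnly", "CoboundSet", function(x) x@sfmbtOnly)

#' @rdname CoboundSet-class
#' @export
setMethod("coboundCounts", "CoboundSet", function(x) {
  c(cobound_regions = length(x@cobound),
    pho_cobound = x@phoCoboundCount,
    sfmbt_cobound = x@sfmbtCoboundCount,
    pho_only = length(x@phoOnly),
    sfmbt_only = length(x@sfmbtOnly),
    pho_total = x@phoCoboundCount + length(x@phoOnly),
    sfmbt_total = x@sfmbtCoboundCount + length(x@sfmbtOnly))
})

setMethod("show", "CoboundSet", function(object) {
  ct <- coboundCounts(object)
  cat(sprintf(paste0(
    "CoboundSet: %d co-bound regions (%d/%d first-factor peaks,",
    " %d/%d second-factor peaks)\n"),
    ct[["cobound_regions"]], ct[["pho_cobound"]], ct[["pho_total"]],
    ct[["sfmbt_cobound"]], ct[["sfmbt_total"]]))
})

#' @rdname MetaProfile-class
#' @export
setMethod("profileMatrix", "MetaProfile", function(x) x@matrix)

#' @rdname MetaProfile-class
#' @export
setMethod("summaryCurve", "MetaProfile", function(x) x@summary)

#' @rdname MetaProfile-class
#' @export
setMethod("confidenceBands", "MetaProfile", function(x) {
  if (!length(x@ciLower)) return(NULL)
  data.frame(lower = x@ciLower, upper = x@ciUpper)
})

setMethod("show", "MetaProfile", function(object) {
  cat(sprintf(
    "MetaProfile '%s': %d regions x %d bins (+/- %d bp at %d bp)\n",
    object@label, nrow(object@matrix), ncol(object@matrix),
    object@windowHalfwidth, object@binWidth))
})

#' @rdname MotifModel-class
#' @export
setMethod("motifMatrix", "MotifModel", function(x) x@matrix)

#' @rdname MotifModel-class
#' @export
setMethod("motifBackground", "MotifModel", function(x) x@background)

#' @rdname MotifModel-class
#' @export
setMethod("motifWidth", "MotifModel", function(x) ncol(x@matrix))

#' @rdname MotifModel-class
#' @export
setMethod("motifConsensus", "MotifModel", function(x) {
  paste(rownames(x@matrix)[apply(x@matrix, 2, which.max)], collapse = "")
})

#' @rdname MotifModel-class
#' @export
setMethod("informationContent", "MotifModel", function(x) {
  # mean per-position relative entropy (bits) vs the background
  ic <- colSums(x@matrix * log2(x@matrix / x@background))
  mean(ic)
})

#' @rdname reverseComplementMotif
#' @export
setMethod("reverseComplementMotif", "MotifModel", function(x) {
  m <- x@matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(x@matrix))),
                drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  bg <- x@background[c(4, 3, 2, 1)]
  names(bg) <- c("A", "C", "G", "T")
  new("MotifModel", matrix = m, background = bg,
      pseudocount = x@pseudocount)
})

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel: width %d, consensus %s, IC %.2f bits/position\n",
              motifWidth(object), motifConsensus(object),
              informationContent(object)))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: log2 OR = %.3f%s, p = %.4g\n",
    object@log2OddsRatio,
    if (object@correctionApplied) " (Haldane-Anscombe corrected)" else "",
    object@pValue))
  print(object@table)
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0(
    "SyntheticConfig: %d chromosome(s) x %d bp, %d genes,",
    " %d Pho / %d dSfmbt peaks, cobound fraction %.2f,",
    " repressed-promoter fraction %.3f, seed %d\n"),
    object@nChromosomes, object@chromLength, object@nGenes,
    object@nPhoPeaks, object@nSfmbtPeaks, object@coboundFraction,
    object@fracRepressedPromoters, object@seed))
})
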