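#' @rdname SignalTrack-class
#' @param x a SignalTrack (or other object with a bin width)
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname SignalTrack-class
#' @param chrom optional chromosome name; if omitted the full list
#' @export
setGeneric("trackValues", function(x, chrom) standardGeneric("trackValues"))

#' @rdname SignalTrack-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname SignalTrack-class
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))

#' @rdname CoboundSet-class
#' @param x a CoboundSet
#' @export
setGeneric("coboundRegions", function(x) standardGeneric("coboundRegions"))

#' @rdname CoboundSet-class
#' @export
setGeneric("phoOnly", function(x) standardGeneric("phoOnly"))

#' @rdname CoboundSet-class
#' @export
setGeneric("sfmbtOnly", function(x) standardGeneric("sfmbtOnly"))

#' @rdname CoboundSet-class
#' @export
setGeneric("coboundCounts", function(x) standardGeneric("coboundCounts"))

#' @rdname MetaProfile-class
#' @param x a MetaProfile
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname MetaProfile-class
#' @export
setGeneric("summaryCurve", function(x) standardGeneric("summaryCurve"))

#' @rdname MetaProfile-class
#' @export
setGeneric("confidenceBands", function(x) standardGeneric("confidenceBands"))

#' @rdname MotifModel-class
#' @param x a MotifModel
#' @export
setGeneric("motifMatrix", function(x) standardGeneric("motifMatrix"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname MotifModel-class
#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))

#' @rdname MotifModel-class
#' @export
setGeneric("informationContent",
           function(x) standardGeneric("informationContent"))

#' Reverse complement of a motif model
#'
#' @param x a MotifModel
#' @return a MotifModel scoring the reverse-complement strand
#' @export
setGeneric("reverseComplementMotif",
           function(x) standardGeneric("reverseComplementMotif"))
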