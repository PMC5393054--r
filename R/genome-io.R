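#' Read a two-column chrom.sizes file
#'
#' @param path file with chromosome name and length per line (tab-separated)
#' @return named integer vector of chromosome lengths
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path))
    polycreStop("polycre_io_error", "file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  setNames(df$length, df$chrom)
}

#' @rdname readChromSizes
#' @param sizes named integer vector
#' @export
writeChromSizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), unname(sizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into GRanges
#'
#' BED coordinates are 0-based half-open; the returned GRanges uses the
#' usual 1-based closed convention.  Input order is preserved.  Lines with
#' fewer than three tab-separated fields, non-numeric coordinates, or
#' start >= end raise a validation error naming the offending line.
#'
#' @param path BED3/BED6 file
#' @param chromSizes optional named lengths; if given, records are checked
#'   against chromosome bounds and seqlengths are set
#' @return GRanges with optional \code{name} and \code{score} metadata
#' @export
readBed <- function(path, chromSizes = NULL) {
  if (!file.exists(path))
    polycreStop("polycre_io_error", "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(chromSizes)) {
      GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
      GenomeInfoDb::seqlengths(gr) <- chromSizes
    }
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    polycreStop("polycre_parse_error",
                "line %d: expected >= 3 tab-separated fields, got %d",
                which(nf < 3L)[1], nf[which(nf < 3L)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    polycreStop("polycre_parse_error",
                "line %d: non-numeric coordinates", bad[1])
  bad <- which(start0 >= end0 | start0 < 0L)
  if (length(bad))
    polycreStop("polycre_validation_error",
                "line %d: invalid interval [%d, %d)",
                bad[1], start0[bad[1]], end0[bad[1]])
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(nf >= 5L, vapply(
    fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_,
    ""), NA_character_)))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f)
    if (length(f) >= 6L) f[[6L]] else "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  if (!is.null(chromSizes)) {
    unknown <- setdiff(unique(chrom), names(chromSizes))
    if (length(unknown))
      polycreStop("polycre_validation_error",
                  "chromosome %s not in size table", unknown[1])
    over <- which(end0 > chromSizes[chrom])
    if (length(over))
      polycreStop("polycre_validation_error",
                  "line %d: interval end %d beyond chromosome %s (%d bp)",
                  over[1], end0[over[1]], chrom[over[1]],
                  chromSizes[[chrom[over[1]]]])
  }
  gr <- granges0(chrom, start0, end0, strand = strand,
                 seqlengths = chromSizes)
  if (any(!is.na(name))) gr$name <- name
  if (any(!is.na(score))) gr$score <- score
  gr
}

#' Write GRanges to a BED file (0-based half-open)
#'
#' @param gr GRanges, optionally with \code{name} and \code{score} columns
#' @param path output path
#' @export
writeBed <- function(gr, path) {
  n <- length(gr)
  name <- if (!is.null(gr$name)) gr$name else paste0("region", seq_len(n))
  score <- if (!is.null(gr$score)) gr$score else rep(0, n)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                 as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr),
                 name, format(score, trim = TRUE, digits = 10), strand)
  writeLines(out, path)
  invisible(path)
}

#' Construct a SignalTrack
#'
#' @param values named list of per-chromosome numeric vectors
#' @param binWidth bin size in bp
#' @param seqlengths named chromosome lengths
#' @param label track label
#' @export
SignalTrack <- function(values, binWidth, seqlengths,
                        label = "signal") {
  new("SignalTrack", values = values, binWidth = as.integer(binWidth),
      seqlengths = setNames(as.integer(seqlengths), names(seqlengths)),
      label = label)
}

#' Read a bedGraph file onto fixed bins
#'
#' Records are mapped onto bins of \code{binWidth} by coverage-weighted
#' mean (bedGraph values are per-base): a record covering a fraction of a
#' bin contributes its value weighted by the covered fraction; uncovered
#' parts of a bin contribute zero.  Records beyond chromosome bounds are a
#' validation error.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open)
#' @param binWidth bin size in bp
#' @param chromSizes named chromosome lengths
#' @param label track label
#' @return a \linkS4class{SignalTrack}
#' @export
readBedGraph <- function(path, binWidth, chromSizes, label = "signal") {
  if (!file.exists(path))
    polycreStop("polycre_io_error", "file not found: %s", path)
  empty <- lapply(chromSizes, function(L)
    numeric(ceiling(L / binWidth)))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(SignalTrack(empty, binWidth, chromSizes, label))
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  if (!nrow(df))
    return(SignalTrack(empty, binWidth, chromSizes, label))
  unknown <- setdiff(unique(df$chrom), names(chromSizes))
  if (length(unknown))
    polycreStop("polycre_validation_error",
                "chromosome %s not in size table", unknown[1])
  if (any(df$start < 0L) || any(df$end > chromSizes[df$chrom]))
    polycreStop("polycre_validation_error",
                "bedGraph record beyond chromosome bounds")
  if (any(df$start >= df$end))
    polycreStop("polycre_validation_error",
                "bedGraph record with start >= end")
  values <- empty
  for (chrom in unique(df$chrom)) {
    sub <- df[df$chrom == chrom, , drop = FALSE]
    L <- chromSizes[[chrom]]
    # per-bp coverage-weighted values via Rle coverage, then binned means
    cov <- IRanges::coverage(
      IRanges::IRanges(sub$start + 1L, sub$end),
      weight = sub$value, width = L)
    nbin <- ceiling(L / binWidth)
    tiles <- IRanges::IRanges(
      start = (seq_len(nbin) - 1L) * binWidth + 1L,
      end = pmin(seq_len(nbin) * binWidth, L))
    sums <- IRanges::viewSums(IRanges::Views(cov, tiles))
    values[[chrom]] <- as.numeric(sums) / binWidth
  }
  SignalTrack(values, binWidth, chromSizes, label)
}

#' Write a SignalTrack as bedGraph
#'
#' One record per bin (zero bins included), 0-based half-open.
#'
#' @param track a SignalTrack
#' @param path output path
#' @export
writeBedGraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track@values)) {
    v <- track@values[[chrom]]
    n <- length(v)
    starts <- (seq_len(n) - 1L) * track@binWidth
    ends <- pmin(seq_len(n) * track@binWidth, track@seqlengths[[chrom]])
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, starts, ends, v), con)
  }
  invisible(path)
}

#' Subtract one track from another
#'
#' Elementwise \code{a - b}; used for input- and H3-subtracted ChIP
#' signal.  Negative values are clipped to zero by default.
#'
#' @param a,b SignalTracks with identical bin width and chromosomes
#' @param floorAtZero clip negative differences to 0
#' @return a SignalTrack labelled "a - b"
#' @export
subtractTracks <- function(a, b, floorAtZero = TRUE) {
  if (a@binWidth != b@binWidth ||
      !setequal(names(a@values), names(b@values)) ||
      !identical(a@seqlengths[names(a@values)],
                 b@seqlengths[names(a@values)]))
    polycreStop("polycre_shape_error",
                "tracks differ in bin width or chromosome set")
  values <- lapply(names(a@values), function(chrom) {
    d <- a@values[[chrom]] - b@values[[chrom]]
    if (floorAtZero) pmax(d, 0) else d
  })
  names(values) <- names(a@values)
  SignalTrack(values, a@binWidth, a@seqlengths,
              label = paste(a@label, "-", b@label))
}

# Integral of the track's per-bp signal over 0-based [a, b) on one
# chromosome.  The track is piecewise constant per bin, so the cumulative
# mass is piecewise linear and partial bins are exact.  Vectorized over
# a/b.
trackIntegral <- function(track, chrom, a, b) {
  v <- track@values[[chrom]]
  if (is.null(v))
    polycreStop("polycre_validation_error",
                "chromosome %s not on track", chrom)
  bw <- track@binWidth
  L <- track@seqlengths[[chrom]]
  a <- pmax(pmin(a, L), 0)
  b <- pmax(pmin(b, L), 0)
  cum <- c(0, cumsum(as.numeric(v) * bw))
  Fx <- function(x) {
    i <- pmin(floor(x / bw), length(v) - 1L)
    cum[i + 1L] + v[i + 1L] * (x - i * bw)
  }
  Fx(b) - Fx(a)
}

#' Read / write gene models
#'
#' Gene models are a TSV with columns chrom, start, end, strand, gene_id,
#' length; start is 0-based, end exclusive (BED-like).  The returned
#' GRanges carries \code{gene_id} metadata and a \code{tss} column with
#' the 0-based TSS (start for + genes, end - 1 for - genes).
#'
#' @param path TSV path
#' @param chromSizes optional named chromosome lengths
#' @return GRanges of gene bodies
#' @export
readGeneModels <- function(path, chromSizes = NULL) {
  if (!file.exists(path))
    polycreStop("polycre_io_error", "file not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer", "integer",
                                  "character", "character", "integer"))
  if (any(df$start >= df$end))
    polycreStop("polycre_validation_error",
                "gene model with start >= end")
  gr <- granges0(df$chrom, df$start, df$end, strand = df$strand,
                 seqlengths = chromSizes)
  gr$gene_id <- df$gene_id
  gr$tss <- tss0(gr)
  gr
}

#' @rdname readGeneModels
#' @param genes GRanges with gene_id metadata
#' @export
writeGeneModels <- function(genes, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    gene_id = genes$gene_id,
    length = GenomicRanges::width(genes)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-level expression counts
#'
#' TSV with columns gene_id, count, length and optionally library_size
#' (total mapped reads; constant per row).  Without a library_size
#' column, callers typically fall back to the sum of counts.
#'
#' @param path TSV path
#' @return data.frame with gene_id, count, length (, library_size)
#' @export
readExpressionCounts <- function(path) {
  if (!file.exists(path))
    polycreStop("polycre_io_error", "file not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  df$gene_id <- as.character(df$gene_id)
  df
}

#' @rdname readExpressionCounts
#' @param counts data.frame with gene_id, count, length and optional
#'   library_size
#' @export
writeExpressionCounts <- function(counts, path) {
  keep <- intersect(c("gene_id", "count", "length", "library_size"),
                    names(counts))
  write.table(counts[, keep], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
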