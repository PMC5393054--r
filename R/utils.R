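# Internal helpers shared across modules.

# Run `expr` under a private RNG stream: if `seed` is non-NULL, the global
# .Random.seed is saved, the stream reseeded, and the previous state
# restored afterwards, so seeded operations do not perturb callers.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# 0-based midpoint of GRanges regions: floor((start0 + end0) / 2).
midpoint0 <- function(gr) {
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)  # end0 exclusive == 1-based closed end
  as.integer(floor((start0 + end0) / 2))
}

# 0-based TSS of gene models (GRanges with strand): start0 for '+',
# end0 - 1 for '-'.
tss0 <- function(genes) {
  s <- as.character(GenomicRanges::strand(genes))
  ifelse(s == "-",
         GenomicRanges::end(genes) - 1L,
         GenomicRanges::start(genes) - 1L)
}

# Build a GRanges from 0-based half-open coordinates.
granges0 <- function(chrom, start0, end0, strand = "*", seqlengths = NULL,
                     ...) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    ...
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# Largest-remainder apportionment of `n` into parts proportional to `props`.
apportion <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# sample() without the scalar-x surprise: always samples elements of x.
resample <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size, ...)]
}

# Stop with a classed error so callers/tests can match on condition class.
polycreStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "polycreError", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
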