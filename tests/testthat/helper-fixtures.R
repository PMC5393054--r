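# Shared fixtures and independent oracles used across the suite.

# GRanges from 0-based half-open coordinates (test shorthand)
gr0 <- function(chrom, start0, end0, strand = "*", ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start0 + 1L, end0),
                         strand = strand, ...)
}

# a tiny gene model GRanges with tss metadata
mkGenes <- function(chrom, start0, end0, strand, ids = NULL) {
  g <- gr0(chrom, start0, end0, strand)
  g$gene_id <- if (is.null(ids)) sprintf("g%02d", seq_along(g)) else ids
  g$tss <- ifelse(strand == "-", end0 - 1L, start0)
  g
}

# one-chromosome SignalTrack from a plain vector
mkTrack <- function(values, binWidth = 25L, chromLength = NULL,
                    chrom = "chr1", label = "test") {
  if (is.null(chromLength)) chromLength <- length(values) * binWidth
  SignalTrack(setNames(list(values), chrom), binWidth,
              setNames(chromLength, chrom), label)
}

# random ACGT sequences, optionally with a consensus planted once at a
# random position on a random strand
randomSequences <- function(n, len, plant = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (!is.null(plant)) {
      ins <- if (runif(1) < 0.5) plant else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(plant)))
      p <- sample.int(len - nchar(ins) + 1L, 1L)
      s[p:(p + nchar(ins) - 1L)] <- strsplit(ins, "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))
}

# best ungapped overlap-alignment match count between a discovered
# consensus and the planted consensus, over both orientations and all
# registrations (EM models are frequently registered +/- 1 position)
consensusMatchCount <- function(cons, planted) {
  score1 <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    na <- length(ca); nb <- length(cb)
    best <- 0L
    for (off in seq(-nb + 1L, na - 1L)) {
      ia <- max(1L, off + 1L):min(na, off + nb)
      ib <- ia - off
      best <- max(best, sum(ca[ia] == cb[ib]))
    }
    best
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  max(score1(cons, planted), score1(rc, planted))
}

# --- independent oracles -----------------------------------------------

# hypergeometric two-sided p by explicit factorial enumeration
# (lchoose arithmetic, no dhyper)
fisherOracleP <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) -
    lchoose(n, r1)
  probs <- exp(logp)
  pObs <- probs[support == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# brute-force exact two-sided Mann-Whitney p over all C(n+m, n)
# assignments of the pooled values
mwuOracleP <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  uOf <- function(xv, yv)
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  uObs <- uOf(x, y)
  mid <- n * m / 2
  idx <- utils::combn(n + m, n)
  devs <- apply(idx, 2, function(ix)
    abs(uOf(pooled[ix], pooled[-ix]) - mid))
  mean(devs >= abs(uObs - mid) - 1e-9)
}

# O(n*m) brute-force co-occupancy: indices of first-set peaks
# overlapping any second-set peak by >= 1 bp
coboundOracle <- function(first, second) {
  hits <- logical(length(first))
  for (i in seq_along(first)) {
    for (j in seq_along(second)) {
      same <- as.character(GenomicRanges::seqnames(first[i])) ==
        as.character(GenomicRanges::seqnames(second[j]))
      ov <- min(GenomicRanges::end(first[i]),
                GenomicRanges::end(second[j])) -
        max(GenomicRanges::start(first[i]),
            GenomicRanges::start(second[j])) + 1L
      if (same && ov >= 1L) { hits[i] <- TRUE; break }
    }
  }
  which(hits)
}

# brute-force PWM scan over every window of both strands
scanOracle <- function(seq, motif, threshold) {
  bases <- c("A", "C", "G", "T")
  lo <- log2(motifMatrix(motif) / motifBackground(motif))
  w <- motifWidth(motif)
  chars <- strsplit(seq, "")[[1]]
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[chars])
  out <- data.frame(position = integer(0), strand = character(0),
                    score = numeric(0))
  n <- length(chars)
  if (n < w) return(out)
  for (j in seq_len(n - w + 1L)) {
    win <- chars[j:(j + w - 1L)]
    if (all(win %in% bases)) {
      sc <- sum(vapply(seq_len(w), function(k) lo[win[k], k], numeric(1)))
      if (sc >= threshold)
        out <- rbind(out, data.frame(position = j, strand = "+",
                                     score = sc))
    }
    winR <- rc[j:(j + w - 1L)]
    if (all(winR %in% bases)) {
      sc <- sum(vapply(seq_len(w), function(k) lo[winR[k], k],
                       numeric(1)))
      if (sc >= threshold)
        out <- rbind(out, data.frame(position = n - w + 2L - j,
                                     strand = "-", score = sc))
    }
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

# small synthetic config used by module tests (fast to generate)
smallConfig <- function(...) {
  syntheticConfig(nGenes = 60L, nPhoPeaks = 30L, nSfmbtPeaks = 60L,
                  chromLength = 4000000L,
                  enhancerCounts = c(characterized = 15L,
                                     chip_defined = 30L),
                  nPres = 10L, nPresBound = 8L, ...)
}
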