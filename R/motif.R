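# De novo motif discovery (ZOOPS expectation-maximization) and PWM
# scanning, used to verify direct Pho recruitment potential at bound
# elements.

BASES <- c("A", "C", "G", "T")

# character sequence -> integer codes 1..4 (A C G T), NA for anything else
encodeSeq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], BASES)
}

decodeSeq <- function(code) paste(BASES[code], collapse = "")

revcompCode <- function(code) rev(5L - code)

asCharacterSequences <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else {
    out <- as.character(sequences)
  }
  toupper(out)
}

#' Construct a MotifModel
#'
#' @param matrix 4 x width matrix (rows A, C, G, T); columns are
#'   normalized to sum to 1
#' @param background base frequencies (default uniform)
#' @param pseudocount total pseudocount mass per column, split by
#'   background frequency (default 0.01)
#' @export
MotifModel <- function(matrix, background = rep(0.25, 4),
                       pseudocount = 0.01) {
  stopifnot(nrow(matrix) == 4)
  rownames(matrix) <- BASES
  names(background) <- BASES
  m <- sweep(matrix + pseudocount * background, 2,
             colSums(matrix) + pseudocount, "/")
  new("MotifModel", matrix = m, background = background,
      pseudocount = pseudocount)
}

# Fit a first-order Markov chain to a coded sequence and resample a
# sequence of the same length from it: a dinucleotide-composition
# preserving shuffle used only for seed-enrichment background.
markovShuffle <- function(code) {
  n <- length(code)
  if (n < 2) return(code)
  trans <- matrix(1e-6, 4, 4)
  for (i in seq_len(n - 1))
    trans[code[i], code[i + 1]] <- trans[code[i], code[i + 1]] + 1
  trans <- trans / rowSums(trans)
  out <- integer(n)
  out[1] <- code[1]
  for (i in 2:n)
    out[i] <- sample.int(4L, 1L, prob = trans[out[i - 1], ])
  out
}

# Count k-mers (forward strand) in a list of coded sequences.
countKmers <- function(codes, k) {
  pow <- 4^(seq_len(k) - 1)
  allIdx <- unlist(lapply(codes, function(code) {
    n <- length(code)
    if (n < k) return(numeric(0))
    # integer encoding of every k-mer window, vectorized by offset
    nw <- n - k + 1L
    idx <- numeric(nw)
    for (j in seq_len(k))
      idx <- idx + (code[j:(j + nw - 1L)] - 1) * pow[j]
    idx
  }))
  table(allIdx)
}

kmerFromIndex <- function(idx, k) {
  code <- integer(k)
  for (j in seq_len(k)) {
    code[j] <- idx %% 4L + 1L
    idx <- idx %/% 4L
  }
  code
}

# ZOOPS EM refinement of a seed PWM on coded sequences (both strands).
# Returns list(pwm matrix 4 x w, gamma, logLik, sites data.frame).
zoopsEm <- function(codes, seedPwm, background, pseudocount,
                    maxIter = 100L, tol = 1e-4) {
  w <- ncol(seedPwm)
  nSeq <- length(codes)
  logBg <- log(background)
  # Per-sequence flattened (base, position) index vectors for every
  # window on both strands: gid = base + 4*(pos-1), column-major over
  # windows.  The same indices serve the E step (PWM lookup) and the M
  # step (rowsum accumulation).
  windows <- lapply(codes, function(code) {
    n <- length(code)
    nw <- n - w + 1L
    posOff <- 4L * (seq_len(w) - 1L)
    gidOne <- function(cd) {
      m <- vapply(seq_len(w), function(j) cd[j:(j + nw - 1L)],
                  integer(nw))           # nw x w
      as.vector(t(m) + rep(posOff, times = nw))  # w-major per window
    }
    rc <- revcompCode(code)
    list(gidF = gidOne(code), gidR = gidOne(rc), nw = nw)
  })
  pwm <- seedPwm
  gamma <- 0.5
  ll <- -Inf
  zs <- vector("list", nSeq)
  for (iter in seq_len(maxIter)) {
    logRatioVec <- as.vector(log(pwm) - matrix(logBg, 4, w))
    llNew <- 0
    for (i in seq_len(nSeq)) {
      wd <- windows[[i]]
      lrF <- colSums(matrix(logRatioVec[wd$gidF], nrow = w))
      lrR <- colSums(matrix(logRatioVec[wd$gidR], nrow = w))
      lr <- exp(c(lrF, lrR))
      m2 <- 2 * wd$nw
      denom <- (1 - gamma) + gamma * sum(lr) / m2
      zs[[i]] <- gamma * lr / m2 / denom
      llNew <- llNew + log(denom)
    }
    if (llNew < ll - 1e-8)
      stop("internal error: ZOOPS log-likelihood decreased")
    converged <- abs(llNew - ll) < tol
    ll <- llNew
    # M step: weighted base counts (reverse windows are already in motif
    # orientation through the reverse-complemented indices)
    counts <- matrix(0, 4, w)
    gammaNew <- 0
    for (i in seq_len(nSeq)) {
      wd <- windows[[i]]
      z <- zs[[i]]
      wts <- rep(z, each = w)
      agg <- rowsum(wts, c(wd$gidF, wd$gidR))
      counts[as.integer(rownames(agg))] <-
        counts[as.integer(rownames(agg))] + agg[, 1]
      gammaNew <- gammaNew + sum(z)
    }
    pwm <- sweep(counts + pseudocount * background, 2,
                 colSums(counts) + pseudocount, "/")
    gamma <- min(max(gammaNew / nSeq, 1e-4), 1 - 1e-4)
    if (converged) break
  }
  # best site per sequence from the final responsibilities
  sites <- do.call(rbind, lapply(seq_len(nSeq), function(i) {
    wd <- windows[[i]]
    z <- zs[[i]]
    j <- which.max(z)
    if (j <= wd$nw)
      data.frame(sequence = i, position = j, strand = "+",
                 responsibility = z[j])
    else
      data.frame(sequence = i, position = wd$nw - (j - wd$nw) + 1L,
                 strand = "-", responsibility = z[j])
  }))
  list(pwm = pwm, gamma = gamma, logLik = ll, sites = sites)
}

#' De novo motif discovery by seeded ZOOPS expectation-maximization
#'
#' Seeds are the top \code{nSeeds} most enriched (width - 2)-mers versus
#' a dinucleotide-shuffled background of the same sequences; each seed is
#' refined by EM under a zero-or-one-occurrence-per-sequence (ZOOPS)
#' model on both strands until the log-likelihood improves by less than
#' \code{tol} or \code{maxIter} iterations.  The highest-likelihood
#' refined model is returned.
#'
#' @param sequences character vector or DNAStringSet (>= 10 sequences,
#'   each at least \code{width} long)
#' @param width motif width (default 8)
#' @param seed RNG seed (shuffling background; local to this call)
#' @param nSeeds number of k-mer seeds refined (default 5)
#' @param pseudocount total pseudocount mass per PWM column (default
#'   0.01, split by background frequency)
#' @param maxIter,tol EM stopping rule
#' @return list with \code{motif} (a \linkS4class{MotifModel}),
#'   \code{sites} (per-sequence best site), \code{logLik}, \code{gamma}
#' @export
discoverMotif <- function(sequences, width = 8L, seed = 1L, nSeeds = 5L,
                          pseudocount = 0.01, maxIter = 100L,
                          tol = 1e-4) {
  seqs <- asCharacterSequences(sequences)
  if (length(seqs) < 10L)
    polycreStop("polycre_validation_error",
                "need at least 10 sequences, got %d", length(seqs))
  short <- which(nchar(seqs) < width)
  if (length(short))
    polycreStop("polycre_validation_error",
                "sequences shorter than motif width %d: %s", width,
                paste(short, collapse = ", "))
  codes <- lapply(seqs, encodeSeq)
  if (any(vapply(codes, anyNA, logical(1))))
    polycreStop("polycre_validation_error",
                "sequences must contain only A/C/G/T for discovery")
  baseCounts <- table(factor(unlist(codes), levels = 1:4))
  background <- as.numeric(baseCounts) / sum(baseCounts)
  names(background) <- BASES
  k <- width - 2L
  withSeed(seed, {
    # seed enrichment: observed k-mers (both strands) vs shuffled copies
    codesBoth <- c(codes, lapply(codes, revcompCode))
    fg <- countKmers(codesBoth, k)
    shuffled <- lapply(codesBoth, markovShuffle)
    bg <- countKmers(shuffled, k)
    allKeys <- names(fg)
    bgc <- as.integer(bg[allKeys])
    bgc[is.na(bgc)] <- 0L
    score <- (as.integer(fg) + 1) / (bgc + 1)
    topKeys <- allKeys[order(score, decreasing = TRUE)][
      seq_len(min(nSeeds, length(allKeys)))]
    best <- NULL
    for (key in topKeys) {
      kmer <- kmerFromIndex(as.numeric(key), k)
      # seed PWM: k-mer centered in `width` columns, 0.8 point mass
      seedPwm <- matrix(background, 4, width)
      off <- (width - k) %/% 2L
      for (j in seq_len(k)) {
        col <- rep((1 - 0.8) / 3, 4)
        col[kmer[j]] <- 0.8
        seedPwm[, off + j] <- col
      }
      fit <- zoopsEm(codes, seedPwm, background, pseudocount,
                     maxIter = maxIter, tol = tol)
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    motif <- new("MotifModel",
                 matrix = {
                   m <- best$pwm
                   rownames(m) <- BASES
                   m
                 },
                 background = background, pseudocount = pseudocount)
    list(motif = motif, sites = best$sites, logLik = best$logLik,
         gamma = best$gamma)
  })
}

#' Scan a sequence with a PWM
#'
#' Log-odds score of each window: sum of log2(p_pos(base) /
#' background(base)).  Both strands are scanned; windows containing N (or
#' any non-ACGT base) are skipped.  Hits with score >= threshold are
#' returned sorted by position (1-based window start on the forward
#' strand).
#'
#' @param sequence a single character string or DNAString
#' @param motif a \linkS4class{MotifModel}
#' @param scoreThreshold minimum log-odds score in bits
#' @return data.frame with position, strand, score
#' @export
scanPwm <- function(sequence, motif, scoreThreshold) {
  s <- asCharacterSequences(sequence)[1]
  code <- encodeSeq(s)
  w <- motifWidth(motif)
  n <- length(code)
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < w) return(empty)
  lo <- log2(motif@matrix / motif@background)
  nw <- n - w + 1L
  scoreAt <- function(codeVec) {
    vapply(seq_len(nw), function(j) {
      win <- codeVec[j:(j + w - 1L)]
      if (anyNA(win)) return(NA_real_)
      sum(lo[cbind(win, seq_len(w))])
    }, numeric(1))
  }
  fwd <- scoreAt(code)
  rcCode <- revcompCode(code)
  revScores <- scoreAt(rcCode)
  # map reverse-strand window j (on revcomp) back to forward coordinates
  revPos <- n - w + 2L - seq_len(nw)
  hits <- rbind(
    data.frame(position = seq_len(nw), strand = "+", score = fwd),
    data.frame(position = revPos, strand = "-", score = revScores))
  hits <- hits[!is.na(hits$score) & hits$score >= scoreThreshold, ]
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

#' Motif enrichment of foreground vs background sequences
#'
#' Counts sequences with at least one PWM hit at the threshold in each
#' set, builds the 2x2 table and applies \code{\link{fisherExact}}.
#'
#' @param fgSequences,bgSequences character vectors or DNAStringSets
#' @param motif a \linkS4class{MotifModel}
#' @param scoreThreshold log-odds threshold in bits
#' @return list with fgFraction, bgFraction, enrichment
#'   (\linkS4class{EnrichmentResult} or NULL when the table is
#'   degenerate with a zero margin)
#' @export
motifEnrichment <- function(fgSequences, bgSequences, motif,
                            scoreThreshold) {
  fg <- asCharacterSequences(fgSequences)
  bg <- asCharacterSequences(bgSequences)
  stopifnot(length(fg) > 0, length(bg) > 0)
  hasHit <- function(s)
    nrow(scanPwm(s, motif, scoreThreshold)) > 0
  fgHits <- sum(vapply(fg, hasHit, logical(1)))
  bgHits <- sum(vapply(bg, hasHit, logical(1)))
  tab <- matrix(c(fgHits, length(fg) - fgHits,
                  bgHits, length(bg) - bgHits), 2, 2, byrow = TRUE)
  enr <- tryCatch(fisherExact(tab),
                  polycre_undefined_test = function(e) NULL)
  list(fgFraction = fgHits / length(fg),
       bgFraction = bgHits / length(bg),
       enrichment = enr, table = tab)
}

#' Write a motif in MEME minimal format
#'
#' @param motif a \linkS4class{MotifModel}
#' @param path output path
#' @param name motif name in the file
#' @param nsites number of contributing sites recorded in the header
#' @export
writeMemeMotif <- function(motif, path, name = "motif1", nsites = 20L) {
  m <- motif@matrix
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", BASES, motif@background), collapse = " "),
    "",
    sprintf("MOTIF %s", name),
    sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(m), nsites),
    vapply(seq_len(ncol(m)), function(j)
      paste(sprintf("%.6f", m[, j]), collapse = "  "), character(1)))
  writeLines(lines, path)
  invisible(path)
}
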