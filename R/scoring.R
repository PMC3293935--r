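#' Bounded base-2 logarithm
#'
#' log2(x) for x > exp(2c); for x <= exp(2c) the tangent line to log2 at
#' x0 = exp(2c), which keeps the function continuous, differentiable at the
#' junction, monotone non-decreasing, and finite at x = 0. Used in place of
#' pseudocounts to bound log-odds matrix entries from below.
#'
#' @param x non-negative numeric vector.
#' @param c bounding constant; the junction sits at x0 = exp(2c) where the
#'   value is 2c*log2(e). Default -3.
#' @return numeric vector, same length as `x`.
#' @examples
#' boundedLog(1)            # 0
#' boundedLog(0)            # finite: (2*(-3) - 1) * log2(exp(1))
#' @export
boundedLog <- function(x, c = -3) {
  if (any(x < 0)) stop("boundedLog is defined for x >= 0 only")
  x0 <- exp(2 * c)
  out <- x                      # keeps dim/dimnames for matrix input
  hi <- x > x0
  out[hi] <- log2(x[hi])
  # tangent to log2 at x0: log2(x0) + (x - x0) / (x0 * ln 2)
  out[!hi] <- 2 * c * log2(exp(1)) + (x[!hi] - x0) / (x0 * log(2))
  out
}

#' Genome background nucleotide frequencies
#'
#' Estimates the A/C/G/T probabilities from a genome, pooling both strands
#' (which forces A=T and C=G) and ignoring N and other ambiguity codes.
#'
#' @param genome a [Biostrings::DNAStringSet] (or DNAString).
#' @param bothStrands pool the reverse complement (default TRUE).
#' @return named numeric length-4 vector summing to 1.
#' @export
backgroundFrequencies <- function(genome, bothStrands = TRUE) {
  if (is(genome, "DNAString")) genome <- Biostrings::DNAStringSet(genome)
  counts <- colSums(Biostrings::alphabetFrequency(genome)[, DNA_BASES4,
                                                          drop = FALSE])
  if (bothStrands) counts <- counts + rev(counts)  # A<->T, C<->G
  if (sum(counts) == 0) stop("genome contains no unambiguous bases")
  freqs <- counts / sum(counts)
  if (any(freqs == 0))
    stop("background frequency of zero; supply 'background' explicitly")
  freqs
}

#' Build a bounded log-odds matrix from a motif matrix
#'
#' Each entry is f(q_ij / b_i) with f = [boundedLog()], where q_ij is the
#' probability of base i at position j and b_i the genome background
#' probability of base i. Zero probabilities are legal: they land on the
#' linear branch of f.
#'
#' @param motif a [MotifMatrix-class].
#' @param background length-4 background probabilities (named or in A,C,G,T
#'   order), e.g. from [backgroundFrequencies()].
#' @param c bounding constant, default -3.
#' @return a [LogOddsMatrix-class].
#' @export
buildLogOddsMatrix <- function(motif, background = rep(0.25, 4), c = -3) {
  b <- as.numeric(background)
  if (length(b) != 4L || any(b <= 0) || abs(sum(b) - 1) > 1e-9)
    stop("background must be 4 positive probabilities summing to 1")
  q <- motifProbs(motif)
  entries <- boundedLog(q / b, c = c)
  dimnames(entries) <- list(DNA_BASES4, NULL)
  new("LogOddsMatrix", source = motifId(motif), c = c, entries = entries,
      background = setNames(b, DNA_BASES4),
      ymin = sum(apply(entries, 2L, min)),
      ymax = sum(apply(entries, 2L, max)))
}

.encodeSeq <- function(seq) {
  # A=1 C=2 G=3 T=4, anything else NA
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("a")] <- 1L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("g")] <- 3L; lut[utf8ToInt("t")] <- 4L
  codes <- utf8ToInt(as.character(seq))
  codes[codes > 127L] <- 127L
  lut[codes]
}

#' Log-odds score of one sequence window
#'
#' Sum over positions of the bounded log-odds entry for the observed base.
#' The score of the consensus sequence is `lomMax(lom)`, of the
#' anti-consensus `lomMin(lom)`.
#'
#' @param seq character or DNAString of length exactly the motif length.
#' @param lom a [LogOddsMatrix-class].
#' @return LOD score, or NA if the window contains a non-ACGT symbol
#'   (unscorable window).
#' @export
lodScore <- function(seq, lom) {
  code <- .encodeSeq(seq)
  L <- ncol(lom@entries)
  if (length(code) != L)
    stop("sequence length ", length(code), " != matrix length ", L)
  if (anyNA(code)) return(NA_real_)
  sum(lom@entries[cbind(code, seq_len(L))])
}

#' Normalized log-odds (NLOD) score
#'
#' Min-max normalization of the LOD score to `[0, 1]`:
#' (LOD - ymin) / (ymax - ymin). Consensus scores 1, anti-consensus 0.
#'
#' @inheritParams lodScore
#' @return NLOD in `[0, 1]`, or NA for an unscorable window.
#' @export
nlodScore <- function(seq, lom) {
  .rescaleNlod(lodScore(seq, lom), lom)
}

.rescaleNlod <- function(lod, lom) {
  if (lom@ymax - lom@ymin <= 1e-12)
    stop("uninformative matrix: ymax == ymin")
  (lod - lom@ymin) / (lom@ymax - lom@ymin)
}

# Vectorized LOD over every window start of a character sequence.
# Returns numeric vector of length nchar(seq) - L + 1 (NA where the window
# contains a non-ACGT symbol); length-0 vector if the sequence is shorter
# than the motif.
.scoreAllWindows <- function(seqchar, lom) {
  code <- .encodeSeq(seqchar)
  L <- ncol(lom@entries)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  entryAt <- function(off) {
    idx <- code[seq_len(n) + off]
    v <- lom@entries[cbind(idx, rep.int(off + 1L, n))]
    v[is.na(idx)] <- NA_real_
    v
  }
  tot <- entryAt(0L)
  for (off in seq_len(L - 1L)) tot <- tot + entryAt(off)
  tot
}

.revcompChar <- function(seqchar) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqchar)))
}

#' Calibrate the NLOD z-score for a matrix against a genome
#'
#' Samples `nSamples` windows uniformly at random (with replacement) over
#' all scorable positions of both strands of the genome, scores each with
#' the matrix, and records the sample mean and standard deviation of the
#' NLOD score. Deterministic given `seed`.
#'
#' @param lom a [LogOddsMatrix-class].
#' @param genome a [Biostrings::DNAStringSet] (or DNAString, or plain
#'   character vector of chromosome sequences).
#' @param nSamples number of windows to draw (default 1e5; at least 1000).
#' @param seed integer RNG seed (mandatory).
#' @return a [ZCalibration-class].
#' @export
calibrateZ <- function(lom, genome, nSamples = 100000L, seed) {
  if (missing(seed)) stop("a seed is required for calibration")
  nSamples <- as.integer(nSamples)
  if (nSamples < 1000L) stop("nSamples must be >= 1000")
  chrs <- .asCharGenome(genome)
  scores <- unlist(lapply(chrs, function(s) {
    c(.scoreAllWindows(s, lom), .scoreAllWindows(.revcompChar(s), lom))
  }), use.names = FALSE)
  scores <- scores[!is.na(scores)]
  if (length(scores) < 1L)
    stop("genome has no scorable windows of the motif length")
  nlod <- .rescaleNlod(scores, lom)
  withSeed(seed, {
    samp <- nlod[sample.int(length(nlod), nSamples, replace = TRUE)]
  })
  sigma <- sd(samp)
  if (!is.finite(sigma) || sigma <= 0)
    stop("uninformative matrix: constant NLOD over the genome")
  new("ZCalibration", matrixId = lom@source, mu = mean(samp), sigma = sigma,
      nSamples = nSamples, seed = as.integer(seed))
}

# run expr under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

.asCharGenome <- function(genome) {
  if (is(genome, "DNAString")) genome <- Biostrings::DNAStringSet(genome)
  if (is(genome, "DNAStringSet")) {
    chrs <- as.character(genome)
    if (is.null(names(chrs)))
      names(chrs) <- paste0("chr", seq_along(chrs))
    return(chrs)
  }
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("chr", seq_along(genome))
    return(genome)
  }
  stop("genome must be a DNAStringSet, DNAString or named character vector")
}

#' Standardize an NLOD score
#'
#' @param nlod NLOD score(s).
#' @param cal a [ZCalibration-class].
#' @return z-score(s): (nlod - mu) / sigma.
#' @export
zScore <- function(nlod, cal) (nlod - cal@mu) / cal@sigma

#' z-score threshold for an upper-tail p-value (and its inverse)
#'
#' `zThresholdForP(p)` returns the standard-normal quantile whose upper tail
#' holds probability p; `pValueForZ(z)` is the inverse. A z threshold of
#' 4.27 corresponds to p = 1e-5, the default for mammalian-scale scans;
#' 2.57-3.72 (p 0.005-1e-4) suits small genomes.
#'
#' @param p upper-tail probability in (0, 1).
#' @return the z threshold.
#' @examples
#' pValueForZ(4.27)   # ~1e-5
#' zThresholdForP(0.00001)
#' @export
zThresholdForP <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  qnorm(1 - p)
}

#' @rdname zThresholdForP
#' @param z z-score.
#' @export
pValueForZ <- function(z) 1 - pnorm(z)
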