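#' @import methods
#' @importFrom stats median pnorm qnorm runif sd setNames cor quantile rexp
#' @importFrom graphics hist
#' @importFrom utils head read.table write.csv write.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' MotifMatrix: a position probability matrix for a transcription factor
#'
#' Columns are motif positions, rows are the four nucleotides (A, C, G, T);
#' each column holds the probability of observing each base at that position
#' and must sum to one.
#'
#' @slot id character(1), matrix identifier (e.g. a JASPAR accession).
#' @slot tfName character(1), the transcription factor the matrix models.
#' @slot probs 4 x L numeric matrix of per-position base probabilities,
#'   rows named A/C/G/T.
#' @exportClass MotifMatrix
setClass("MotifMatrix",
  representation(id = "character", tfName = "character", probs = "matrix"))

setValidity("MotifMatrix", function(object) {
  p <- object@probs
  if (!is.numeric(p) || nrow(p) != 4L)
    return("'probs' must be a numeric 4 x L matrix (rows A,C,G,T)")
  if (ncol(p) < 1L)
    return("motif length must be >= 1")
  if (!identical(rownames(p), DNA_BASES4))
    return("rows of 'probs' must be named A, C, G, T in that order")
  if (any(p < 0))
    return("probabilities must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-9))
    return("each column of 'probs' must sum to 1 (tolerance 1e-9)")
  if (length(object@id) != 1L || !nzchar(object@id))
    return("'id' must be a non-empty string")
  TRUE
})

#' Construct a MotifMatrix
#'
#' Accepts either a probability matrix or a count matrix; counts are
#' column-normalized to probabilities with no pseudocounts (the bounded
#' log-odds transform makes pseudocounts unnecessary; see
#' [buildLogOddsMatrix()]).
#'
#' @param probs numeric 4 x L matrix (rows A,C,G,T; or unnamed in that
#'   order), probabilities or counts.
#' @param id matrix identifier.
#' @param tfName transcription factor name (defaults to `id`).
#' @param pseudocount optional pseudocount added to every cell before
#'   normalization (classical behaviour; default 0).
#' @return A [MotifMatrix-class] object.
#' @examples
#' m <- MotifMatrix(matrix(c(8, 0, 0, 0, 0, 0, 0, 8), 4,
#'                  dimnames = list(c("A", "C", "G", "T"), NULL)), id = "AT1")
#' motifLength(m)
#' @export
MotifMatrix <- function(probs, id, tfName = id, pseudocount = 0) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L)
    stop("matrix must have 4 rows (A, C, G, T)")
  if (is.null(rownames(probs))) rownames(probs) <- DNA_BASES4
  probs <- probs[DNA_BASES4, , drop = FALSE]
  probs <- probs + pseudocount
  cs <- colSums(probs)
  if (any(cs <= 0)) stop("every column must have positive total mass")
  probs <- sweep(probs, 2L, cs, "/")
  dimnames(probs) <- list(DNA_BASES4, NULL)
  new("MotifMatrix", id = as.character(id), tfName = as.character(tfName),
      probs = probs)
}

#' @describeIn MotifMatrix motif length (number of columns).
#' @param x,object a MotifMatrix.
#' @export
motifLength <- function(x) ncol(x@probs)

#' @describeIn MotifMatrix matrix identifier.
#' @export
motifId <- function(x) x@id

#' @describeIn MotifMatrix transcription factor name.
#' @export
tfName <- function(x) x@tfName

#' @describeIn MotifMatrix the 4 x L probability matrix.
#' @export
motifProbs <- function(x) x@probs

#' @describeIn MotifMatrix consensus sequence (argmax base per column,
#'   first of A,C,G,T on ties).
#' @export
consensusSeq <- function(x) {
  paste(DNA_BASES4[apply(x@probs, 2L, which.max)], collapse = "")
}

setMethod("show", "MotifMatrix", function(object) {
  cat("MotifMatrix", object@id, "(", object@tfName, "), length",
      motifLength(object), "\n")
  cat("consensus:", consensusSeq(object), "\n")
  print(round(object@probs, 3))
})

#' LogOddsMatrix: bounded log-odds scoring matrix
#'
#' Entries are f(q_ij / b_i) where f is [boundedLog()]: log2 above
#' x0 = exp(2c) and its tangent line below, so that zero probabilities get a
#' finite penalty instead of -Inf (no pseudocounts needed).
#'
#' @slot source id of the parent [MotifMatrix-class].
#' @slot c bounding constant of the scoring transform (default -3).
#' @slot entries 4 x L numeric matrix of bounded log-odds values.
#' @slot background length-4 background probabilities (A,C,G,T).
#' @slot ymin,ymax minimum / maximum achievable LOD score.
#' @exportClass LogOddsMatrix
setClass("LogOddsMatrix",
  representation(source = "character", c = "numeric", entries = "matrix",
                 background = "numeric", ymin = "numeric", ymax = "numeric"))

setValidity("LogOddsMatrix", function(object) {
  e <- object@entries
  if (nrow(e) != 4L || !identical(rownames(e), DNA_BASES4))
    return("'entries' must be 4 x L with rows A,C,G,T")
  if (abs(object@ymax - sum(apply(e, 2L, max))) > 1e-9)
    return("ymax must equal the column-wise maximum sum")
  if (abs(object@ymin - sum(apply(e, 2L, min))) > 1e-9)
    return("ymin must equal the column-wise minimum sum")
  if (object@ymax < object@ymin) return("ymax < ymin")
  TRUE
})

setMethod("show", "LogOddsMatrix", function(object) {
  cat("LogOddsMatrix for", object@source, "(c =", object@c, ")\n")
  cat("length", ncol(object@entries), "; LOD range [",
      round(object@ymin, 3), ",", round(object@ymax, 3), "]\n")
})

#' @describeIn LogOddsMatrix the 4 x L bounded log-odds entries.
#' @param x a LogOddsMatrix.
#' @export
lomEntries <- function(x) x@entries

#' @describeIn LogOddsMatrix minimum achievable LOD.
#' @export
lomMin <- function(x) x@ymin

#' @describeIn LogOddsMatrix maximum achievable LOD.
#' @export
lomMax <- function(x) x@ymax

#' ZCalibration: empirical NLOD score calibration for one matrix
#'
#' Mean and standard deviation of the NLOD score over random genomic
#' windows, used to standardize NLOD into a z-score.
#'
#' @slot matrixId id of the calibrated matrix.
#' @slot mu,sigma sample mean and standard deviation of NLOD over random
#'   windows (both strands pooled).
#' @slot nSamples number of windows sampled.
#' @slot seed RNG seed used for sampling.
#' @exportClass ZCalibration
setClass("ZCalibration",
  representation(matrixId = "character", mu = "numeric", sigma = "numeric",
                 nSamples = "integer", seed = "integer"))

setValidity("ZCalibration", function(object) {
  if (!(object@sigma > 0)) return("sigma must be > 0")
  if (object@nSamples < 1000L) return("nSamples must be >= 1000")
  TRUE
})

setMethod("show", "ZCalibration", function(object) {
  cat(sprintf("ZCalibration for %s: mu = %.4f, sigma = %.4f (n = %d, seed = %d)\n",
              object@matrixId, object@mu, object@sigma, object@nSamples,
              object@seed))
})
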