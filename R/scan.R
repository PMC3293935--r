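#' Scan a genome for candidate binding sites
#'
#' Scores every window of the motif length on both strands of every
#' chromosome, converts LOD to NLOD and z, and keeps windows with
#' z >= `zMin`. Windows containing N or other ambiguity codes are skipped.
#' Sites overlapping any mask interval (exons, repeats) by at least 1 bp
#' are removed, then the top-k cap of [topKFilter()] is applied. Output is
#' sorted by (chromosome, start, strand).
#'
#' @param genome [Biostrings::DNAStringSet], DNAString or named character
#'   vector of chromosome sequences.
#' @param lom a [LogOddsMatrix-class].
#' @param cal the matching [ZCalibration-class]; `cal@matrixId` must equal
#'   `lom@source`.
#' @param zMin z-score threshold (default 4.27, upper-tail p 1e-5; use
#'   2.57-3.72 for small genomes).
#' @param k top-k cap on the number of reported sites (ties at the k-th
#'   z kept; default 100000).
#' @param masks optional [GenomicRanges::GRanges] of excluded intervals.
#' @return a `GRanges` of sites (1-based closed coordinates) with metadata
#'   columns `matrixId`, `seq` (strand-oriented match), `lod`, `nlod`, `z`.
#' @export
scanGenome <- function(genome, lom, cal, zMin = 4.27, k = 100000L,
                       masks = NULL) {
  if (missing(cal) || !is(cal, "ZCalibration"))
    stop("a ZCalibration is required")
  if (!identical(cal@matrixId, lom@source))
    stop("calibration is for matrix '", cal@matrixId,
         "', not '", lom@source, "'")
  chrs <- .asCharGenome(genome)
  L <- ncol(lom@entries)
  hits <- list()
  for (chrom in names(chrs)) {
    s <- chrs[[chrom]]
    n <- nchar(s)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") s else .revcompChar(s)
      lod <- .scoreAllWindows(sc, lom)
      if (length(lod) == 0L) next
      nlod <- .rescaleNlod(lod, lom)
      z <- zScore(nlod, cal)
      keep <- which(!is.na(z) & z >= zMin)
      if (length(keep) == 0L) next
      start <- if (strand == "+") keep else n - (keep + L - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = start, strand = strand,
        seq = substring(sc, keep, keep + L - 1L),
        lod = lod[keep], nlod = nlod[keep], z = z[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(.emptySites(lom@source, L))
  df <- do.call(rbind, hits)
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(start = df$start, width = L),
          strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    matrixId = lom@source, seq = df$seq, lod = df$lod,
    nlod = df$nlod, z = df$z)
  if (!is.null(masks) && length(masks) > 0L) {
    ov <- GenomicRanges::findOverlaps(gr, masks, ignore.strand = TRUE)
    if (length(ov) > 0L) gr <- gr[-unique(S4Vectors::queryHits(ov))]
  }
  gr <- topKFilter(gr, k)
  .sortSites(gr)
}

.sortSites <- function(gr) {
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr),
               as.character(GenomicRanges::strand(gr)))
  gr[ord]
}

.emptySites <- function(matrixId, L) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    matrixId = character(0), seq = character(0), lod = numeric(0),
    nlod = numeric(0), z = numeric(0))
  gr
}

#' Cap a site list at the k best z-scores, keeping ties
#'
#' Orders sites by decreasing z and keeps every site whose z is at least
#' as high as the k-th site's z, so ties at the cutoff are retained and the
#' output may exceed k.
#'
#' @param sites `GRanges` with a `z` metadata column.
#' @param k positive integer cap.
#' @return the filtered `GRanges`.
#' @export
topKFilter <- function(sites, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (length(sites) <= k) return(sites)
  z <- S4Vectors::mcols(sites)$z
  zk <- sort(z, decreasing = TRUE)[k]
  sites[z >= zk]
}
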