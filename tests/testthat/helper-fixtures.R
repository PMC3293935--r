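suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# one-hot-leaning palindromic 8-mer (consensus AACGCGTT = its own
# reverse complement)
palindromeMotif <- function(major = 0.9) {
  cons <- strsplit("AACGCGTT", "")[[1]]
  probs <- vapply(cons, function(b) {
    p <- rep((1 - major) / 3, 4)
    p[match(b, c("A", "C", "G", "T"))] <- major
    p
  }, numeric(4))
  rownames(probs) <- c("A", "C", "G", "T")
  MotifMatrix(probs, id = "PAL1")
}

# motif whose columns are reverse-complemented (reverse column order,
# swap A<->T and C<->G rows)
revcompMotif <- function(m, id = paste0(motifId(m), "_rc")) {
  p <- motifProbs(m)
  p <- p[c("T", "G", "C", "A"), rev(seq_len(ncol(p))), drop = FALSE]
  rownames(p) <- c("A", "C", "G", "T")
  MotifMatrix(p, id = id, tfName = tfName(m))
}

revcompChar <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# exhaustive every-window scan oracle: score each window of each strand
# one by one with lodScore(), then threshold, mask and cap
oracleScan <- function(genome, lom, cal, zMin, masks = NULL, k = Inf) {
  chrs <- as.character(genome)
  if (is.null(names(chrs))) names(chrs) <- paste0("chr", seq_along(chrs))
  L <- ncol(lomEntries(lom))
  rows <- list()
  for (chrom in names(chrs)) {
    s <- chrs[[chrom]]
    n <- nchar(s)
    for (i in seq_len(n - L + 1L)) {
      w <- substr(s, i, i + L - 1L)
      for (strand in c("+", "-")) {
        ws <- if (strand == "+") w else revcompChar(w)
        lod <- lodScore(ws, lom)
        if (is.na(lod)) next
        nlod <- (lod - lomMin(lom)) / (lomMax(lom) - lomMin(lom))
        z <- zScore(nlod, cal)
        if (z >= zMin)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = i, strand = strand, seq = ws,
            lod = lod, nlod = nlod, z = z, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), seq = character(0),
                      lod = numeric(0), nlod = numeric(0),
                      z = numeric(0)))
  df <- do.call(rbind, rows)
  if (!is.null(masks) && length(masks) > 0L) {
    gr <- GRanges(df$chrom, IRanges::IRanges(df$start, width = L))
    hit <- unique(queryHits(findOverlaps(gr, masks, ignore.strand = TRUE)))
    if (length(hit) > 0L) df <- df[-hit, , drop = FALSE]
  }
  if (is.finite(k) && nrow(df) > k) {
    zk <- sort(df$z, decreasing = TRUE)[k]
    df <- df[df$z >= zk, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

sitesToDf <- function(sites) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   start = start(sites),
                   strand = as.character(strand(sites)),
                   seq = mcols(sites)$seq, lod = mcols(sites)$lod,
                   nlod = mcols(sites)$nlod, z = mcols(sites)$z,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# GRanges of synthetic sites for postprocess tests
fakeSites <- function(start, width = 10L, matrixId = "M1", nlod = 0.9,
                      bbls = 1, chrom = "chr1", strand = "+") {
  n <- length(start)
  gr <- GRanges(rep(chrom, length.out = n),
                IRanges::IRanges(start = start, width = width),
                strand = rep(strand, length.out = n))
  mcols(gr) <- DataFrame(matrixId = rep(matrixId, length.out = n),
                         nlod = rep(nlod, length.out = n),
                         bbls = rep(bbls, length.out = n))
  gr
}

# brute-force transitive-closure overlap grouping (O(n^2) fixpoint)
oracleGroups <- function(sites) {
  n <- length(sites)
  grp <- seq_len(n)
  ov <- findOverlaps(sites, sites, ignore.strand = TRUE)
  repeat {
    changed <- FALSE
    for (h in seq_along(ov)) {
      a <- queryHits(ov)[h]; b <- subjectHits(ov)[h]
      g <- min(grp[a], grp[b])
      if (grp[a] != g || grp[b] != g) {
        grp[grp == grp[a] | grp == grp[b]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}

# brute-force pairwise AUC with half-credit ties
oracleAuc <- function(score, positive) {
  ps <- score[positive]; ns <- score[!positive]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}
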