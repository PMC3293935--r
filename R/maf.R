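#' Read a Multiple Alignment Format (MAF) file
#'
#' Streams `a`/`s` lines; `e` (empty) and `i` (context) lines are ignored.
#' Species names follow the UCSC convention: the part of the source name
#' before the first dot (`hg.chr1` -> species `hg`, chromosome `chr1`).
#'
#' @param path MAF file path.
#' @return a list of alignment blocks; each block is a data.frame with one
#'   row per species: `species`, `chrom`, `start` (0-based, strand
#'   coordinates), `size` (ungapped length), `strand`, `srcSize`, `text`
#'   (aligned sequence with `-` gaps).
#' @export
readMAF <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  rows <- NULL
  flush <- function() {
    if (!is.null(rows) && nrow(rows) > 0L)
      blocks[[length(blocks) + 1L]] <<- rows
    rows <<- NULL
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      rows <- data.frame(species = character(0), chrom = character(0),
                         start = integer(0), size = integer(0),
                         strand = character(0), srcSize = integer(0),
                         text = character(0), stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      src <- f[2]
      sp <- sub("\\..*$", "", src)
      chrom <- sub("^[^.]*\\.?", "", src)
      if (!nzchar(chrom)) chrom <- src
      row <- data.frame(species = sp, chrom = chrom,
                        start = as.integer(f[3]), size = as.integer(f[4]),
                        strand = f[5], srcSize = as.integer(f[6]),
                        text = f[7], stringsAsFactors = FALSE)
      rows <- rbind(rows, row)
    }
    # 'e', 'i', 'q', comments: ignored
  }
  flush()
  for (b in blocks) {
    widths <- nchar(b$text)
    if (length(unique(widths)) > 1L)
      stop("malformed MAF: unequal aligned text lengths within a block")
    ungapped <- nchar(gsub("-", "", b$text))
    if (any(ungapped != b$size))
      stop("malformed MAF: 'size' does not match ungapped text length")
  }
  blocks
}

#' Write alignment blocks to a MAF file
#'
#' @param blocks a list of block data.frames as returned by [readMAF()].
#' @param path output path.
#' @export
writeMAF <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a score=0.0", con)
    for (i in seq_len(nrow(b))) {
      writeLines(sprintf("s %s.%s %d %d %s %d %s",
                         b$species[i], b$chrom[i], b$start[i], b$size[i],
                         b$strand[i], b$srcSize[i], b$text[i]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Extract alignment blocks overlapping a padded site
#'
#' Expands the reference-site interval by `pad` base pairs on each side
#' (clipped at the chromosome bounds) and returns every block whose
#' reference-species row overlaps the expanded interval. The padding
#' compensates for the low resolution of whole-genome alignments: the true
#' orthologous motif may sit a few bases out of alignment frame.
#'
#' @param site a length-1 `GRanges` site (from [scanGenome()]).
#' @param maf list of blocks from [readMAF()].
#' @param refSpecies reference species name as used in the MAF.
#' @param pad expansion in bp on each side (default 15).
#' @return the subset of `maf` whose reference rows overlap; may be empty.
#' @export
extractBlocks <- function(site, maf, refSpecies, pad = 15L) {
  chrom <- as.character(GenomicRanges::seqnames(site))
  lo <- max(0L, GenomicRanges::start(site) - 1L - pad)   # 0-based
  hi <- GenomicRanges::end(site) + pad                   # 0-based exclusive
  keep <- vapply(maf, function(b) {
    r <- b[b$species == refSpecies & b$chrom == chrom & b$strand == "+", ,
           drop = FALSE]
    any(r$start < hi & (r$start + r$size) > lo)
  }, logical(1))
  maf[keep]
}

#' Merge nearby per-species alignment rows into contiguous segments
#'
#' Alignment blocks for one species can be far apart on the chromosome or
#' on different chromosomes entirely; only rows on the same chromosome and
#' strand within `maxGap` bp of each other (in the species' own
#' coordinates) are concatenated, keeping the intervening sequence: taken
#' from `genomeLookup` when available, otherwise filled with N. Rows
#' farther apart, overlapping rows, and rows on other chromosomes/strands
#' start separate segments.
#'
#' @param blocks list of blocks (e.g. from [extractBlocks()]).
#' @param species species whose rows to merge.
#' @param maxGap maximum inter-row gap in bp to bridge (default 30).
#' @param genomeLookup optional named list / DNAStringSet of that species'
#'   chromosome sequences used to fill plus-strand gaps.
#' @return character vector of merged ungapped segments (possibly empty).
#' @export
mergeBlocks <- function(blocks, species, maxGap = 30L,
                        genomeLookup = NULL) {
  rows <- do.call(rbind, lapply(blocks, function(b)
    b[b$species == species, , drop = FALSE]))
  if (is.null(rows) || nrow(rows) == 0L) return(character(0))
  rows$ungapped <- gsub("-", "", rows$text)
  rows <- rows[nchar(rows$ungapped) > 0L, , drop = FALSE]
  if (nrow(rows) == 0L) return(character(0))
  rows <- rows[order(rows$chrom, rows$strand, rows$start), , drop = FALSE]
  segs <- character(0)
  cur <- rows$ungapped[1L]
  curEnd <- rows$start[1L] + rows$size[1L]
  curChrom <- rows$chrom[1L]; curStrand <- rows$strand[1L]
  for (i in seq_len(nrow(rows))[-1L]) {
    gap <- rows$start[i] - curEnd
    if (rows$chrom[i] == curChrom && rows$strand[i] == curStrand &&
        gap >= 0L && gap <= maxGap) {
      fill <- if (gap == 0L) "" else .gapFill(genomeLookup, curChrom,
                                              curStrand, curEnd, gap)
      cur <- paste0(cur, fill, rows$ungapped[i])
      curEnd <- rows$start[i] + rows$size[i]
    } else {
      segs <- c(segs, cur)
      cur <- rows$ungapped[i]
      curEnd <- rows$start[i] + rows$size[i]
      curChrom <- rows$chrom[i]; curStrand <- rows$strand[i]
    }
  }
  c(segs, cur)
}

.gapFill <- function(genomeLookup, chrom, strand, start0, len) {
  if (!is.null(genomeLookup) && strand == "+" &&
      chrom %in% names(genomeLookup)) {
    s <- as.character(genomeLookup[[chrom]])
    if (start0 + len <= nchar(s))
      return(substr(s, start0 + 1L, start0 + len))
  }
  strrep("N", len)
}

#' Best motif match per species around a reference site
#'
#' For each non-reference species in the extracted blocks, merges its rows
#' into segments ([mergeBlocks()]), scans every window of both strands of
#' every segment, and records the maximum-NLOD window and its z-score.
#' Windows containing N are skipped; species with no scorable window (e.g.
#' aligned only by gaps) are omitted. The reference species' entry is taken
#' from the already-scored site, not re-derived from its MAF row.
#'
#' @param site a length-1 `GRanges` site with `seq`, `nlod`, `z` columns.
#' @param blocks blocks from [extractBlocks()] for this site.
#' @param lom,cal the matrix and calibration that produced the site.
#' @param refSpecies reference species name.
#' @param maxGap passed to [mergeBlocks()]; set a negative value to disable
#'   merging (each row scanned alone).
#' @param genomeLookup optional per-species genome lookup: a named list
#'   `species -> chromosome sequences` for gap filling.
#' @return a [S4Vectors::DataFrame] with one row per species: `species`,
#'   `seq` (best window), `nlod`, `z`; metadata `alignedSpeciesCount` (the
#'   number of species with any aligned bases) and `site` (the input site).
#' @export
bestSpeciesHits <- function(site, blocks, lom, cal, refSpecies,
                            maxGap = 30L, genomeLookup = NULL) {
  allSpecies <- unique(unlist(lapply(blocks, function(b) b$species)))
  aligned <- vapply(allSpecies, function(sp) {
    any(vapply(blocks, function(b)
      any(b$species == sp & nchar(gsub("-", "", b$text)) > 0L),
      logical(1)))
  }, logical(1))
  others <- setdiff(allSpecies[aligned], refSpecies)
  rows <- list(data.frame(species = refSpecies,
                          seq = S4Vectors::mcols(site)$seq,
                          nlod = S4Vectors::mcols(site)$nlod,
                          z = S4Vectors::mcols(site)$z,
                          stringsAsFactors = FALSE))
  mg <- max(0L, maxGap)
  for (sp in others) {
    segs <- if (maxGap < 0L) {
      unlist(lapply(blocks, function(b) {
        u <- gsub("-", "", b$text[b$species == sp])
        u[nchar(u) > 0L]
      }), use.names = FALSE)
    } else {
      mergeBlocks(blocks, sp, maxGap = mg,
                  genomeLookup = genomeLookup[[sp]])
    }
    best <- .bestWindow(segs, lom)
    if (is.null(best)) next
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, seq = best$seq, nlod = best$nlod,
      z = zScore(best$nlod, cal), stringsAsFactors = FALSE)
  }
  out <- S4Vectors::DataFrame(do.call(rbind, rows))
  S4Vectors::metadata(out) <- list(
    alignedSpeciesCount = sum(aligned), site = site)
  out
}

# best NLOD window over both strands of each segment; NULL if unscorable
.bestWindow <- function(segs, lom) {
  L <- ncol(lom@entries)
  best <- NULL
  for (seg in segs) {
    if (nchar(seg) < L) next
    for (s in c(seg, .revcompChar(seg))) {
      lod <- .scoreAllWindows(s, lom)
      if (all(is.na(lod))) next
      i <- which.max(lod)
      nlod <- .rescaleNlod(lod[i], lom)
      if (is.null(best) || nlod > best$nlod)
        best <- list(seq = substr(s, i, i + L - 1L), nlod = nlod)
    }
  }
  best
}

#' Minimum-species conservation filter
#'
#' A site passes when at least `required` non-reference species (optionally
#' restricted to `eligibleSpecies`, e.g. non-primates) have a best-hit
#' z-score at or above `zFloor`.
#'
#' @param hits a DataFrame from [bestSpeciesHits()].
#' @param required minimum number of conserved non-reference species
#'   (`required = 0` always passes).
#' @param refSpecies reference species name.
#' @param eligibleSpecies optional character vector restricting which
#'   species may count.
#' @param zFloor conservation z threshold (default 1.64, one-sided p 0.05).
#' @return logical(1).
#' @export
minSpeciesFilter <- function(hits, required, refSpecies,
                             eligibleSpecies = NULL, zFloor = 1.64) {
  if (required < 0) stop("'required' must be >= 0")
  if (required == 0) return(TRUE)
  df <- as.data.frame(hits)
  df <- df[df$species != refSpecies & df$z >= zFloor, , drop = FALSE]
  if (!is.null(eligibleSpecies))
    df <- df[df$species %in% eligibleSpecies, , drop = FALSE]
  nrow(df) >= required
}
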