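#' Read motif matrices in JASPAR plain-text format
#'
#' Records start with a `>` header line (`>ID name`); the following four
#' lines give the A, C, G, T counts, optionally wrapped in
#' `A [ 1 2 3 ]`-style brackets. Counts are column-normalized to
#' probabilities (no pseudocounts unless requested).
#'
#' @param path file path.
#' @param pseudocount passed to [MotifMatrix()].
#' @return a named list of [MotifMatrix-class] objects.
#' @export
readJASPAR <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' headers found in ", path)
  out <- lapply(starts, function(i) {
    header <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]]
    id <- header[1]
    tf <- if (length(header) > 1L) header[2] else id
    rows <- lapply(lines[i + 1:4], function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", ln)      # optional row label
      ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged matrix for ", id)
    m <- do.call(rbind, rows)
    rownames(m) <- DNA_BASES4
    MotifMatrix(m, id = id, tfName = tf, pseudocount = pseudocount)
  })
  names(out) <- vapply(out, motifId, character(1))
  out
}

#' Read motif matrices in TRANSFAC-style format
#'
#' Expects `AC`/`ID`/`NA` metadata lines, a `P0 A C G T` column header, and
#' one numbered line per motif position; records end with `//`.
#'
#' @inheritParams readJASPAR
#' @return a named list of [MotifMatrix-class] objects.
#' @export
readTRANSFAC <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  out <- list()
  id <- tf <- NA_character_
  rows <- list()
  colOrder <- DNA_BASES4
  flush <- function() {
    if (length(rows) == 0L) return(NULL)
    m <- t(do.call(rbind, rows))      # to 4 x L
    rownames(m) <- colOrder
    m <- m[DNA_BASES4, , drop = FALSE]
    MotifMatrix(m, id = id, tfName = if (is.na(tf)) id else tf,
                pseudocount = pseudocount)
  }
  for (ln in lines) {
    tag <- substr(ln, 1L, 2L)
    rest <- trimws(substr(ln, 3L, nchar(ln)))
    if (tag %in% c("AC", "ID") && is.na(id)) id <- strsplit(rest, "\\s+")[[1]][1]
    else if (tag == "NA") tf <- rest
    else if (tag == "P0" || tag == "PO")
      colOrder <- toupper(strsplit(rest, "\\s+")[[1]][1:4])
    else if (grepl("^\\d", tag)) {
      vals <- strsplit(trimws(ln), "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(vals[2:5])
    } else if (tag == "//") {
      m <- flush()
      if (!is.null(m)) out[[motifId(m)]] <- m
      id <- tf <- NA_character_; rows <- list(); colOrder <- DNA_BASES4
    }
  }
  m <- flush()
  if (!is.null(m)) out[[motifId(m)]] <- m
  if (length(out) == 0L) stop("no TRANSFAC records found in ", path)
  out
}

#' Write / read motif matrices as TSV
#'
#' Internal tab-separated dialect: a `#id<TAB>tfName` header line followed
#' by four probability rows labeled A/C/G/T; records separated by blank
#' lines. Round-trips through [readMatrixTSV()].
#'
#' @param motifs a [MotifMatrix-class] or list of them.
#' @param path output file path.
#' @export
writeMatrixTSV <- function(motifs, path) {
  if (is(motifs, "MotifMatrix")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0("#", motifId(m), "\t", tfName(m)), con)
    p <- motifProbs(m)
    for (b in DNA_BASES4)
      writeLines(paste(c(b, format(p[b, ], digits = 10)), collapse = "\t"),
                 con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  lines <- readLines(path)
  starts <- grep("^#", lines)
  out <- lapply(starts, function(i) {
    header <- strsplit(sub("^#", "", lines[i]), "\t")[[1]]
    rows <- lapply(lines[i + 1:4], function(ln) {
      f <- strsplit(ln, "\t")[[1]]
      as.numeric(f[-1])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- DNA_BASES4
    MotifMatrix(m, id = header[1],
                tfName = if (length(header) > 1L) header[2] else header[1])
  })
  names(out) <- vapply(out, motifId, character(1))
  out
}
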