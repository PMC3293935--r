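#' Export sites to BED, GFF3 or CSV
#'
#' BED output is 0-based half-open with the z-score in the score column;
#' GFF3 output is 1-based closed; CSV carries every metadata column plus
#' 1-based coordinates.
#'
#' @param sites `GRanges` of sites.
#' @param path output file path.
#' @param name metadata column used for the BED name / GFF attribute
#'   (default "matrixId").
#' @return the path, invisibly.
#' @export
writeSitesBED <- function(sites, path, name = "matrixId") {
  mc <- S4Vectors::mcols(sites)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    name = if (name %in% colnames(mc)) mc[[name]] else ".",
    score = if ("z" %in% colnames(mc)) round(mc$z, 4) else 0,
    strand = as.character(GenomicRanges::strand(sites)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSitesBED
#' @export
writeSitesGFF <- function(sites, path, name = "matrixId") {
  mc <- S4Vectors::mcols(sites)
  attr <- sprintf("ID=site%d;Name=%s", seq_along(sites),
                  if (name %in% colnames(mc)) mc[[name]] else ".")
  if ("nlod" %in% colnames(mc))
    attr <- paste0(attr, sprintf(";nlod=%.4f", mc$nlod))
  if ("bbls" %in% colnames(mc))
    attr <- paste0(attr, sprintf(";bbls=%.4f", mc$bbls))
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(sites)),
    source = "phyloMotif", type = "TF_binding_site",
    start = GenomicRanges::start(sites),     # 1-based closed
    end = GenomicRanges::end(sites),
    score = if ("z" %in% colnames(mc)) sprintf("%.4f", mc$z) else ".",
    strand = as.character(GenomicRanges::strand(sites)),
    phase = ".", attributes = attr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSitesBED
#' @export
writeSitesCSV <- function(sites, path) {
  df <- as.data.frame(sites)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file of intervals as GRanges
#'
#' Thin wrapper over [rtracklayer::import.bed()] (converting to the 1-based
#' closed GRanges convention). Used for masks (exons, repeats) and labeled
#' region sets; a region set's name field "positive"/"negative" populates a
#' logical `positive` column.
#'
#' @param path BED file path.
#' @param labeled interpret the BED name field as a positive/negative
#'   label (default FALSE).
#' @return a `GRanges`.
#' @export
readBed <- function(path, labeled = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  if (labeled) {
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) stop("labeled BED requires a name field")
    S4Vectors::mcols(gr)$positive <- tolower(nm) %in%
      c("positive", "pos", "1", "true")
  }
  gr
}

#' Read SNP positions from BED
#'
#' Width-1 ranges; the BED name field becomes `snp_id`.
#'
#' @param path BED file path.
#' @return `GRanges` with an `snp_id` column.
#' @export
readSnpBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$snp_id <-
    if (is.null(nm)) paste0("snp", seq_along(gr)) else nm
  gr
}

#' Read SNP positions from a minimal VCF (CHROM/POS/ID)
#'
#' Only the chromosome, position and identifier fields are used.
#'
#' @param path VCF file path.
#' @return `GRanges` of width-1 positions with an `snp_id` column.
#' @export
readMinimalVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  GenomicRanges::GRanges(fix$CHROM,
    IRanges::IRanges(start = as.integer(fix$POS), width = 1L),
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0("snp", seq_len(nrow(fix))), fix$ID))
}

#' Read TSS annotations from GFF
#'
#' Keeps `TSS`-typed features (or derives the TSS from gene/transcript
#' features: their strand-aware 5' end) as width-1 ranges with a `gene_id`
#' column.
#'
#' @param path GFF file path.
#' @return `GRanges` of TSS positions.
#' @export
readTssGff <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type %in% c("TSS", "gene", "transcript", "mRNA")
  gr <- gr[keep]
  tssPos <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                   GenomicRanges::end(gr), GenomicRanges::start(gr))
  gene <- S4Vectors::mcols(gr)$ID
  if (is.null(gene)) gene <- S4Vectors::mcols(gr)$Name
  if (is.null(gene)) gene <- paste0("gene", seq_along(gr))
  out <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(gr)),
    IRanges::IRanges(start = tssPos, width = 1L),
    strand = GenomicRanges::strand(gr),
    gene_id = as.character(gene))
  unique(out)
}

#' Write a genome to FASTA
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param path output path.
#' @export
writeFasta <- function(genome, path) {
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return a `DNAStringSet` named by the first word of each header.
#' @export
readFasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
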