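#' Collapse overlapping sites to one representative per transcription factor
#'
#' A factor is often annotated with several matrices, so the same locus can
#' be hit more than once. Within each transcription factor, overlapping
#' sites (any overlap of at least 1 bp, strand-agnostic, by transitive
#' closure) form a group, and the group's representative is its
#' maximum-BBLS site; ties broken by higher NLOD, then leftmost start.
#' Sites of different factors never compete.
#'
#' @param sites `GRanges` with `matrixId`, `nlod` and `bbls` metadata
#'   columns.
#' @param matrixToTf named character vector mapping matrix id to
#'   transcription factor name; must cover every matrix id present.
#' @return the non-overlapping representative `GRanges`, with a `tf`
#'   metadata column added.
#' @export
redundancyFilter <- function(sites, matrixToTf) {
  if (length(sites) == 0L) return(sites)
  ids <- S4Vectors::mcols(sites)$matrixId
  unmapped <- setdiff(unique(ids), names(matrixToTf))
  if (length(unmapped) > 0L)
    stop("no transcription factor mapped for matrix id(s): ",
         paste(unmapped, collapse = ", "))
  tf <- unname(matrixToTf[ids])
  S4Vectors::mcols(sites)$tf <- tf
  keep <- unlist(lapply(split(seq_along(sites), tf), function(idx) {
    sub <- sites[idx]
    # reduce() with min.gapwidth = 0 merges exactly the overlapping runs,
    # giving the transitive-closure overlap groups
    groups <- GenomicRanges::reduce(sub, ignore.strand = TRUE,
                                    min.gapwidth = 0L)
    ov <- GenomicRanges::findOverlaps(sub, groups, ignore.strand = TRUE)
    gid <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    mc <- S4Vectors::mcols(sub)
    vapply(split(seq_along(sub), gid), function(g) {
      o <- order(-mc$bbls[g], -mc$nlod[g], GenomicRanges::start(sub)[g])
      idx[g[o[1L]]]
    }, numeric(1))
  }), use.names = FALSE)
  .sortSites(sites[sort(keep)])
}

#' Distance from each site to the nearest transcription start site
#'
#' The nearest TSS is chosen by absolute distance from the site midpoint;
#' the signed distance is negative when the site lies upstream of the TSS
#' relative to the gene's strand.
#'
#' @param sites `GRanges` of sites.
#' @param annotations `GRanges` of TSS positions (width-1 ranges at each
#'   TSS, strand set to the gene strand) with a `gene_id` metadata column.
#' @return data.frame with columns `gene_id` and `distance` (NA for sites
#'   on chromosomes without any annotation).
#' @export
tssDistance <- function(sites, annotations) {
  mid <- (GenomicRanges::start(sites) + GenomicRanges::end(sites)) / 2
  tssPos <- GenomicRanges::start(annotations)
  out <- data.frame(gene_id = rep(NA_character_, length(sites)),
                    distance = rep(NA_real_, length(sites)),
                    stringsAsFactors = FALSE)
  chrS <- as.character(GenomicRanges::seqnames(sites))
  chrA <- as.character(GenomicRanges::seqnames(annotations))
  for (i in seq_along(sites)) {
    j <- which(chrA == chrS[i])
    if (length(j) == 0L) next
    d <- mid[i] - tssPos[j]
    k <- j[which.min(abs(d))]
    dist <- mid[i] - tssPos[k]
    if (as.character(GenomicRanges::strand(annotations))[k] == "-")
      dist <- -dist
    out$gene_id[i] <- S4Vectors::mcols(annotations)$gene_id[k]
    out$distance[i] <- dist
  }
  out
}

#' Select sites within a promoter window of their nearest gene
#'
#' Keeps sites whose signed TSS distance lies in
#' `[-upstream, +downstream]` (both bounds inclusive); the default window
#' is 15 kb upstream to 3 kb downstream.
#'
#' @param sites `GRanges` with a `distance` metadata column (signed bp, as
#'   from [tssDistance()]).
#' @param upstream,downstream window extents in bp.
#' @param genes optional character vector of gene ids to restrict to
#'   (requires a `gene_id` metadata column).
#' @return the filtered `GRanges`.
#' @export
promoterWindowSelect <- function(sites, upstream = 15000, downstream = 3000,
                                 genes = NULL) {
  mc <- S4Vectors::mcols(sites)
  keep <- !is.na(mc$distance) &
    mc$distance >= -upstream & mc$distance <= downstream
  if (!is.null(genes)) keep <- keep & mc$gene_id %in% genes
  sites[keep]
}

#' Sites overlapping SNP positions
#'
#' Emits every (site, SNP) pair where the SNP base lies within the site
#' interval.
#'
#' @param sites `GRanges` of sites.
#' @param snps `GRanges` of width-1 SNP positions with a `snp_id` metadata
#'   column (e.g. from [readSnpBed()] or [readMinimalVCF()]).
#' @return data.frame with columns `site` (index into `sites`) and
#'   `snp_id`.
#' @export
snpOverlap <- function(sites, snps) {
  ov <- GenomicRanges::findOverlaps(sites, snps, ignore.strand = TRUE)
  data.frame(site = S4Vectors::queryHits(ov),
             snp_id = S4Vectors::mcols(snps)$snp_id[
               S4Vectors::subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Stratify sites into BBLS quartiles with TSS-distance histograms
#'
#' Orders sites by BBLS (stable for ties, so equal scores fill groups in
#' input order) and splits them into four groups of equal size (within one
#' for remainders), quartile 1 holding the lowest scores and quartile 4 the
#' highest. Each group gets a histogram of absolute TSS distances at the
#' requested bin width, capped at `maxDistance`.
#'
#' @param sites `GRanges` with `bbls` and `distance` metadata columns;
#'   needs at least 4 sites.
#' @param binWidth histogram bin width in bp (default 500).
#' @param maxDistance distance cap in bp (default 10000; use 50000 for the
#'   wide view).
#' @return list of 4 elements (`Q1` lowest BBLS .. `Q4` highest), each a
#'   list with `sites` (the group's `GRanges`), `bblsRange`, `breaks` and
#'   `counts`.
#' @export
bblsQuartileStratify <- function(sites, binWidth = 500, maxDistance = 10000) {
  n <- length(sites)
  if (n < 4L) stop("need at least 4 sites to form quartiles")
  mc <- S4Vectors::mcols(sites)
  ord <- order(mc$bbls)                       # stable: ties in input order
  sizes <- rep(n %/% 4L, 4L) + c(rep(1L, n %% 4L), rep(0L, 4L - n %% 4L))
  groups <- split(ord, rep(1:4, sizes))
  breaks <- seq(0, maxDistance, by = binWidth)
  out <- lapply(groups, function(idx) {
    g <- sites[idx]
    d <- abs(S4Vectors::mcols(g)$distance)
    d <- d[!is.na(d) & d <= maxDistance]
    counts <- if (length(d) > 0)
      hist(d, breaks = breaks, plot = FALSE)$counts
    else rep(0L, length(breaks) - 1L)
    list(sites = g,
         bblsRange = range(S4Vectors::mcols(g)$bbls),
         breaks = breaks, counts = counts)
  })
  names(out) <- paste0("Q", 1:4)
  out
}

#' AUC for recovering labeled regions by site score
#'
#' Each region is ranked by the maximum score of the sites it contains.
#' With `negativesMode = "include"` regions containing no site stay in the
#' ranking below every scored region (the convention that treats
#' site-free experimental regions as true negatives); with `"exclude"`
#' they are dropped. The AUC is the Wilcoxon-Mann-Whitney statistic of
#' positive versus negative regions, with ties counted 1/2.
#'
#' @param sites `GRanges` of sites.
#' @param regions `GRanges` of labeled regions with a logical `positive`
#'   metadata column.
#' @param score name of the site metadata column to rank by (default
#'   "bbls"; "nlod", "z" or any supplied column also work).
#' @param negativesMode `"include"` (default) or `"exclude"`.
#' @return AUC in `[0, 1]`.
#' @export
evaluateAuc <- function(sites, regions, score = "bbls",
                        negativesMode = c("include", "exclude")) {
  negativesMode <- match.arg(negativesMode)
  sc <- S4Vectors::mcols(sites)[[score]]
  if (is.null(sc)) stop("sites have no '", score, "' column")
  ov <- GenomicRanges::findOverlaps(regions, sites, ignore.strand = TRUE)
  regScore <- rep(-Inf, length(regions))
  if (length(ov) > 0L) {
    agg <- tapply(sc[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), max)
    regScore[as.integer(names(agg))] <- agg
  }
  pos <- S4Vectors::mcols(regions)$positive
  if (is.null(pos)) stop("regions need a logical 'positive' column")
  if (negativesMode == "exclude") {
    keep <- is.finite(regScore)
    regScore <- regScore[keep]; pos <- pos[keep]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need at least one positive and one negative region")
  r <- rank(regScore, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
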