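#' Window-correlation similarity between two motif matrices
#'
#' For every pair of length-8 column windows (one window position in each
#' matrix), the per-column Pearson correlations between the paired
#' 4-vectors are averaged; the similarity is the maximum of these averages
#' over all window pairs. Columns with zero variance (e.g. uniform columns)
#' contribute correlation 0, as they carry no shape information. By
#' default the cutoff is applied to this un-normalized window maximum;
#' `normalize = TRUE` divides by the motif length instead.
#'
#' @param a,b [MotifMatrix-class] objects of equal length >= 8.
#' @param window window width in columns (default 8).
#' @param normalize divide the result by the motif length (default FALSE).
#' @return similarity in `[-1, 1]` (or that divided by L).
#' @export
matrixSimilarity <- function(a, b, window = 8L, normalize = FALSE) {
  pa <- motifProbs(a); pb <- motifProbs(b)
  L <- ncol(pa)
  if (ncol(pb) != L) stop("matrices must have equal length")
  if (L < window)
    stop("matrices shorter than ", window, " columns are not eligible")
  nw <- L - window + 1L
  best <- -Inf
  for (i in seq_len(nw)) {
    for (j in seq_len(nw)) {
      cc <- vapply(0:(window - 1L), function(k)
        .safeCor(pa[, i + k], pb[, j + k]), numeric(1))
      best <- max(best, mean(cc))
    }
  }
  if (normalize) best / L else best
}

.safeCor <- function(x, y) {
  if (sd(x) < 1e-12 || sd(y) < 1e-12) return(0)
  cor(x, y)
}

#' Expected CG-dinucleotide frequency of a motif matrix
#'
#' Mean over adjacent column pairs of q_C(j) * q_G(j+1): the probability of
#' emitting a CpG dinucleotide at each step, averaged along the motif.
#' Used to constrain shuffled control matrices for mammalian genomes,
#' where CpG content strongly affects background hit rates.
#'
#' @param m a [MotifMatrix-class] of length >= 2.
#' @return CG frequency in `[0, 1]`.
#' @export
cgDinucleotideFreq <- function(m) {
  p <- motifProbs(m)
  L <- ncol(p)
  if (L < 2L) stop("motif must have length >= 2")
  mean(p["C", -L] * p["G", -1L])
}

#' Generate shuffled control matrices
#'
#' Draws random column permutations of the motif matrix and accepts one as
#' a control when (1) its [matrixSimilarity()] to the parent is at most
#' `simCutoff`, (2) its permutation differs from all previously accepted
#' ones, and (3), if `cgConstrained`, its expected CG-dinucleotide
#' frequency is within `cgTol` of the parent's. Drawing stops after
#' `nControls` acceptances or `maxAttempts` draws, so fewer than
#' `nControls` may be returned. Deterministic given `seed`.
#'
#' @param m parent [MotifMatrix-class], length >= 8.
#' @param nControls controls wanted (default 10).
#' @param maxAttempts maximum permutations drawn (default 10000).
#' @param simCutoff similarity acceptance cutoff (default 0.35).
#' @param cgConstrained enforce the CG constraint (default FALSE).
#' @param cgTol absolute CG-frequency tolerance (default 0.01).
#' @param seed integer RNG seed.
#' @param normalize passed to [matrixSimilarity()].
#' @return list of controls, each a list with elements `matrix` (a
#'   [MotifMatrix-class] with id `<parent>_shuf<i>`), `perm` (the column
#'   permutation) and `similarity`.
#' @export
generateControls <- function(m, nControls = 10L, maxAttempts = 10000L,
                             simCutoff = 0.35, cgConstrained = FALSE,
                             cgTol = 0.01, seed, normalize = FALSE) {
  if (missing(seed)) stop("a seed is required")
  L <- motifLength(m)
  if (L < 8L) stop("matrix shorter than 8 columns is not eligible")
  cgParent <- cgDinucleotideFreq(m)
  controls <- list()
  seen <- character(0)
  withSeed(seed, {
    for (attempt in seq_len(maxAttempts)) {
      if (length(controls) >= nControls) break
      perm <- sample.int(L)
      key <- paste(perm, collapse = ",")
      if (key %in% seen) next
      shuf <- MotifMatrix(motifProbs(m)[, perm, drop = FALSE],
                          id = sprintf("%s_shuf%d", motifId(m),
                                       length(controls) + 1L),
                          tfName = tfName(m))
      sim <- matrixSimilarity(m, shuf, normalize = normalize)
      if (sim > simCutoff) next
      if (cgConstrained &&
          abs(cgDinucleotideFreq(shuf) - cgParent) > cgTol) next
      seen <- c(seen, key)
      controls[[length(controls) + 1L]] <-
        list(matrix = shuf, perm = perm, similarity = sim)
    }
  })
  controls
}

#' Is a matrix retained for the Monte-Carlo FDR procedure?
#'
#' Retained matrices must be at least eight columns long and must admit at
#' least three sufficiently different shuffled versions.
#'
#' @param m a [MotifMatrix-class].
#' @param controls list from [generateControls()].
#' @return logical(1).
#' @export
matrixRetention <- function(m, controls) {
  motifLength(m) >= 8L && length(controls) >= 3L
}

#' Monte-Carlo FDR table over (NLOD, BBLS) thresholds
#'
#' For each grid point, counts the real-matrix sites and each control
#' matrix's sites with nlod >= nlodMin and bbls >= bblsMin, and estimates
#' FDR as median(control counts) / real count. Grid points where the real
#' count is 0 get FDR NA (undefined, not 0). FDR values above 1 are
#' reported as computed unless `clip = TRUE`.
#'
#' @param realSites `GRanges` for the real matrix with `nlod` and `bbls`
#'   metadata columns (`bbls` absent is treated as 0).
#' @param controlSites list of `GRanges`, one per control matrix, produced
#'   with identical scan and conservation parameters.
#' @param nlodGrid,bblsGrid threshold grids; every combination is
#'   evaluated. Defaults: nlod 0.70 to 1 in steps of 0.05, bbls just 0.
#' @param clip clip FDR at 1 for display (default FALSE).
#' @return data.frame with columns `nlodMin`, `bblsMin`, `realCount`,
#'   `fdr`, plus a `controlCounts` matrix column (one column per control).
#' @export
fdrTable <- function(realSites, controlSites,
                     nlodGrid = seq(0.70, 1, by = 0.05),
                     bblsGrid = 0, clip = FALSE) {
  if (length(controlSites) == 0L) stop("no control site lists supplied")
  grid <- expand.grid(nlodMin = nlodGrid, bblsMin = bblsGrid,
                      KEEP.OUT.ATTRS = FALSE)
  countAt <- function(sites, nlodMin, bblsMin) {
    mc <- S4Vectors::mcols(sites)
    b <- if ("bbls" %in% colnames(mc)) mc$bbls else rep(0, length(sites))
    sum(mc$nlod >= nlodMin & b >= bblsMin)
  }
  realCount <- mapply(countAt, nlodMin = grid$nlodMin,
                      bblsMin = grid$bblsMin,
                      MoreArgs = list(sites = realSites))
  cc <- sapply(controlSites, function(cs)
    mapply(countAt, nlodMin = grid$nlodMin, bblsMin = grid$bblsMin,
           MoreArgs = list(sites = cs)))
  cc <- matrix(cc, nrow = nrow(grid))
  fdr <- apply(cc, 1L, median) / ifelse(realCount > 0, realCount, NA)
  if (clip) fdr <- pmin(fdr, 1)
  out <- data.frame(nlodMin = grid$nlodMin, bblsMin = grid$bblsMin,
                    realCount = realCount, fdr = fdr)
  out$controlCounts <- cc
  out
}

#' Per-site FDR from an FDR table
#'
#' Each site is assigned the minimum FDR over all grid points whose
#' thresholds it satisfies (NA when it satisfies none with a defined FDR).
#'
#' @param sites `GRanges` with `nlod` (and optionally `bbls`) columns.
#' @param tab data.frame from [fdrTable()].
#' @return numeric vector of per-site FDRs.
#' @export
siteFdr <- function(sites, tab) {
  mc <- S4Vectors::mcols(sites)
  b <- if ("bbls" %in% colnames(mc)) mc$bbls else rep(0, length(sites))
  vapply(seq_along(sites), function(i) {
    ok <- mc$nlod[i] >= tab$nlodMin & b[i] >= tab$bblsMin &
      !is.na(tab$fdr)
    if (!any(ok)) NA_real_ else min(tab$fdr[ok])
  }, numeric(1))
}
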