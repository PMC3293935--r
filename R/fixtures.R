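#' Random phylogeny for simulations
#'
#' Random (pure-birth style) topology over the given species with
#' independent exponential branch lengths; deterministic given the seed.
#'
#' @param species character vector of leaf names (>= 2).
#' @param meanBranch mean branch length (default 0.5 substitutions/site,
#'   a typical deep-mammal scale).
#' @param seed integer RNG seed.
#' @return an [ape::phylo] tree.
#' @export
randomTree <- function(species, meanBranch = 0.5, seed) {
  n <- length(species)
  if (n < 2L) stop("need at least 2 species")
  withSeed(seed, {
    tr <- ape::rtree(n, br = function(k) rexp(k, rate = 1 / meanBranch))
  })
  tr$tip.label <- species[as.integer(sub("^t", "", tr$tip.label))]
  tr
}

#' Simulate a reference chromosome with planted motif instances
#'
#' Draws an i.i.d. background sequence and overwrites the given loci with
#' the supplied motif instances (typically consensus sequences, optionally
#' pre-mutated by the caller). Plants may not overlap.
#'
#' @param length chromosome length in bp.
#' @param plants optional data.frame with columns `pos` (1-based start) and
#'   `seq` (the planted sequence).
#' @param background length-4 A/C/G/T probabilities (default uniform).
#' @param chromName chromosome name (default "chr1").
#' @param seed integer RNG seed.
#' @return a named `DNAStringSet` of one chromosome.
#' @export
simulateReference <- function(length, plants = NULL,
                              background = rep(0.25, 4),
                              chromName = "chr1", seed) {
  withSeed(seed, {
    bases <- sample(DNA_BASES4, length, replace = TRUE, prob = background)
  })
  if (!is.null(plants) && nrow(plants) > 0L) {
    ends <- plants$pos + nchar(plants$seq) - 1L
    if (any(plants$pos < 1L) || any(ends > length))
      stop("planted site outside genome bounds")
    o <- order(plants$pos)
    if (any(plants$pos[o][-1L] <= ends[o][-length(ends)]))
      stop("planted sites overlap")
    for (i in seq_len(nrow(plants))) {
      idx <- plants$pos[i]:ends[i]
      bases[idx] <- strsplit(plants$seq[i], "")[[1]]
    }
  }
  g <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(g) <- chromName
  g
}

#' Simulate an identity-aligned multi-species alignment
#'
#' Each non-reference species genome is a copy of the reference with a
#' fixed number of uniform point substitutions outside the planted loci;
#' at each planted locus, carrier species keep the planted sequence (less
#' `carrierMutations` substitutions inside it) while non-carriers have it
#' replaced with fresh background sequence. The alignment is emitted as
#' identity-aligned MAF blocks tiling the reference (`blockLength` aligned
#' columns separated by `blockGap` unaligned bp), with identical
#' coordinates in every species (no indels; insertion/deletion structure
#' is emulated by block gaps instead, see [simulateLiftCase()]).
#'
#' @param reference named `DNAStringSet`/character, one chromosome (from
#'   [simulateReference()]).
#' @param species character vector of non-reference species names.
#' @param plants data.frame with `pos`, `seq` and a list-column `carriers`
#'   (character vector of carrier species per plant), or NULL.
#' @param mutations substitutions per species genome outside plants; a
#'   single count or a named vector per species (default 0).
#' @param carrierMutations substitutions inside each carried plant
#'   (default 0).
#' @param blockLength aligned block length in bp (default 100).
#' @param blockGap unaligned bp between consecutive blocks (default 0).
#' @param refSpecies reference species name (default "ref").
#' @param background background base probabilities for non-carrier
#'   replacement sequence.
#' @param seed integer RNG seed.
#' @return list with `maf` (list of blocks, see [readMAF()]), `genomes`
#'   (named list: species -> named character vector of chromosomes,
#'   reference included) and `refSpecies`.
#' @export
simulateAlignment <- function(reference, species, plants = NULL,
                              mutations = 0, carrierMutations = 0,
                              blockLength = 100L, blockGap = 0L,
                              refSpecies = "ref",
                              background = rep(0.25, 4), seed) {
  chrs <- .asCharGenome(reference)
  chromName <- names(chrs)[1L]
  refSeq <- chrs[[1L]]
  n <- nchar(refSeq)
  plantIdx <- integer(0)
  if (!is.null(plants) && nrow(plants) > 0L)
    plantIdx <- unlist(lapply(seq_len(nrow(plants)), function(i)
      plants$pos[i]:(plants$pos[i] + nchar(plants$seq[i]) - 1L)))
  if (length(mutations) == 1L && is.null(names(mutations)))
    mutations <- setNames(rep(mutations, length(species)), species)
  genomes <- list()
  genomes[[refSpecies]] <- setNames(refSeq, chromName)
  withSeed(seed, {
    for (sp in species) {
      bases <- strsplit(refSeq, "")[[1]]
      free <- setdiff(seq_len(n), plantIdx)
      nmut <- min(mutations[[sp]], length(free))
      if (nmut > 0L) {
        at <- sample(free, nmut)
        bases[at] <- vapply(bases[at], .otherBase, character(1))
      }
      if (length(plantIdx) > 0L) {
        for (i in seq_len(nrow(plants))) {
          idx <- plants$pos[i]:(plants$pos[i] + nchar(plants$seq[i]) - 1L)
          if (sp %in% plants$carriers[[i]]) {
            bases[idx] <- strsplit(plants$seq[i], "")[[1]]
            if (carrierMutations > 0L) {
              at <- sample(idx, min(carrierMutations, length(idx)))
              bases[at] <- vapply(bases[at], .otherBase, character(1))
            }
          } else {
            bases[idx] <- sample(DNA_BASES4, length(idx), replace = TRUE,
                                 prob = background)
          }
        }
      }
      genomes[[sp]] <- setNames(paste(bases, collapse = ""), chromName)
    }
  })
  starts <- seq(1L, n, by = blockLength + blockGap)
  blocks <- lapply(starts, function(s) {
    e <- min(s + blockLength - 1L, n)
    do.call(rbind, lapply(names(genomes), function(sp) {
      data.frame(species = sp, chrom = chromName, start = s - 1L,
                 size = e - s + 1L, strand = "+", srcSize = n,
                 text = substr(genomes[[sp]][[chromName]], s, e),
                 stringsAsFactors = FALSE)
    }))
  })
  list(maf = blocks, genomes = genomes, refSpecies = refSpecies)
}

.otherBase <- function(b) sample(setdiff(DNA_BASES4, b), 1L)

#' Pathological alignment-lifting fixtures
#'
#' Generates the single-site scenarios that motivate padded extraction and
#' block merging: `"exact"` (species motif at the aligned position),
#' `"shifted"` (species motif displaced `shift` bp out of alignment frame,
#' still inside the `pad` window) and `"split"` (species motif intact in
#' its genome but broken across two MAF blocks whose species rows are
#' `gap` bp apart, so only gap-bounded merging can reassemble it).
#'
#' @param motifSeq the motif instance to plant (e.g. [consensusSeq()] of
#'   the matrix).
#' @param type scenario, one of "exact", "shifted", "split".
#' @param shift displacement in bp for "shifted" (default 8).
#' @param gap unaligned species bp between the two blocks for "split"
#'   (default 5).
#' @param pad block half-width around the site (default 15, matching the
#'   extraction pad).
#' @param flank background flank length on each side (default 60).
#' @param species,refSpecies species names.
#' @param seed integer RNG seed.
#' @return list with `refGenome` (named `DNAStringSet`), `motifStart`
#'   (1-based start of the reference plant), `maf` (block list),
#'   `genomeLookup` (named list for [bestSpeciesHits()]) and `refSpecies`.
#' @export
simulateLiftCase <- function(motifSeq, type = c("exact", "shifted", "split"),
                             shift = 8L, gap = 5L, pad = 15L, flank = 60L,
                             species = "other", refSpecies = "ref",
                             seed) {
  type <- match.arg(type)
  L <- nchar(motifSeq)
  n <- 2L * flank + L
  refG <- simulateReference(n, data.frame(pos = flank + 1L, seq = motifSeq),
                            chromName = "chr1", seed = seed)
  refSeq <- as.character(refG)[[1L]]
  p0 <- flank                                   # 0-based ref motif start
  spPlant <- switch(type, exact = flank + 1L,
                    shifted = flank + 1L + shift, split = flank + 1L)
  spG <- simulateReference(n + (type == "split") * gap,
                           data.frame(pos = spPlant, seq = motifSeq),
                           chromName = "chr1", seed = seed + 1L)
  spSeq <- as.character(spG)[[1L]]
  q0 <- spPlant - 1L
  mkRow <- function(sp, seq, start, size, srcSize)
    data.frame(species = sp, chrom = "chr1", start = start, size = size,
               strand = "+", srcSize = srcSize,
               text = substr(seq, start + 1L, start + size),
               stringsAsFactors = FALSE)
  if (type == "split") {
    j <- L %/% 2L
    stopifnot(j >= 1L, j + gap <= L - 1L)
    b1 <- rbind(mkRow(refSpecies, refSeq, p0 - pad, pad + j, n),
                mkRow(species, spSeq, q0 - pad, pad + j, nchar(spSeq)))
    b2 <- rbind(mkRow(refSpecies, refSeq, p0 + j, L - j + pad, n),
                mkRow(species, spSeq, q0 + j + gap, L - j + pad,
                      nchar(spSeq)))
    maf <- list(b1, b2)
  } else {
    start <- p0 - pad
    size <- L + 2L * pad
    maf <- list(rbind(mkRow(refSpecies, refSeq, start, size, n),
                      mkRow(species, spSeq, start, size, nchar(spSeq))))
  }
  lookup <- list(setNames(list(spSeq), "chr1"))
  names(lookup) <- species
  list(refGenome = refG, motifStart = flank + 1L, maf = maf,
       genomeLookup = lookup, refSpecies = refSpecies)
}

#' Simulate gene, mask, SNP and labeled-region annotations for a fixture
#'
#' Places a TSS within `tssWindow` bp of a configurable fraction of the
#' planted sites (emulating the concentration of regulatory sites near
#' transcription starts) and the rest uniformly; emits exclusion masks
#' over chosen plants, SNPs at the midpoints of chosen plants, and a
#' labeled region set (positive regions covering chosen plants, negative
#' regions elsewhere, non-overlapping).
#'
#' @param plants data.frame with `pos` and `seq` (as planted).
#' @param genomeLength chromosome length.
#' @param chromName chromosome name (default "chr1").
#' @param fractionNearTss fraction of plants given a nearby TSS
#'   (default 1).
#' @param nearIdx explicit indices of the plants given a nearby TSS
#'   (overrides `fractionNearTss`).
#' @param tssIdx indices of the plants that get a TSS at all (default all;
#'   restricting this leaves the other plants' neighbourhoods gene-free).
#' @param tssWindow maximum |TSS - plant| distance in bp (default 1000).
#' @param maskIdx indices of plants to cover with a mask (default none).
#' @param snpIdx indices of plants given a midpoint SNP (default none).
#' @param positiveIdx indices of plants covered by positive regions
#'   (default all).
#' @param negativeIdx indices of plants covered by negative regions
#'   (default none; use for decoy plants).
#' @param nNegativeRegions additional plant-free negative regions
#'   (default 5).
#' @param regionPad padding of labeled regions around each plant
#'   (default 50).
#' @param seed integer RNG seed.
#' @return list of `GRanges`: `tss` (width-1, `gene_id`, stranded),
#'   `masks`, `snps` (`snp_id`), `regions` (logical `positive`).
#' @export
simulateAnnotations <- function(plants, genomeLength, chromName = "chr1",
                                fractionNearTss = 1, nearIdx = NULL,
                                tssIdx = NULL, tssWindow = 1000L,
                                maskIdx = integer(0), snpIdx = integer(0),
                                positiveIdx = seq_len(nrow(plants)),
                                negativeIdx = integer(0),
                                nNegativeRegions = 5L, regionPad = 50L,
                                seed) {
  np <- nrow(plants)
  lens <- nchar(plants$seq)
  mids <- plants$pos + lens %/% 2L
  withSeed(seed, {
    near <- if (is.null(nearIdx)) sample(np, round(fractionNearTss * np))
            else nearIdx
    tssPos <- integer(np)
    tssPos[near] <- pmin(pmax(mids[near] +
      sample(-tssWindow:tssWindow, length(near), replace = TRUE), 1L),
      genomeLength)
    far <- setdiff(seq_len(np), near)
    tssPos[far] <- sample.int(genomeLength, length(far))
    tssStrand <- sample(c("+", "-"), np, replace = TRUE)
    negFree <- sample.int(genomeLength - 2L * regionPad - 1L,
                          nNegativeRegions)
  })
  tss <- GenomicRanges::GRanges(chromName,
    IRanges::IRanges(start = tssPos, width = 1L), strand = tssStrand,
    gene_id = paste0("gene", seq_len(np)))
  if (!is.null(tssIdx)) tss <- tss[tssIdx]
  mkRegions <- function(idx) {
    GenomicRanges::GRanges(rep(chromName, length(idx)), IRanges::IRanges(
      start = pmax(1L, plants$pos[idx] - regionPad),
      end = pmin(genomeLength, plants$pos[idx] + lens[idx] - 1L +
                   regionPad)))
  }
  masks <- mkRegions(maskIdx)
  snps <- GenomicRanges::GRanges(rep(chromName, length(snpIdx)),
    IRanges::IRanges(start = mids[snpIdx], width = 1L))
  S4Vectors::mcols(snps)$snp_id <- if (length(snpIdx) > 0L)
    paste0("rsF", snpIdx) else character(0)
  posR <- mkRegions(positiveIdx)
  negR <- mkRegions(negativeIdx)
  free <- GenomicRanges::GRanges(rep(chromName, length(negFree)),
    IRanges::IRanges(start = negFree, width = 2L * regionPad + 1L))
  allPlants <- mkRegions(seq_len(np))
  drop <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(free, allPlants)))
  if (length(drop) > 0L) free <- free[-drop]
  negR <- c(negR, free)
  regions <- c(posR, negR)
  S4Vectors::mcols(regions)$positive <-
    rep(c(TRUE, FALSE), c(length(posR), length(negR)))
  list(tss = tss, masks = masks, snps = snps, regions = regions)
}

#' The standard end-to-end fixture
#'
#' A coherent synthetic study used by the test suite and the
#' reproducibility script: an informative 12-bp motif matrix; a random
#' 8-species phylogeny; a 30 kb reference with 12 conserved plants
#' (carried by every species) and 12 non-conserved decoy plants (reference
#' only); an identity-aligned MAF; TSSs placed within 1 kb of the
#' conserved plants only; and a labeled region set (conserved plants
#' positive, decoys negative).
#'
#' @param seed integer RNG seed driving every random component.
#' @param nConserved,nDecoy numbers of conserved and decoy plants.
#' @param genomeLength reference length in bp (default 30000).
#' @param mutations background substitutions per species genome
#'   (default 150, i.e. 0.5% divergence).
#' @return list with `motif`, `tree`, `genome`, `plants`, `aln` (from
#'   [simulateAlignment()]), `ann` (from [simulateAnnotations()]),
#'   `species`, `refSpecies`, `conservedIdx`, `decoyIdx`.
#' @export
standardFixture <- function(seed, nConserved = 12L, nDecoy = 12L,
                            genomeLength = 30000L, mutations = 150L) {
  motif <- fixtureMotif()
  cons <- consensusSeq(motif)
  species <- c("ref", paste0("sp", 2:8))
  tree <- randomTree(species, seed = seed + 1L)
  np <- nConserved + nDecoy
  withSeed(seed + 2L, {
    slots <- seq(500L, genomeLength - 500L, length.out = np)
    pos <- as.integer(slots + sample(-100:100, np, replace = TRUE))
  })
  conservedIdx <- seq_len(nConserved)
  decoyIdx <- nConserved + seq_len(nDecoy)
  plants <- data.frame(pos = pos, seq = cons, stringsAsFactors = FALSE)
  plants$carriers <- c(rep(list(species), nConserved),
                       rep(list(character(0)), nDecoy))
  genome <- simulateReference(genomeLength, plants, seed = seed + 3L)
  aln <- simulateAlignment(genome, setdiff(species, "ref"), plants,
                           mutations = mutations, blockLength = 200L,
                           refSpecies = "ref", seed = seed + 4L)
  ann <- simulateAnnotations(plants, genomeLength, nearIdx = conservedIdx,
                             tssIdx = conservedIdx,
                             positiveIdx = conservedIdx,
                             negativeIdx = decoyIdx,
                             nNegativeRegions = 5L, seed = seed + 5L)
  list(motif = motif, tree = tree, genome = genome, plants = plants,
       aln = aln, ann = ann, species = species, refSpecies = "ref",
       conservedIdx = conservedIdx, decoyIdx = decoyIdx)
}

#' A reference 12-bp informative motif matrix
#'
#' Mixed sharp (0.85) and softer (0.70) columns over all four bases: high
#' information content so planted consensus sites calibrate to large
#' z-scores, yet column-diverse so column shuffles are dissimilar enough
#' to pass the control-matrix similarity cutoff.
#'
#' @param id matrix id (default "FIX0001").
#' @return a [MotifMatrix-class].
#' @export
fixtureMotif <- function(id = "FIX0001") {
  cons <- c("A", "C", "G", "T", "A", "G", "C", "A", "T", "G", "C", "T")
  major <- rep(c(0.85, 0.70), 6L)
  probs <- vapply(seq_along(cons), function(j) {
    p <- rep((1 - major[j]) / 3, 4L)
    p[match(cons[j], DNA_BASES4)] <- major[j]
    p
  }, numeric(4))
  rownames(probs) <- DNA_BASES4
  MotifMatrix(probs, id = id, tfName = "FIXTF")
}
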