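#' Add BBLS conservation scores to scanned sites
#'
#' For each site: extract the MAF blocks overlapping its padded interval,
#' find the best motif match per species, convert the per-species hits to
#' leaf presence probabilities, and compute the BBLS on the tree. Sites
#' failing the minimum-species requirement are dropped.
#'
#' @param sites `GRanges` from [scanGenome()].
#' @param maf block list from [readMAF()] (or a fixture's `maf`).
#' @param tree [ape::phylo] whose tips cover the alignment species.
#' @param lom,cal matrix and calibration used for the scan.
#' @param refSpecies reference species name in the MAF.
#' @param pad extraction pad in bp (default 15).
#' @param maxGap block-merging gap bound in bp (default 30; negative
#'   disables merging).
#' @param genomeLookup optional per-species genome lookup for gap filling.
#' @param zFloor z threshold for presence probabilities (default 1.64).
#' @param refCertain force the reference presence probability to 1
#'   (default FALSE: the reference uses its own NLOD).
#' @param minSpecies minimum conserved non-reference species (default 0).
#' @param eligibleSpecies optional restriction for `minSpecies` counting.
#' @return the input `GRanges` with `bbls` and `alignedSpeciesCount`
#'   metadata columns, minus sites failing the species filter.
#' @export
conservationScore <- function(sites, maf, tree, lom, cal, refSpecies,
                              pad = 15L, maxGap = 30L, genomeLookup = NULL,
                              zFloor = 1.64, refCertain = FALSE,
                              minSpecies = 0L, eligibleSpecies = NULL) {
  if (length(sites) == 0L) {
    S4Vectors::mcols(sites)$bbls <- numeric(0)
    S4Vectors::mcols(sites)$alignedSpeciesCount <- integer(0)
    return(sites)
  }
  bblsV <- numeric(length(sites))
  alnV <- integer(length(sites))
  keep <- logical(length(sites))
  for (i in seq_along(sites)) {
    site <- sites[i]
    blocks <- extractBlocks(site, maf, refSpecies, pad = pad)
    hits <- bestSpeciesHits(site, blocks, lom, cal, refSpecies,
                            maxGap = maxGap, genomeLookup = genomeLookup)
    p <- leafProbabilities(hits, tree, zFloor = zFloor,
                           refSpecies = refSpecies,
                           refCertain = refCertain)
    bblsV[i] <- bbls(tree, p)
    alnV[i] <- S4Vectors::metadata(hits)$alignedSpeciesCount
    keep[i] <- minSpeciesFilter(hits, minSpecies, refSpecies,
                                eligibleSpecies = eligibleSpecies,
                                zFloor = zFloor)
  }
  S4Vectors::mcols(sites)$bbls <- bblsV
  S4Vectors::mcols(sites)$alignedSpeciesCount <- alnV
  sites[keep]
}

#' Scan, conserve and FDR-score one motif matrix end to end
#'
#' Runs the full Monte-Carlo FDR procedure for a matrix: builds its
#' bounded log-odds matrix and z calibration, scans the genome, optionally
#' adds BBLS conservation over a MAF and tree, generates shuffled control
#' matrices, repeats the identical pipeline for each control, and
#' tabulates FDR over the threshold grid.
#'
#' @param motif a [MotifMatrix-class].
#' @param genome reference genome.
#' @param seed integer seed driving calibration and shuffling.
#' @param background background frequencies (default estimated from the
#'   genome).
#' @param c bounded-log constant (default -3).
#' @param nSamples calibration sample count (default 1e5).
#' @param zMin,k scan thresholds (see [scanGenome()]).
#' @param masks optional mask `GRanges`.
#' @param maf,tree,refSpecies,genomeLookup conservation inputs; leave
#'   `maf` NULL to skip conservation (all bbls treated as 0).
#' @param minSpecies,zFloor conservation filter parameters.
#' @param nControls,simCutoff,cgConstrained control-matrix parameters
#'   (see [generateControls()]).
#' @param nlodGrid,bblsGrid FDR threshold grids (see [fdrTable()]).
#' @return list with `sites` (real-matrix `GRanges`, with per-site `fdr`
#'   column), `controls` (from [generateControls()]), `controlSites`
#'   (list of `GRanges`), `fdr` (the [fdrTable()] data.frame) and
#'   `retained` (the [matrixRetention()] verdict).
#' @export
runFdrPipeline <- function(motif, genome, seed,
                           background = NULL, c = -3, nSamples = 100000L,
                           zMin = 4.27, k = 100000L, masks = NULL,
                           maf = NULL, tree = NULL, refSpecies = "ref",
                           genomeLookup = NULL, minSpecies = 0L,
                           zFloor = 1.64, nControls = 10L,
                           simCutoff = 0.35, cgConstrained = FALSE,
                           nlodGrid = seq(0.70, 1, by = 0.05),
                           bblsGrid = 0) {
  if (is.null(background)) background <- backgroundFrequencies(genome)
  runOne <- function(m, sd) {
    lom <- buildLogOddsMatrix(m, background, c = c)
    cal <- calibrateZ(lom, genome, nSamples = nSamples, seed = sd)
    sites <- scanGenome(genome, lom, cal, zMin = zMin, k = k,
                        masks = masks)
    if (!is.null(maf))
      sites <- conservationScore(sites, maf, tree, lom, cal, refSpecies,
                                 genomeLookup = genomeLookup,
                                 zFloor = zFloor, minSpecies = minSpecies)
    sites
  }
  realSites <- runOne(motif, seed)
  controls <- generateControls(motif, nControls = nControls,
                               simCutoff = simCutoff,
                               cgConstrained = cgConstrained, seed = seed)
  controlSites <- lapply(seq_along(controls), function(i)
    runOne(controls[[i]]$matrix, seed + i))
  retained <- matrixRetention(motif, controls)
  tab <- NULL
  if (length(controlSites) > 0L) {
    tab <- fdrTable(realSites, controlSites, nlodGrid = nlodGrid,
                    bblsGrid = bblsGrid)
    S4Vectors::mcols(realSites)$fdr <- siteFdr(realSites, tab)
  }
  list(sites = realSites, controls = controls,
       controlSites = controlSites, fdr = tab, retained = retained)
}
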