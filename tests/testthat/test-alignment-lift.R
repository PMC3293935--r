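# hand-built 3-block MAF on chr1: ref blocks [100,140), [140,160), [170,210)
threeBlockMaf <- function() {
  mkBlock <- function(refStart, size, spStart) {
    refTxt <- strrep("A", size)
    spTxt <- strrep("C", size)
    data.frame(species = c("ref", "sp2"), chrom = "chr1",
               start = c(refStart, spStart), size = size, strand = "+",
               srcSize = 1000L, text = c(refTxt, spTxt),
               stringsAsFactors = FALSE)
  }
  list(mkBlock(100L, 40L, 500L), mkBlock(140L, 20L, 540L),
       mkBlock(170L, 40L, 600L))
}

siteAt <- function(start1, width = 12L) {
  gr <- GRanges("chr1", IRanges::IRanges(start1, width = width),
                strand = "+")
  mcols(gr) <- DataFrame(matrixId = "M", seq = strrep("A", width),
                         lod = 1, nlod = 0.9, z = 5)
  gr
}

test_that("extractBlocks returns blocks overlapping the padded interval", {
  maf <- threeBlockMaf()
  # fully inside block 1: 0-based [110,122) padded [95,137)
  expect_equal(length(extractBlocks(siteAt(111), maf, "ref")), 1L)
  # spanning the block 1 / block 2 boundary at 0-based 140
  expect_equal(length(extractBlocks(siteAt(135), maf, "ref")), 2L)
  # site 0-based [145,157) touches block 2 directly; the 15 bp pad pulls
  # in block 1 (boundary 140 > 130) and block 3, 13 bp away (170 < 172)
  expect_equal(length(extractBlocks(siteAt(146), maf, "ref")), 3L)
  # without the pad only the directly overlapped block is returned
  expect_equal(length(extractBlocks(siteAt(146), maf, "ref", pad = 0L)),
               1L)
  # far away: none
  expect_equal(length(extractBlocks(siteAt(900), maf, "ref")), 0L)
})

mkRow <- function(sp, chrom, start, text, strand = "+") {
  data.frame(species = sp, chrom = chrom, start = start,
             size = nchar(gsub("-", "", text)), strand = strand,
             srcSize = 100000L, text = text, stringsAsFactors = FALSE)
}

test_that("mergeBlocks bridges gaps up to 30 bp and respects boundaries", {
  rowA <- mkRow("sp2", "chr1", 100L, "ACGT")
  gapAt <- function(gap) list(rowA, mkRow("sp2", "chr1", 104L + gap,
                                          "TTTT"))
  # adjacent rows concatenate
  expect_equal(mergeBlocks(gapAt(0), "sp2"), "ACGTTTTT")
  # gap 5 without a lookup is N-filled; length = 4 + 5 + 4
  seg <- mergeBlocks(gapAt(5), "sp2")
  expect_equal(seg, "ACGTNNNNNTTTT")
  expect_equal(nchar(seg), 13L)
  # gap 5 with a genome lookup takes the intervening sequence
  genome <- list(chr1 = paste(rep("G", 200), collapse = ""))
  expect_equal(mergeBlocks(gapAt(5), "sp2", genomeLookup = genome),
               "ACGTGGGGGTTTT")
  # gap 30 merges, 31 does not
  expect_length(mergeBlocks(gapAt(30), "sp2"), 1L)
  expect_length(mergeBlocks(gapAt(31), "sp2"), 2L)
  # different chromosome or strand never merges
  expect_length(mergeBlocks(list(rowA, mkRow("sp2", "chr2", 104L, "TTTT")),
                            "sp2"), 2L)
  expect_length(mergeBlocks(list(rowA, mkRow("sp2", "chr1", 104L, "TTTT",
                                             strand = "-")), "sp2"), 2L)
})

test_that("bestSpeciesHits lifts identical, gapped and shifted species", {
  motif <- fixtureMotif()
  lom <- buildLogOddsMatrix(motif)
  g <- simulateReference(10000, seed = 2)
  cal <- calibrateZ(lom, g, nSamples = 20000, seed = 3)
  cons <- consensusSeq(motif)

  # identical aligned row reproduces the reference NLOD
  fx <- simulateLiftCase(cons, "exact", seed = 41)
  site <- scanGenome(fx$refGenome, lom, cal, zMin = zScore(1, cal) - 1e-9)
  blocks <- extractBlocks(site, fx$maf, fx$refSpecies)
  hits <- as.data.frame(bestSpeciesHits(site, blocks, lom, cal,
                                        fx$refSpecies,
                                        genomeLookup = fx$genomeLookup))
  expect_equal(hits$nlod[hits$species == "other"], 1)
  expect_equal(hits$nlod[hits$species == "ref"], 1)

  # species aligned only by gaps is omitted
  gapBlock <- list(rbind(
    mkRow("ref", "chr1", 45L, strrep("A", 42)),
    mkRow("sp2", "chr1", 45L, strrep("A", 42)),
    data.frame(species = "spGap", chrom = "chr1", start = 0L, size = 0L,
               strand = "+", srcSize = 1000L, text = strrep("-", 42),
               stringsAsFactors = FALSE)))
  h2 <- as.data.frame(bestSpeciesHits(siteAt(60), gapBlock, lom, cal,
                                      "ref"))
  expect_false("spGap" %in% h2$species)
  expect_true("sp2" %in% h2$species)
  expect_equal(metadata(bestSpeciesHits(siteAt(60), gapBlock, lom, cal,
                                        "ref"))$alignedSpeciesCount, 2L)

  # motif shifted 4 bp out of frame is still found at full score
  fx4 <- simulateLiftCase(cons, "shifted", shift = 4L, seed = 43)
  site4 <- scanGenome(fx4$refGenome, lom, cal, zMin = zScore(1, cal) - 1e-9)
  b4 <- extractBlocks(site4, fx4$maf, fx4$refSpecies)
  h4 <- as.data.frame(bestSpeciesHits(site4, b4, lom, cal, fx4$refSpecies,
                                      genomeLookup = fx4$genomeLookup))
  expect_equal(h4$nlod[h4$species == "other"], 1)
})

test_that("minSpeciesFilter counts conserved eligible species only", {
  mkHits <- function(df) S4Vectors::DataFrame(df)
  hits <- mkHits(data.frame(
    species = c("ref", "mouse", "dog", "chimp", "macaque"),
    seq = "X", nlod = c(1, .9, .9, .9, .9),
    z = c(6, 5, 5, 5, 0.5), stringsAsFactors = FALSE))
  expect_true(minSpeciesFilter(hits, 1, "ref"))
  expect_true(minSpeciesFilter(hits, 0, "ref"))
  expect_true(minSpeciesFilter(hits, 3, "ref"))      # macaque z too low
  expect_false(minSpeciesFilter(hits, 4, "ref"))
  # restricted to non-primates: only mouse and dog count
  nonPrimates <- c("mouse", "dog")
  expect_true(minSpeciesFilter(hits, 2, "ref",
                               eligibleSpecies = nonPrimates))
  expect_false(minSpeciesFilter(hits, 3, "ref",
                                eligibleSpecies = nonPrimates))
  expect_error(minSpeciesFilter(hits, -1, "ref"), ">= 0")
})

test_that("MAF files round-trip through writer and reader", {
  maf <- threeBlockMaf()
  path <- tempfile(fileext = ".maf")
  writeMAF(maf, path)
  back <- readMAF(path)
  expect_equal(length(back), 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$species, maf[[i]]$species)
    expect_equal(back[[i]]$start, maf[[i]]$start)
    expect_equal(back[[i]]$text, maf[[i]]$text)
  }
  # malformed MAF (size mismatch) is rejected
  bad <- maf
  bad[[1]]$size[1] <- 39L
  path2 <- tempfile(fileext = ".maf")
  writeMAF(bad, path2)
  expect_error(readMAF(path2), "size")
})
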