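test_that("redundancyFilter keeps the max-BBLS representative per TF group", {
  tfMap <- c(M1 = "TFA", M2 = "TFA", M3 = "TFB")
  s <- c(fakeSites(100, matrixId = "M1", bbls = 2.0, nlod = 0.8),
         fakeSites(105, matrixId = "M2", bbls = 3.5, nlod = 0.7),
         fakeSites(300, matrixId = "M1", bbls = 1.0, nlod = 0.9))
  out <- redundancyFilter(s, tfMap)
  expect_equal(start(out), c(105L, 300L))
  expect_equal(mcols(out)$bbls, c(3.5, 1.0))
  # overlapping sites of different TFs both survive
  s2 <- c(fakeSites(100, matrixId = "M1", bbls = 2.0),
          fakeSites(105, matrixId = "M3", bbls = 1.0))
  expect_equal(length(redundancyFilter(s2, tfMap)), 2L)
  # BBLS tie: higher NLOD wins, then leftmost start
  s3 <- c(fakeSites(100, matrixId = "M1", bbls = 2, nlod = 0.7),
          fakeSites(104, matrixId = "M2", bbls = 2, nlod = 0.9))
  expect_equal(start(redundancyFilter(s3, tfMap)), 104L)
  s4 <- c(fakeSites(100, matrixId = "M1", bbls = 2, nlod = 0.9),
          fakeSites(104, matrixId = "M2", bbls = 2, nlod = 0.9))
  expect_equal(start(redundancyFilter(s4, tfMap)), 100L)
  expect_error(redundancyFilter(fakeSites(1, matrixId = "MX"), tfMap),
               "MX")
})

test_that("redundancyFilter agrees with a brute-force grouping oracle", {
  set.seed(55)
  n <- 400
  sites <- fakeSites(sample(1:5000, n, replace = TRUE), width = 20,
                     matrixId = sample(c("M1", "M2"), n, replace = TRUE),
                     nlod = runif(n), bbls = runif(n, 0, 5))
  tfMap <- c(M1 = "TFA", M2 = "TFA")
  out <- redundancyFilter(sites, tfMap)
  # no overlapping pair within the TF remains
  expect_equal(length(findOverlaps(out, drop.self = TRUE,
                                   ignore.strand = TRUE)), 0L)
  expect_lte(length(out), length(sites))
  # representatives are the max-BBLS members of oracle groups
  grp <- oracleGroups(sites)
  reps <- vapply(split(seq_len(n), grp), function(g) {
    o <- order(-mcols(sites)$bbls[g], -mcols(sites)$nlod[g],
               start(sites)[g])
    g[o[1]]
  }, numeric(1))
  want <- sort(sites[sort(reps)])
  expect_equal(sort(start(out)), sort(start(want)))
  expect_equal(sort(mcols(out)$bbls), sort(mcols(want)$bbls))
})

mkTss <- function(pos, strand = "+", gene = paste0("g", seq_along(pos)))
  GRanges("chr1", IRanges::IRanges(pos, width = 1), strand = strand,
          gene_id = gene)

test_that("tssDistance picks the nearest TSS and signs by gene strand", {
  # site midpoint at the TSS
  s <- fakeSites(95, width = 11)           # midpoint 100
  expect_equal(tssDistance(s, mkTss(100))$distance, 0)
  # 500 bp 5' of a plus-strand TSS is upstream: -500
  s2 <- fakeSites(495, width = 11)         # midpoint 500
  expect_equal(tssDistance(s2, mkTss(1000))$distance, -500)
  # same geometry on a minus-strand gene is downstream: +500
  expect_equal(tssDistance(s2, mkTss(1000, strand = "-"))$distance, 500)
  # nearest of two TSSs at 300 and 800 bp
  d <- tssDistance(s2, mkTss(c(800, 1300)))
  expect_equal(d$gene_id, "g1")
  expect_equal(d$distance, -300)   # 300 bp upstream of the nearer gene
  # chromosome with no annotation: undefined
  sOff <- GRanges("chr9", IRanges::IRanges(1, 10))
  mcols(sOff) <- DataFrame(matrixId = "M1", nlod = 1, bbls = 1)
  expect_true(is.na(tssDistance(sOff, mkTss(100))$distance))
})

test_that("promoterWindowSelect applies inclusive -15k/+3k bounds", {
  s <- fakeSites(c(1, 2, 3, 4))
  mcols(s)$distance <- c(-15000, -15001, 3000, 3001)
  kept <- promoterWindowSelect(s)
  expect_equal(start(kept), c(1L, 3L))
  mcols(s)$gene_id <- c("a", "a", "b", "b")
  expect_equal(start(promoterWindowSelect(s, genes = "a")), 1L)
})

test_that("snpOverlap uses half-open interval semantics", {
  site <- fakeSites(100, width = 10)       # covers bases 100..109
  snpAt <- function(pos) GRanges("chr1", IRanges::IRanges(pos, width = 1),
                                 snp_id = "rs1")
  expect_equal(nrow(snpOverlap(site, snpAt(100))), 1L)  # at start
  expect_equal(nrow(snpOverlap(site, snpAt(109))), 1L)  # last base
  expect_equal(nrow(snpOverlap(site, snpAt(110))), 0L)  # one past the end
  expect_equal(nrow(snpOverlap(site, snpAt(99))), 0L)   # one before
  both <- snpOverlap(c(site, fakeSites(105, width = 10)), snpAt(105))
  expect_equal(both$site, c(1L, 2L))
})

test_that("minimal VCF and SNP BED readers yield width-1 positions", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=100000>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t150\trs42\tA\tC\t.\t.\t.",
               "chr1\t300\t.\tG\tT\t.\t.\t."), vcf)
  snps <- readMinimalVCF(vcf)
  expect_equal(start(snps), c(150L, 300L))
  expect_equal(width(snps), c(1L, 1L))
  expect_equal(mcols(snps)$snp_id, c("rs42", "snp2"))
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t149\t150\trs42", "chr1\t299\t300\trs99"), bed)
  sb <- readSnpBed(bed)
  expect_equal(start(sb), c(150L, 300L))
  expect_equal(mcols(sb)$snp_id, c("rs42", "rs99"))
})

test_that("bblsQuartileStratify forms equal groups with stable tie order", {
  s <- fakeSites(seq(1, by = 100, length.out = 8))
  mcols(s)$bbls <- c(5, 1, 7, 3, 8, 2, 6, 4)
  mcols(s)$distance <- rep(100, 8)
  q <- bblsQuartileStratify(s)
  expect_equal(vapply(q, function(g) length(g$sites), integer(1)),
               c(Q1 = 2L, Q2 = 2L, Q3 = 2L, Q4 = 2L))
  expect_equal(sort(mcols(q$Q4$sites)$bbls), c(7, 8))
  expect_equal(sort(mcols(q$Q1$sites)$bbls), c(1, 2))
  # all-equal BBLS fills groups in input order
  mcols(s)$bbls <- rep(1, 8)
  qe <- bblsQuartileStratify(s)
  expect_equal(start(qe$Q1$sites), c(1L, 101L))
  expect_equal(start(qe$Q4$sites), c(601L, 701L))
  # remainders spread one extra site into the earliest groups
  s9 <- fakeSites(seq(1, by = 100, length.out = 9))
  mcols(s9)$bbls <- 1:9
  mcols(s9)$distance <- rep(100, 9)
  expect_equal(vapply(bblsQuartileStratify(s9),
                      function(g) length(g$sites), integer(1)),
               c(Q1 = 3L, Q2 = 2L, Q3 = 2L, Q4 = 2L))
  expect_error(bblsQuartileStratify(s9[1:3]), "at least 4")
})

test_that("evaluateAuc ranks regions by max contained score", {
  mkRegions <- function(starts, positive)
    GRanges("chr1", IRanges::IRanges(starts, width = 50),
            positive = positive)
  # worked 4-region case: positives score {5, 3}, negatives {4, none}
  sites <- fakeSites(c(110, 210, 310), width = 10)
  mcols(sites)$bbls <- c(5, 3, 4)
  regions <- mkRegions(c(100, 200, 300, 400), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(evaluateAuc(sites, regions), 0.75)
  # exclude mode drops the site-free region
  expect_equal(evaluateAuc(sites, regions, negativesMode = "exclude"),
               0.5)
  # perfect separation
  r2 <- mkRegions(c(100, 200, 300, 400), c(TRUE, TRUE, FALSE, FALSE))
  s2 <- fakeSites(c(110, 210, 310, 410), width = 10)
  mcols(s2)$bbls <- c(9, 8, 1, 2)
  expect_equal(evaluateAuc(s2, r2), 1)
  expect_error(evaluateAuc(s2, mkRegions(100, TRUE)), "undefined")
})

test_that("rank-based AUC equals the brute-force pairwise fraction", {
  set.seed(77)
  starts <- seq(1, by = 200, length.out = 120)
  regions <- GRanges("chr1", IRanges::IRanges(starts, width = 100),
                     positive = rbinom(120, 1, 0.5) == 1)
  # sites land in ~70% of regions, with duplicated scores to force ties
  inReg <- sample(120, 84)
  sites <- fakeSites(starts[inReg] + 10, width = 10)
  mcols(sites)$bbls <- sample(seq(0, 2, by = 0.25), 84, replace = TRUE)
  auc <- evaluateAuc(sites, regions)
  score <- rep(-Inf, 120)
  score[inReg] <- mcols(sites)$bbls
  expect_equal(auc, oracleAuc(score, mcols(regions)$positive))
  # random scores against random labels sit near 1/2
  expect_lt(abs(auc - 0.5), 0.15)
})
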