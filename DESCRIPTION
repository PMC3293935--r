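Package: phyloMotif
Title: Genome-Wide Transcription Factor Binding Site Mapping with
    Phylogenetic Conservation Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps candidate transcription factor binding sites genome-wide
    by scanning a reference genome with bounded log-odds position weight
    matrix scores (normalized log-odds, NLOD, with empirical z-score
    calibration), assessing evolutionary conservation of each site across a
    multiple whole-genome alignment with the Bayesian Branch Length Score
    (BBLS, the expected branch length score over per-species motif presence
    probabilities), and estimating false discovery rates by Monte Carlo with
    column-shuffled control matrices. Includes alignment-block lifting with
    padded extraction and gap-bounded merging, per-transcription-factor
    redundancy filtering, TSS-distance and SNP annotation, ROC/AUC
    evaluation against labeled region sets, and a seeded synthetic-data
    generator (genomes, alignments, trees, matrices, annotations) so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: MotifAnnotation, Transcription, SequenceMatching, Alignment,
    Phylogenetics
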