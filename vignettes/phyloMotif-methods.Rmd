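---
title: "Scoring, conservation and error control in phyloMotif"
author: "phyloMotif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, conservation and error control in phyloMotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(phyloMotif)
  library(GenomicRanges)
  library(S4Vectors)
})
```

phyloMotif maps candidate transcription factor binding sites genome-wide by
combining three scores at every locus: a normalized log-odds motif match
score (NLOD) with an empirical z calibration, a Bayesian branch length
score (BBLS) measuring evolutionary conservation across a whole-genome
alignment, and a Monte-Carlo false discovery rate estimated from
column-shuffled control matrices. This vignette explains each model, the
parameters that matter, the numerical choices we made where the design was
genuinely open, and what the synthetic data used by the test suite does and
does not establish about real genomes.

## Bounded log-odds scoring

A motif is a position probability matrix $q_{ij}$ (probability of base $i$
at position $j$). A window $S$ is scored as

$$\mathrm{LOD}(S) = \sum_{j=1}^{|S|} f\!\left(\frac{q_{S_j j}}{b_{S_j}}\right),$$

where $b_i$ is the genome-wide background probability of base $i$ and $f$
is a bounded base-2 logarithm: $f(x) = \log_2 x$ for $x > e^{2c}$, and for
$x \le e^{2c}$ the tangent line to $\log_2$ at $x_0 = e^{2c}$,

$$f(x) = 2c\,\log_2 e + \frac{x - x_0}{x_0 \ln 2}.$$

The tangent is the unique linear continuation that keeps $f$ continuous
*and* differentiable at the junction; it is finite at $x = 0$
(`boundedLog(0, -3)` $\approx -10.10$), so zero-probability matrix cells
are legal and no pseudocounts are required. Count matrices are
column-normalized as-is; a `pseudocount` argument restores the classical
behaviour for comparison. The default $c = -3$ puts the junction at
$x_0 = e^{-6} \approx 0.0025$: ratios below a quarter of a percent of
background are penalized linearly instead of diverging.

The NLOD score is the min-max rescaling
$(\mathrm{LOD} - y_{\min})/(y_{\max} - y_{\min})$, where $y_{\max}$ and
$y_{\min}$ are the scores of the consensus and anti-consensus sequences, so
NLOD is always in $[0, 1]$ and comparable across matrices of different
lengths and information content.

## z calibration

Because NLOD distributions differ per matrix, thresholds are expressed as
z-scores: `calibrateZ()` samples windows uniformly at random (default
$10^5$, both strands pooled, with replacement, seed mandatory) from the
scorable positions of the genome and records the sample mean and standard
deviation of NLOD. We calibrate on NLOD rather than raw LOD so the same
standardization applies to the rescaled score that downstream steps
consume. The scan threshold `zMin = 4.27` (upper-tail p $10^{-5}$) is the
mammalian-scale operating point; 2.57–3.72 (p 0.005–$10^{-4}$) suits
small, dense genomes where binding sites sit closer to genes. The top-k
cap (default $k = 10^5$) keeps every site whose z is at least that of the
k-th best, so ties at the boundary are never split arbitrarily.

Windows containing N or other ambiguity codes are skipped, not penalized;
masked intervals (exons, repeats) remove a site on any 1-bp overlap — the
conservative reading, since partial exon overlap already makes a
regulatory interpretation doubtful. Masking is applied before the top-k
cap, so the cap spends its budget on sites that survive filtering.

## Lifting sites through a multiple alignment

Whole-genome alignments are low-resolution: the orthologous motif is often
a few bases out of the aligned columns, or split between alignment blocks.
For each reference site we therefore extract every MAF block overlapping
the site expanded by `pad = 15` bp on each side, and per species
concatenate rows that are within `maxGap = 30` bp of each other *in that
species' own coordinates* (the purpose of merging is to reconstruct the
species' local sequence, so the species coordinate system is the right
one; intervening bases are taken from the species genome when available,
otherwise N-filled). Rows on different chromosomes or strands, or farther
apart, never merge. Each merged segment is then rescanned on both strands
— alignment strand assignments are not reliable for motif-length features
— and the species' best NLOD window becomes its hit. The reference
species' own hit is taken from the already-scored site rather than
re-derived from its alignment row.

The test suite exercises the two pathological geometries this design
exists for: a motif shifted 8 bp out of alignment frame, and a motif split
across two blocks whose species rows are 5 bp apart. Both recover a full
NLOD of 1.0; disabling merging makes the split case fail, which is the
behavioural contract for the 30 bp merge rule.

## BBLS: expected branch length score

For one site, let $p_i \in [0,1]$ be the probability that species $i$
carries the motif: $p_i$ is the species' best NLOD when its z is at least
`zFloor`, else 0. The floor defaults to 1.64 (one-sided p 0.05) — the
weakest defensible evidence level; anything below it is treated as
absence. The reference species contributes its own NLOD rather than a
forced 1, so a marginal reference match is not overweighted (`refCertain`
restores the certain-reference convention).

The binary branch length score BLS($\sigma$) is the total branch length of
the minimal subtree spanning the present species (taken unrooted; 0 when
fewer than two species are present). BBLS is its expectation under
independent leaf presences:

$$\mathrm{BBLS} = E(\mathrm{BLS}) = \sum_{\sigma_1,\dots,\sigma_N}
r_1 \cdots r_N \,\mathrm{BLS}(\sigma), \qquad
r_i = \begin{cases} p_i & \sigma_i = 1 \\ 1 - p_i & \sigma_i = 0.\end{cases}$$

Independence across leaves makes the exponential sum collapse: a branch
belongs to the spanning subtree exactly when at least one present leaf
lies on each of its sides, so

$$\mathrm{BBLS} = \sum_{b} \ell_b
\Bigl(1 - \prod_{i \in A_b}(1 - p_i)\Bigr)
\Bigl(1 - \prod_{i \notin A_b}(1 - p_i)\Bigr),$$

with $A_b$ the leaves below branch $b$. `bbls()` computes this in one
post-order and one pre-order pass (sibling products are used instead of
dividing by a subtree product, so $p_i = 1$ never divides by zero).
`bblsBruteForce()` enumerates all $2^N$ presence patterns and is the
oracle: the test suite checks agreement to $10^{-9}$ on 100 random trees
of up to 12 leaves, plus exact reduction to `bls()` for binary inputs.
Useful consequences that the tests also pin down: BBLS is monotone in
every $p_i$, bounded by the total branch length, and exactly 0 when only
one species is present — which is why "BBLS > 0" doubles as an "at least
one other species" conservation filter, and why a minimum-species
requirement (e.g. four non-primate species for deep mammalian maps) is
expressed through `minSpeciesFilter()`.

## Monte-Carlo FDR

Control matrices are random column permutations of the real matrix,
accepted when sufficiently dissimilar: the similarity between two
equal-length matrices is the maximum over all pairs of length-8 column
windows of the mean per-column Pearson correlation of the paired
probability 4-vectors. Zero-variance columns (uniform) are given
correlation 0 — they carry no shape information, and leaving them
undefined would make homopolymer-adjacent matrices unshuffleable for the
wrong reason. The acceptance cutoff is 0.35 on this un-normalized window
maximum. A further division by motif length is available via `normalize`,
but since the window correlation is already in $[-1, 1]$, dividing by
$L \ge 8$ would make every permutation pass the 0.35 cutoff and the rule
vacuous; we therefore default to the un-normalized statistic. Controls
must also be distinct permutations, and for CG-constrained runs (mammals,
where CpG content dominates background hit rates) the expected
CG-dinucleotide frequency $\frac{1}{L-1}\sum_j q_{C,j} q_{G,j+1}$ must
match the parent within an absolute tolerance of 0.01 — exact equality is
unattainable under column permutation, so a tolerance is the only
workable reading. Up to 10,000 draws produce up to 10 controls; a matrix
is retained only if it is at least 8 columns long and yields at least 3
controls.

Each control then runs through the *identical* scan-and-conservation
pipeline, and for each (NLOD, BBLS) threshold pair the FDR is the median
control site count divided by the real count. Grid points with a real
count of 0 are reported NA, not 0 (no evidence is not perfect evidence);
FDR values above 1 are reported as computed unless clipped for display. A
site's FDR is the minimum over the grid points it satisfies. FDR is not
forced to be monotone along the grid and the package does not pretend
otherwise.

## Post-processing

A factor annotated with several matrices must not count the same locus
twice: within each factor, overlapping sites (any 1-bp overlap,
strand-agnostic, grouped by transitive closure) are collapsed to the
max-BBLS representative; ties break to higher NLOD, then leftmost start
(the tie rule is ours — some rule is needed for determinism). TSS
distances are signed from the site midpoint (symmetric for motif-length
intervals, and the choice matters by at most half a motif length),
negative upstream relative to the gene strand; the promoter window
defaults to 15 kb upstream / 3 kb downstream, inclusive. SNP overlap uses
half-open interval semantics. AUC evaluation ranks labeled regions by the
maximum score of contained sites; regions without any site are kept below
every scored region ("include" mode, mirroring the convention that
experimental regions without a conserved site are true negatives) or
dropped ("exclude"); ties count one half, and the rank formula is checked
against brute-force pairwise comparison.

## What the synthetic data does and does not show

The fixtures module generates every input the pipeline consumes: i.i.d.
background genomes with planted motif instances, identity-aligned MAF
blocks over mutated species copies (default divergence in the standard
fixture: 150 substitutions over 30 kb, i.e. 0.5% per species), random
pure-birth trees with exponential branch lengths (mean 0.5
substitutions/site, a deep-mammal scale), and TSS/mask/SNP/region
annotations. Problem sizes were chosen so the whole suite runs in minutes
on one core: 20 kb genomes for oracle-equality checks, 100 kb with 50
planted sites for the FDR study, $2 \times 10^4$ calibration samples in
tests (the package default is $10^5$).

Two deliberate simplifications matter for interpretation. First, species
sequences are reference copies with point substitutions — there is no
indel or rearrangement model, so insertion/deletion structure is emulated
through block gaps and the dedicated shifted/split lift cases rather than
through a molecular-evolution simulator. Second, because unplanted
background is also copied across species, background scan hits in the
standard fixture are themselves "conserved" (as they would be between
closely related genomes); the end-to-end AUC therefore measures separation
of conserved plants from non-conserved decoys, not from neutral drift.
Passing tests establish algorithmic correctness (scan = exhaustive oracle,
DP = enumeration, filters enforce their stated rules) and directional
behaviour (planted signal yields FDR near 0, shuffles yield FDR near 1,
conserved plants rank first); they do not establish biological error
rates on real genomes, which depend on alignment quality, repeat content
and matrix quality.

## A worked example

```{r example, eval = FALSE}
fx <- standardFixture(1234)
bg <- backgroundFrequencies(fx$genome)
lom <- buildLogOddsMatrix(fx$motif, bg)
cal <- calibrateZ(lom, fx$genome, nSamples = 20000, seed = 1235)
sites <- scanGenome(fx$genome, lom, cal, zMin = 4.27)
scored <- conservationScore(sites, fx$aln$maf, fx$tree, lom, cal, "ref",
                            genomeLookup = fx$aln$genomes)
evaluateAuc(scored, fx$ann$regions, score = "bbls")
```

On the standard fixture this recovers all 12 conserved plants at
BBLS equal to the total tree length and ranks them above every decoy
(AUC = 1.0); `scripts/acceptance.R` recomputes this and the other
headline quantities from scratch.

## Known limitations

Linear scanning is $O(\text{genome} \times L)$ per matrix with no index
acceleration — adequate at desk scale and for the chromosome-at-a-time
production pattern, slow for thousands of matrices on gigabase genomes.
The MAF reader is streaming and minimal ("s" lines only; "e"/"i"/"q"
lines ignored); species names follow the UCSC prefix-before-first-dot
convention. Gap filling during block merging uses the species genome only
for plus-strand rows and N-fills otherwise. No substitution-model
conservation scores are computed; externally supplied per-site scores can
be ranked through `evaluateAuc()` for comparison.
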