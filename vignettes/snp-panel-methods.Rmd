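---
title: "Methods: SNP discovery, assay panel design and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP discovery, assay panel design and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpanel)
library(data.table)
```

## The problem

Developing SNP genotyping markers for a non-model species typically starts
from a de novo assembled transcriptome: reads from a small discovery panel of
individuals are assembled into contigs, candidate SNPs are called from the
read alignments, candidates are filtered for multiplexed-assay suitability
(e.g. the GoldenGate bead array, which needs 60 clean flanking bases on each
side of the site), and a panel is validated by genotyping a larger sample.
Without a reference genome, many candidates fail: paralog co-assembly,
sequencing error, introns hidden inside the assay target region, and poor
flank quality all convert to failed or monomorphic assays. `snpanel`
implements this pipeline end to end, together with the statistical battery
used to compare discovery strategies (e.g. a long-read low-depth platform
versus a short-read deep-coverage platform) and to find predictors of assay
success.

## Candidate SNP calling

Calling is rule-based, not model-based. A pileup column yields a candidate
iff:

* exactly two nucleotides each have >= 2 supporting reads
  (`min_allele_reads`),
* total nucleotide depth at the column is >= 4 (`min_depth`),
* gap and `N` observations are ignored entirely (no indel variants are
  considered; ambiguous bases count neither as alleles nor as depth).

Columns where three or more nucleotides reach the read minimum are rejected
as multiallelic rather than reduced to their top two alleles, because the
downstream assays are strictly biallelic. The defaults encode the published
count criteria; both thresholds are arguments of `call_snps()`.

Each candidate carries the descriptor variables used throughout the
validation analysis: `depth`; `msaf` (minor sequencing allele frequency,
minor reads / depth — note the denominator includes stray below-threshold
reads); `individuals` and `geosites` (distinct labelled individuals and
sampling sites contributing at least one read covering the site — unlabelled
reads count toward depth only, which represents both a tag-based protocol
with discarded untagged reads and per-lane short-read data with explicit
labels). An `msaf` tie at 0.5 is broken lexicographically (alphabetically
first base = major) so the caller is deterministic.

Discovery density (`summarize_discovery()`) uses the cumulative length of
SNP-containing contigs as the per-100-bp denominator; that is the only
reading under which the published density summaries are internally
consistent, and it is what the acceptance script recomputes.

## Assay suitability

**Target region.** `extract_target()` returns the 121-base window (SNP ± 60)
only when both flanks fit inside the contig; absence is a value, not an
error, and such candidates are excluded from panels.

**Q score.** `compute_q()` counts flank positions (within ± 60 by default)
where at least one aligned read disagrees with the column consensus
(plurality nucleotide, ties lexicographic; `N` and gap observations always
disagree). Positions-with-any-mismatch was chosen over total mismatching
bases because it stays a small, depth-insensitive integer — the scale on
which a quality cutoff like "Q > 1" is meaningful; `mode = "bases"` provides
the alternative.

**Surrogate design score.** Commercial assay-design scores are proprietary.
`surrogate_design_score()` is a documented, deterministic stand-in,
range-matched to [0, 1] so the conventional thresholds (discard below 0.4,
prefer above 0.7) apply unchanged. It is the equal-weighted mean (weights
configurable) of four sub-scores:

* **GC**: distance of target GC content to the [0.35, 0.65] band, linear to
  0 at 0.35 outside it;
* **Tm**: GC-count melting approximation `64.9 + 41 (GC - 16.4) / L` per
  60-mer flank, scored against the common window [70, 80] °C with a 15 °C
  linear decay;
* **uniqueness**: fraction of the target's canonical 15-mers that occur
  nowhere else (in the contig set when an index is supplied, otherwise
  within the target itself — a homopolymer or short-period repeat is
  maximally non-unique even without context);
* **hairpin**: one minus the normalized longest self-complementary stem
  (loop >= 3 bases; stems shorter than 6 ignored).

All four are reverse-complement invariant, so the score does not depend on
the arbitrary orientation of an assembled contig. Degenerate inputs
illustrate the arithmetic: a poly-A target scores 0.25 (GC, Tm, uniqueness
all zero; no stem is possible), and an ACGT-periodic target scores ~0.50 —
ideal composition, but maximally repetitive and almost perfectly
self-complementary, both real reasons to avoid such targets.

**Panel selection.** `select_panel()` drops candidates without a target,
below the score floor, or with a predicted intron in the target region
(overridable), then ranks within each contig by an explicit composite: lower
Q first, candidates above the preferred score outrank others at equal Q,
then higher score, greater distance to the nearest other candidate in the
contig, higher depth. In the original workflow this ranking was a manual,
operator-assigned inspection step; the composite is a deterministic stand-in
that encodes the same published considerations (flank quality, score,
clustering of polymorphic sites, depth) and is documented as such. The panel
takes every contig's best candidate first, then fills globally — spreading
loci across contigs before deepening within them.

## Comparative annotation

**Built-in aligner.** `find_hsps()` is a seed-and-extend local aligner:
exact 12-mer seeds define (subject, strand, diagonal) triples and every
seeded diagonal contributes its maximum-scoring ungapped segment (match +2,
mismatch −3; minimum score 40 ≈ 20 identical bases, calibrated so
shuffled-sequence false hits are rarer than 1e−3 per comparison at typical
contig lengths). The aligner is deliberately *ungapped*: the variant-calling
rules exclude indels, and the intron-exon logic depends on each exon of a
genomic subject producing its own HSP — a gapped aligner may bridge an
intron with one long gap and erase exactly the structure being tested.
`subject_index()` prebuilds the seed index so that aligning many contigs
against a genome costs per-query time independent of genome size. Users with
an external aligner can substitute its 12-column tabular output via
`read_tabular_hits()`.

**Intron-exon boundary prediction** runs two routes per reference species,
mirroring the two published comparison strategies:

* *Route A* (`ie_route_a()`): contig vs genome. Code `"1"` when a single
  local hit's query span contains the full SNP window, `"0"` when
  significant hits exist but none covers it (an intron is assumed inside the
  target region), `"no"` otherwise.
* *Route B* (`ie_route_b()`): contig vs transcriptome; the SNP position is
  mapped onto the best homolog transcript through the alignment coordinates
  and located within the transcript's exon structure (reference exon map, or
  transcript-vs-genome alignment when no map is given). The window is
  clipped at the transcript ends; "single exon" means one exon span contains
  the whole clipped window — alignment-derived exon spans may touch or
  overlap by a chance-matching base, so span containment is used rather than
  exon-index equality.

`combine_ie()` pools all per-species, per-route codes with precedence
`1 > 0 > no` ("embedded in a single exon in at least one comparison" wins),
and counts species with any significant match; that count is zero exactly
when the combined code is `"no"`.

**Effect classification.** `classify_effect()` finds the reading frame by
translating all six frames and locally aligning each against the supplied
peptides (BLOSUM62), then translates the SNP codon for both alleles and
classifies the substitution with the five physico-chemical classes
(non-polar G A V L I P M C, polar S T N Q, negative D E, positive K R H,
aromatic F W Y — His is treated as charged-positive and Cys/Met as
non-polar; the table is an argument for users who prefer a different
membership). Same residue → synonymous; same class → conservative;
different class or a gained/lost stop → non-conservative (stops additionally
flagged nonsense). The effect pipeline reuses the same 121-base target
window as assay design; a published description mentioning "120 bp" flanking
sequence is treated as this same SNP ± 60 window for internal consistency.

**GO enrichment** (`go_enrichment()`) is a per-term Fisher exact test of
test-set vs reference-set contig counts with Benjamini–Hochberg FDR; GO
graph propagation to ancestor terms is out of scope.

## Validation statistics

* `apply_qc()` removes samples below a 0.8 call rate and marks
  poorly-clustering loci as conversion failures. "Poor clustering" is an
  input flag (`cluster_ok`): the package never sees raw intensity data.
* `chi2_yates()` applies the continuity correction with a floor (statistic
  exactly 0 when |ad−bc| ≤ N/2). Yates correction is the default for every
  2×2 comparison because the published contingency statistics are
  reproducible only under it; an uncorrected mode exists behind a flag.
* `mann_whitney_mc()` reports the tie-corrected U plus a Monte-Carlo
  permutation p (default 1,000,000 permutations, matching the original
  analysis protocol) with a 99% CI for the estimate; two-sided by default,
  since the original protocol does not state sidedness.
* `logistic_fit()` fits by maximum likelihood (IRLS) and, in
  `backward_wald` mode, repeatedly removes the predictor block with the
  largest Wald p while it exceeds 0.10 — the conventional stay threshold of
  the statistical package named in the original protocol, configurable.
  Categorical predictors use the last level as reference (same convention),
  multi-level factors are removed as blocks using the multi-df Wald test,
  collinear predictors are dropped with a warning, and complete separation
  is flagged rather than silently reported.
* `roc_analysis()` builds the empirical curve, computes AUC by trapezoid
  (identical to the scaled Mann-Whitney U), the DeLong placement variance by
  default (Hanley–McNeil optional), a z test against 0.5, and the
  Youden-optimal cutoff with ties resolved to the smaller cutoff; a point is
  positive when score > cutoff.
* `compare_platforms()` fixes the variable-to-test mapping declared for the
  platform comparison (t-test: contig length, depth; χ²: conversion,
  polymorphism, intron-exon code; Mann-Whitney: species matches, geosites,
  design score, MSAF, ...). No multiple-testing correction is applied across
  this report; FDR control is used only in GO enrichment, matching the
  original analysis.

## The simulator

`simulate_dataset()` generates the full study structure from one seed:
contigs with a known coding frame (built from sense codons, so the true
proteome exists by construction), a configurable fraction drawn from a
synthetic mitochondrial genome, planted biallelic SNPs with Beta(1, 3)
population allele frequencies and Hardy–Weinberg genotypes in a discovery
panel of 8 individuals spread 2+2+2+2 over four geosites, and reads sampled
per individual under one of two platform profiles:

| profile | read length | error rate | mean depth | contig lengths |
|---|---|---|---|---|
| `longread` | 206 ± 40 bp | 0.3% | 45× | log-normal, ≈ 331 bp mean |
| `shortread` | 74 bp | 1% | 600× | log-normal, ≈ 190 bp mean |

The profile magnitudes are fixed once from the published platform summaries
(read lengths, depth contrast, contig-length contrast); every field is
overridable. A companion "model species" reference set is derived from the
contigs: a genome with introns inserted as a Poisson process (rate 1/300 bp,
lengths 200–800 bp), the homolog transcriptome with an exon map, and the
proteome of the true frames.

Two design choices matter for interpreting test results:

* **Truth allele frequency is the realized panel frequency.** MSAF estimates
  the allele frequency of the *sequenced individuals*; comparing it to the
  Beta-prior population frequency would confound sequencing sampling noise
  with panel sampling noise. `truth_compare()` therefore measures MSAF
  accuracy against the allele frequency realized in the planted genotypes,
  which is the quantity deep sequencing can actually converge to.
* **Intron boundaries are decodable by construction.** The first and last
  20 intron bases are generated to mismatch the exon-adjacent contig bases
  that ungapped extension would compare them against. Without this, a
  chance-matching intron-terminal base (probability 1/4 per boundary)
  legitimately extends an alignment across the planted boundary — the genome
  then genuinely contains the extended exon, and no aligner could recover
  the planted truth exactly. Real splice boundaries do not have this
  property, so on real data intron-exon codes near window edges are fuzzy by
  a few bases.

What the simulator does *not* model — and what passing tests therefore do
not show about real data: indels and assembly chimeras, paralog co-assembly
(a major real-world source of failed assays), base-quality profiles,
expression-level variation of a non-normalized cDNA library, and linkage
between nearby SNPs. Between-geosite divergence is available
(Balding–Nichols `fst`) but defaults to panmixia.

## Problem sizes and numerical choices

The test suite validates the full pipeline on seeded simulations of 200
contigs × 8 individuals under both profiles at zero sequencing error (the
regime where sensitivity and intron-exon recovery have exact expected
values: 100% of discoverable planted SNPs — both alleles sampled at least
twice — and no false calls), and compares MSAF accuracy between profiles
with a one-sided Mann–Whitney test. Property suites run exhaustively where
the space is small: all pileup columns to depth 6 against an enumeration
oracle, all 2×2 tables with cells ≤ 30 against the observed-vs-expected
χ² formulation, all 576 single-base codon changes against a genetic-code
oracle. Monte-Carlo procedures in tests use 2,000–50,000 permutations with
fixed seeds; all stochastic procedures in the package are reproducible
bit-for-bit given a seed.

Known limitations: the aligner's ungapped HSPs under-cover homologs that
truly differ by indels (use the external-aligner adapter in that case);
`classify_effect()` trusts the best protein hit and does not detect frame
shifts within a contig; the design-score surrogate shares only the decision
*structure* (range and thresholds) of commercial scorers, not their values;
and the panel-ranking composite is an explicit stand-in for what was
originally a manual inspection step.
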