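---
title: "Dissecting phage transcription from direct RNA sequencing reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting phage transcription from direct RNA sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2drs)
```

## The problem

MS2 is a positive-sense ssRNA coliphage whose 3,569 nt genome doubles as
its mRNA, carrying four ORFs (*mat*, *coat*, *lys*, *rep*). Nanopore direct
RNA sequencing (DRS) of an infection time course yields a mixture of read
populations that must be disentangled before any biological statement can
be made:

* **full-length genomic reads** (span ≥ 90% of the genome, on either
  strand — negative-strand reads are replication intermediates);
* **3′-anchored truncated reads**: DRS threads RNA through the pore 3′→5′,
  so any interrupted read retains the 3′ terminus. These are a platform
  artifact, not biology;
* **5′-anchored reads**: RNA degraded from the 3′ end, i.e. genuine decay
  products;
* **internal subgenomic reads** containing the *coat* (or *coat*+*lys*)
  ORFs — candidate functional small transcripts;
* **chimeric (hybrid) reads** from replicase template switching: deletions
  and tandem duplications with offsets concentrated in 20–60 nt, plus rare
  (+/−) foldback (copyback) RNAs;
* **modified bases** (pseudouridine, m5C) whose apparent stoichiometry is
  inflated by a high platform false-positive rate, controlled here by an
  unmodified in-vitro-transcribed (IVT) library.

The package implements each analysis as plain functions over tidy tables,
with an orchestrating `run_pipeline()`, and ships a synthetic-data
generator so that every stage is testable against known ground truth.

## Conventions that everything else depends on

* Coordinates are **0-based half-open** internally; every TSV/BED written
  for humans converts positional columns to 1-based inclusive (BED stays
  0-based, as the format requires).
* A negative-strand read is stored in the genome frame with `strand == "-"`;
  its biological 5′ end is its genome-**maximum** coordinate. Anchoring
  tests, window start/end counting and junction arithmetic all use this
  biological orientation.
* Reads are filtered at mean PHRED ≥ 10, computed as the arithmetic mean of
  per-base qualities (a read-level aggregate is the common long-read QC
  choice; the threshold is a parameter).
* Only primary alignments feed coverage and classification; supplementary
  records are surfaced separately to the chimera stage, never double-counted.

## Read classification

`classify_reads()` applies a fixed precedence: full-length, then
3′-anchored, then 5′-anchored, then *coat*+*lys*, then *coat* containment
(≥ 90% of the ORF covered), else `other_internal`. Terminal anchoring wins
over ORF content because the platform-bias-vs-degradation axis is the
primary explanatory split; a read anchored at the 3′ terminus that happens
to contain *coat* is still evidence of truncation, not of a subgenomic
species. The anchoring tolerance (`delta`, default 25 nt) absorbs typical
DRS end raggedness; the 0.90 span and ORF-coverage thresholds mirror the
full-length convention. Span means reference extent, robust to small
indels.

## The hotspot statistic

For each 5-bp window and strand, `window_site_stats()` computes the count
of biological read starts (and ends) in the window over the window's mean
depth, and normalises by the genome-wide **median** of that ratio over
windows with depth ≥ `min_depth` (50). The median is robust: true hotspots
inflate a mean baseline but leave the median untouched. Windows below
`min_depth` are flagged missing rather than producing ratio blow-ups. A
hotspot needs fold ≥ 5 (a preset of 2 matches the looser "two-fold
enrichment" convention) and must lie inside the reporting ranges
(starts 100–3500, ends 0–3400, 1-based). When the median ratio is zero
(terminus-free interiors), the baseline falls back to the median of
positive ratios so folds stay finite — a documented tie-break, not a
parameter.

Codon overlay (`annotate_codons()`) and the AG-richness test
(`ag_richness_test()`) are annotations on called hotspots. AG-richness is
strand-aware: the flank 5′ of a negative-strand hotspot lies at higher
genome coordinates and purines on that strand read T/C in the genome
frame. The test is a one-sided exact binomial against the genome-wide
purine fraction of the same strand, BH-corrected across hotspots — a
deliberately simple substitute for motif discovery, which is out of scope.

## Chimera detection

`find_segments()` runs an affine-gap Smith–Waterman (match +1, mismatch
−2, gap of length $k$ costs $4 + 2k$) of the read against the genome and
its reverse complement, in a compiled core (a ~3.6 kb genome × thousands
of reads makes per-read R-level alignment impractical). The best local
alignment is reported and the finder recurses on the unaligned query
remainders; any alignment carrying an internal gap ≥ 15 nt is split at the
gap and both sides realigned, so a junction "bridged" by one gapped
alignment still separates into two segments. A k-mer strand screen (15-mers
sampled every 10 nt) skips the strand with zero exact hits; an alignable
≥ 60 nt arm at a few percent error contains a clean sampled 15-mer with
overwhelming probability.

`chain_and_call()` keeps the highest-scoring non-conflicting segments,
requires query adjacency (gap ≤ 20 nt, overlap ≤ 20 nt), and ≥ 2 distinct
reference loci (reciprocal overlap < 50% or different strand). Before the
adjacency test, each junction is **refined**: the unaligned query gap is
split between the upstream segment (forwards) and the downstream segment
(backwards) at the split point minimising mismatches against the genome
continuations. This matters for tandem duplications, where the duplicated
block makes the aligner's trim ambiguous by up to |Δ| nt; the refinement
recovers the unique (up to microhomology) junction. Substitution errors
pass through the refinement; gap content matching neither continuation
(> 30% mismatches) refuses it.

The junction offset is computed in transcript orientation,
$\Delta = \mathrm{ref\_start}_2 - \mathrm{ref\_end}_1 - \mathrm{query\_gap}$
(mirrored on the reverse-complement frame for `neg_neg` junctions):
$\Delta > 0$ is a deletion, $\Delta < 0$ a duplication, and
$20 \le |\Delta| \le 60$ raises the recombination flag. Same-strand
junctions with $|\Delta| \le 5$ are treated as contiguous alignment noise,
not template switching. Opposite-strand segments over the same locus
(reciprocal overlap ≥ 50%) are foldbacks and never receive a
deletion/duplication label. The published score filter for this step is not
executable as printed; a raw alignment-score threshold (`min_score = 60`)
stands in for it, and an exhaustive-DP oracle in the test suite guards the
finder's correctness.

## Modification stoichiometry and dynamics

`site_stoichiometry()` counts a read as modified when its per-read call
probability is **strictly** greater than 0.8 (the threshold is per-read;
thresholding per-site stoichiometry instead is exposed through the same
parameter). Sites need coverage ≥ 30 in every compared sample — below
that, stoichiometry is not stable at the ±0.1 level. `ivt_subtract()`
drops any site whose test-minus-IVT stoichiometry is not strictly
positive; a site absent from the IVT table counts as IVT 0. One IVT
library serves all timepoints and length fractions (it is a property of
the RNA, not of the infection), so matching is on (position, modification
type) by default.

Significance is a two-sided Fisher exact test on the modified/unmodified ×
sample table — an open substitution for the modification caller's internal
"balanced MAP-based p-value", which is not specified anywhere usable — with
BH correction applied within one family per timepoint pair × modification
type × length fraction, mirroring per-panel testing.
`temporal_classification()` labels each consecutive pair increase /
decrease / no_difference (q < 0.05) and emits the named presets: for long
reads (> 3000 nt) blue = (decrease, increase), purple = (decrease,
no_difference), brown = (increase, no_difference) over the first two
pairs; for short reads (< 800 nt) cyan/red = final-pair
increase/no_difference. m6A and inosine flow through the data model but
have no presets.

## The synthetic-data generator

`make_genome()` builds a random 3,569 nt sequence with the four ORFs in
MS2 order and realistic relative sizes (*lys* overlapping the *coat*/*rep*
boundary region; coordinates follow the well-known MS2 layout and are
configurable), an ATG at each ORF start, a stop codon at each end, and an
AG-rich hexamer 8–12 nt upstream of each start. `simulate_reads()` draws
classes from a multinomial mixture; each class generator draws coordinates
uniformly within the ranges its definition allows, with a safety margin so
truth labels and classifier output agree except at boundary draws (the
anchored classes draw interior endpoints below the 0.897·L span so they
cannot collide with the full-length rule). Degraded-read lengths are
uniform over the allowed range — the simplest distribution consistent with
the class contracts; real libraries are longer-tailed, which affects none
of the coordinate-based properties tested here. Errors are
substitution-only (no indels), keeping the chimera ground truth exact;
per-base PHRED scores are drawn around mean 14. `simulate_hybrids()`
concatenates genome blocks with the junction bookkeeping recorded in the
truth table; `simulate_modifications()` draws per-read Bernoulli
modification states at the configured stoichiometry (modified calls get
probability U(0.85, 1), unmodified U(0, 0.30)), with `ivt = TRUE` forcing
stoichiometry 0 except at artifact sites planted identically in both
conditions to exercise the subtraction.

What passing tests on this generator do **not** show: robustness to indel
errors, to basecaller-specific quality artifacts, to poly(A) tails, or to
reference/sample divergence. The generator emulates populations and their
coordinates, not signal-level nanopore physics.

## Problem sizes, numerical choices, defaults

* Validation sizes: 20,000 reads for class recovery; 500 planted hybrids +
  100 foldbacks against 5,000 background reads at 2% substitution error;
  50 reads for the DP-oracle comparison; 10,000 reads per hotspot
  replicate (5 uniform seeds); depth 300–1,000 and 100–400 replicates for
  the modification experiments. These sizes give each binomial acceptance
  bound a comfortable margin while keeping a full validation run in
  minutes on one core.
* The artifact-site survival experiment uses 400 replicates: the surviving
  fraction has null rate ≈ 2.3% (half of the two-sided 5% rejection rate),
  and 100 replicates leave a ≤ 5% bound one unlucky draw from failure.
* Ties in the Smith–Waterman traceback resolve to the first-encountered
  best cell (row-major), making segment output deterministic.
* BH q-values from `stats::p.adjust` agree with a brute-force step-up
  implementation to machine precision (the two associate the
  multiplications differently, so bitwise identity is not expected).
* All simulators take an integer seed and produce byte-identical outputs
  for the same seed; `run_pipeline()` reruns reproduce every TSV/BED
  byte-for-byte.

## Known limitations

* The segment finder assumes one reference genome; host–virus chimeras and
  multi-genome recombination are out of scope.
* Hotspot significance is a declared fold-threshold rule, not a calibrated
  test; the type-I property is demonstrated empirically under uniform
  placement.
* Junction coordinates are exact up to microhomology and can shift a few
  nucleotides when a substitution error lands on the junction flank;
  validation budgets a 95% within-±5 nt rate.
* The Fisher test treats per-read modification calls as independent
  Bernoulli draws; real DRS calls are correlated along reads, so q-values
  on real data are optimistic and the IVT subtraction carries the burden of
  false-positive control, as designed.
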