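---
title: "riboStall: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboStall: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboStall)
```

# The scientific problem

Ribosome profiling reduces a translating cell to per-nucleotide counts of
ribosome-protected fragments (RPFs), each assigned to the single P-site
position of the ribosome that protected it.  Two qualitatively different
kinds of translational repression leave distinct fingerprints in those
counts:

* **Initiation block** — fewer ribosomes load onto the CDS.  Density falls
  uniformly along the CDS; with scanning-dependent initiation blocked,
  80S ribosomes may instead accumulate at upstream open reading frames in
  the 5'UTR.
* **Early elongation stall** — ribosomes load normally but pause during
  the first tens of codons.  At steady state, density piles up at and
  upstream of the pause while the gene's total RPF count *rises*, because
  each transcript carries more ribosomes.

Rocaglamide A (RocA), which clamps the initiation helicase eIF4A onto
poly-purine (A/G) sequence, turns out to act in both modes at once, on
different gene sets: genes with long, purine-rich 5'UTRs are
initiation-repressed (IRGs), while genes with short TISU-type 5'UTRs and
purine runs in their early CDS are elongation-repressed (ERGs), with
ribosomes stalling immediately upstream of the CDS poly-purine motifs.
riboStall implements the complete analysis chain needed to detect and
dissect this behaviour from transcript-coordinate footprint data, and a
generator of synthetic data with known ground truth on which every claim
the package makes is tested.

# Data model

Everything operates in transcript coordinates, 0-based half-open
(standard formats that demand 1-based coordinates, such as SAM, are
converted at the boundary; bedGraph output is 0-based half-open).  Two S4
containers carry the state:

* `Transcriptome` — one representative transcript per gene (the longest;
  length ties broken lexicographically by transcript id, a deterministic
  rule chosen because no convention is standard), with validated CDS
  coordinates partitioning each sequence into 5'UTR / CDS / 3'UTR.
* `SampleLibrary` — per-transcript integer vectors of P-site counts plus
  the library size; the RPM factor is `1e6 / librarySize`.

# Preprocessing and P-site assignment

Reads are filtered by base quality (discard when more than 75% of bases
fall below Phred 25; reads without qualities pass with a notice, since
simulated data and some BAMs carry none) and by length: 15–45 nt for
monosome footprints, 30–70 nt for disome footprints, both inclusive.

P-site offsets are calibrated per read length: the offset in 8–18 nt
(bracketing the canonical ~12 nt 5'-to-P-site distance) that places the
most read 5' ends exactly on annotated start codons wins, ties going to
the smaller offset.  A read length is retained only when the reading-frame
distribution of its P-sites inside CDSs is at least 50% in the dominant
frame with at least 100 reads scored — a transparent, simulator-verifiable
replacement for external periodicity callers.  The calibration anchors on
the start-codon occupancy peak that real libraries show; the synthetic
generator reproduces that peak (`startBoost`, default 3) for the same
reason.  Without it, a uniform-density transcript supports offset o and
o − 3 equally (the codon-ladder alias).

Disome reads have no published P-site convention; the package applies the
same offset table to the disome 5' end, which reports the position of the
upstream (collided) ribosome, and the density analyses are interpreted
under that convention.

# Polarity and condition clustering

The polarity score of a transcript summarizes where along the CDS its
density sits.  With codon-level densities $d_i$ ($i = 1..L$, each codon
the sum of its three nucleotide counts) and weights

$$w_i = \frac{2i - (L + 1)}{L - 1},$$

the score is $P = \sum_i d_i w_i / \sum_i d_i \in [-1, 1]$: all density at
the first codon gives −1, at the last +1, uniform 0.  Codon-level
aggregation is used because P-site data are 3-nt periodic; the score is
undefined (NA, never 0) for transcripts without CDS counts.  Δpolarity is
the treatment-minus-control difference with replicates averaged per group
first, giving one value per condition pair.

For clustering perturbation conditions, transcripts must have CDS
RPKM > 1 in every sample of every pair and mean *coverage* — defined here
as the fraction of CDS codons with at least one count, computed per
sample and then averaged, since the source convention is not otherwise
pinned down — strictly above the grand mean across transcripts.
Conditions are clustered on their complete Δpolarity columns with the
Ward criterion on euclidean distances (`hclust` method `ward.D2`, the
same combination as seaborn/scipy's `ward`); transcripts with any
missing Δ are dropped listwise because Ward requires complete vectors.

# ERG/IRG classification

Per gene, the body count is the P-site total over CDS codons 16..(L−5),
excluding the first 15 and last 5 codons so start/stop piling cannot
masquerade as repression.  The differential test is a self-contained
negative-binomial Wald test:

* median-of-ratios size factors (the standard RNA-seq normalization;
  total-count fallback with a warning when no gene is everywhere
  non-zero);
* group means with pseudocount 0.5 — enough to keep fold changes finite,
  negligible at the simulated depths;
* per-gene dispersion by method of moments on normalized counts, shrunk
  toward a local trend (the mean of the raw, *untruncated* moment
  estimates of the 50 nearest genes by mean count) with weight 0.3 on the
  per-gene value, floored at zero after mixing.  Averaging untruncated
  values keeps the trend unbiased under Poisson data; truncating first
  would inflate it and make the test conservative;
* Wald statistic on $\log(m_t/m_c)$ with delta-method variance
  $(1/m + \alpha)/n$ per group, two-sided normal p-value, BH-adjusted.

Classes use the inclusive cutoffs |log2FC| ≥ 1 and q ≤ 0.05: ERG when
up, IRG when down, NS otherwise.  Swapping the condition labels maps the
two sets onto each other exactly (the statistic is antisymmetric).

A structural caveat the validation makes visible: when a true effect sits
*exactly* on the fold-change cutoff (e.g. a gene repressed to precisely
half), an unbiased estimator lands above the cutoff in only half of
realizations no matter how deep the data, so sensitivity against such
genes tends to 0.5, not 1.  Effects strictly beyond the cutoff (as the
stall excess produces for ERG-like genes) are recovered nearly
completely.

# Motif-anchored density enrichment

Poly-purine motifs are maximal A/G runs of at least k (k ∈ {4, 5, 6});
poly-AC runs serve as the negative-control alphabet.  One anchor is
emitted per run per k, at the run start — anchoring every overlapping
k-mer would let a single long run dominate the average.  Runs containing
N never match.

For enrichment, anchors within the first or last 50 nt of their region
are discarded, windows (±50 nt for monosomes, ±100 nt for disomes) must
fit inside the region, and a window must hold at least 10 raw P-site
counts pooled over the two compared groups — pooling avoids conditioning
the filter on either condition.  Densities are RPM-scaled, averaged
within groups, and the per-offset enrichment ratio is the across-motif
mean treatment density over control density.  Significance is a Welch
two-sided t-test of the per-motif mean upstream (−w..−1) density,
treatment versus control: motifs are the natural replicates, whereas
per-offset testing would pretend correlated offsets were independent.

CLIP-style k-mer enrichment retains a read only when it occurs as an
exact substring of a target region (no-mismatch matching;
reverse-complement matching is off because transcript-space reads are
sense-strand), counts k-mer occurrences per million retained reads in
each library, and compares the class k-mers' frequency ratios against
all remaining k-mers of the same k with a Welch test.

# Sequence features

Local tAI/cAI profiles are windowed geometric means of per-codon weights
(window 10 codons, step 1 — the window is not pinned down by any
convention, so it is a declared, configurable default).  Charge uses
K, R = +1 and D, E = −1 with histidine 0 (the common convention at
cytosolic pH); hydrophobicity uses the Kyte–Doolittle scale; both are
windowed arithmetic means over the translated CDS (stop excluded).  tAI
weights are an input table — the shipped
`codon_weights_tai_synthetic.tsv` is a synthetic illustrative table, not
derived from real tRNA abundances; cAI weights can be derived from any
reference codon-frequency table with `caiWeights()` (per-family maximum
normalized to 1).

Ribosome-enriched positions are codons in the first 50 CDS codons with a
treatment/control RPM ratio ≥ 1.5; depleted positions have ratio ≤ 0.67
(both inclusive; zero-control codons are excluded).  The two sets are
compared per feature with a Welch test.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is validated.

**Transcripts.**  One transcript per gene: 5'UTRs of 11–15 nt for the
short TISU-like class (approximating the ~12 nt TISU median while
guaranteeing that a codon-1 footprint's 5' end, P-site minus an 11–13 nt
offset, stays on the transcript) or 130–170 nt for the long class; CDSs
of 150–400 codons; 50 nt 3'UTRs.  Background sequence is i.i.d. with
both AG-class and AC-class runs of ≥4 nt suppressed, so the planted
motifs are the only poly-purine anchors — in unconstrained random
sequence roughly a third of early-CDS nucleotides would sit inside some
AG run's stall window, and the AC negative control could not be clean.
ERG-like genes (10%) get two AG anchors at codons 5–50, at least 24
codons apart so one anchor's ±50 nt window never overlaps the other's
stall stretch, plus AC control anchors at codons 70–95, far enough that
their windows cannot touch any stall window.  IRG-like genes (10%) carry
AG anchors in their long 5'UTRs; background genes get one AG and one AC
anchor at random CDS codons.  CDSs are ATG-initiated with a single
terminal stop; planted runs avoid 4+ consecutive A so no anchor belongs
to both motif alphabets.

**Counts.**  Steady-state expected density per codon is flux × dwell,
$\mu_i = J \tau_i$, with $\tau_i \sim \mathrm{LogNormal}(0, 0.25^2)$,
$J \sim \mathrm{LogNormal}(0, 0.5^2)$, and the initiation codon's dwell
multiplied by `startBoost`.  This is the minimal model consistent with
the steady-state logic: a dwell multiplier (stall factor 5 on the 15 nt
upstream of early AG anchors) piles density locally and raises the
gene's total count without touching downstream density, while a flux
multiplier (initiation factor 0.5) scales a gene's CDS uniformly.  Under
the stall regime ERG-like genes additionally carry a ribosome-loading
fold (`ergFlux`, default 2), so their realized body-count fold is the
loading fold times the dwell excess — strictly above 2; under the block
regime IRG-like genes get flux × 0.5 exactly, plus uORF-like density at
their 5'UTR anchors.  The no-stall mutant regime (the computational
analogue of a RocA-resistant eIF4A mutant) reverts everything to
baseline.  `stallAt = "random"` places the stall windows at random
early-CDS codons instead of motif anchors, which is the configuration
for testing that sequence features do *not* differ between enriched and
depleted positions.  Counts are negative-binomial per codon (dispersion
0.1, a typical footprint overdispersion; 0 gives Poisson) scaled to an
expected library size of 2e6, and placed at the first nucleotide of each
codon.  Materialized reads draw lengths from {28, 29, 30} with offsets
{11, 12, 13} and can blur reading frame via `framePurity`.

**Disomes** are emitted at codons whose effective dwell is in the top
decile of the transcript, at rate proportional to dwell, as 55–65 nt
reads with the 5' end 30 nt upstream of the stalled P-site.  **CLIP
libraries** sample fixed-length windows uniformly (control) or keep
non-anchor-overlapping windows with probability 1/factor (treatment),
giving a controlled oversampling of anchor-overlapping reads.

**What the generator does not emulate:** sequence-realistic base-call
errors, rRNA contamination, uneven nuclease footprint boundaries,
isoform mixtures, codon-usage-driven dwell variation, or genome-space
alignment artifacts.  Green tests therefore demonstrate that the
statistics recover the mechanisms they target under controlled noise,
not that any particular real library is free of the confounders above.

# Numerical choices and degenerate inputs

* Offset ties take the smaller offset; representative-transcript ties are
  lexicographic; both purely for determinism.
* Polarity with an empty CDS is NA and propagates as missing, never 0.
* The metagene profile divides each transcript by its own mean CDS codon
  density after RPM scaling, so it is exactly invariant to count
  rescaling; positions beyond a transcript's extent are excluded and
  tracked via `n_transcripts`.
* All-zero genes are excluded (NA) from the differential test; genes with
  CDS ≤ 20 codons have no body region and are flagged.
* Welch's test refuses samples smaller than 2 and returns t = 0, p = 1
  for two identical constant samples.
* Fewer than 2 surviving motifs is an error (the across-motif test is
  undefined), as is an empty transcript filter result.

# Problem sizes

The validation suite runs the reference cohorts at 2000 genes × 6
libraries × 2e6 expected P-sites for classification, 400 genes for the
motif/disome cohorts, 300 genes for the feature-null cohort, and 60
genes × 3e4 reads for offset calibration — sizes chosen so the complete
suite and the acceptance script each finish in well under a minute of
simulation time while keeping per-gene counts near real-data depths.

# Known limitations

* The NB test is a plain Wald test without LFC shrinkage or multi-factor
  designs; with a single replicate per condition the dispersion trend is
  driven by the (assumed mostly-null) gene ensemble.
* The periodicity screen assumes annotated CDS starts are correct; it
  does not discover ORFs.
* iCLIP retention by exact substring match is conservative with
  sequencing errors (real pipelines allow quality-aware alignment).
* The disome P-site convention is declared, not experimentally derived.
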