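---
title: "Methods: knockdown-controlled ChIP-seq analysis with kdchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockdown-controlled ChIP-seq analysis with kdchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdchip)
```

## The problem and the model

Sequence-specific transcription factors bind only a small fraction of their
cognate motifs in vivo. For an inducible factor such as heat-shock factor
(HSF), two analytical problems arise when mapping its binding sites by
ChIP-seq. First, antiserum cross-reaction produces peaks that have nothing
to do with the factor; an RNAi knockdown of the factor provides a direct
control, because genuine peaks must lose signal when the factor is
depleted while cross-reaction peaks do not. Second, comparing the motifs
the factor *does* bind with equally good motifs it leaves *free* requires
a motif model with calibrated p-values, a mappability filter (an unbound
motif is only interpretable where sequencing tags could have been mapped),
and a way to quantify the chromatin context of each motif class.

`kdchip` implements this full chain as composable stages:

1. **Tag libraries** — aligned 5′-end coordinates with strand; all signal
   quantities are normalized tag counts per 10 million library sequences.
   Windowed intensities use the 240-base window centered on a coordinate
   (300 for replicate correlation, 320 for qPCR-scale comparison, 400 for
   probe intensities).
2. **Peak filtering** — candidates from a region caller and a point caller
   are reconciled (same event when the point center falls inside the
   region boundary; caller-unique peaks are retained). Each candidate is
   then classified by knockdown sensitivity. With depletion defined as the
   experimental/knockdown window-count ratio, a peak is sensitive when it
   is (criterion 1) also called in the knockdown data but depleted more
   than a reference locus, or (criterion 2) absent from the knockdown
   calls and depleted at least 3-fold. Everything else is a
   knockdown-resistant false positive and is discarded.
3. **Motif model** — a position-specific weight matrix (PSWM) for the HSE,
   an inverted tandem array of three AGAAN-type 5-base units. Scores are
   log-odds in bits against a 0-order background; p-values are exact tail
   probabilities of the score distribution. Bound motifs are scanned at
   p ≤ 0.001 and assigned to peaks by nearest center within 60 bases;
   free motifs use the conservative p ≤ 5×10⁻⁶ cutoff.
4. **Mappability** — a position is unique when its 40-mer occurs exactly
   once in the genome counting forward and reverse-complement occurrences
   jointly; a free motif requires every 40-mer in its 400-base window to
   be unique.
5. **Annotation** — motif centers are classified against gene models:
   promoter (500 bases upstream of a TSS, strand-aware), genic, or
   intergenic; promoter and genic may hold simultaneously, and promoter
   windows are deliberately not clipped by neighbouring gene bodies so
   the dual class is visible.
6. **Landscape** — probe-level chromatin tracks are profiled around motifs
   in 100-base windows stepped by 50; per-factor association of bound
   versus free motifs with regions of significant enrichment uses the
   exact two-sided Fisher test; per-motif 400-base mean intensities feed
   k-means clustering with k = 5.

## Numerical choices

**Score lattice.** Log-odds entries are quantised to a 10⁻³-bit lattice at
matrix construction. Window scores are then sums of lattice values, and
the p-value is computed *exactly* on that lattice by dynamic-programming
convolution of the per-position score distributions. Because scoring and
the p-value table share one discrete score space, the reported p-value of
any reported score is exact (the unit tests verify agreement with full
4^W enumeration to better than 10⁻⁹), while the quantisation itself
perturbs a width-15 score by at most 0.0075 bits. Zero-probability matrix
entries give −∞ scores; windows containing N score −∞ and can never
become hits; the p-value of a finite score never includes −∞ outcomes.

**Fisher p-values.** The two-sided p is the hypergeometric tail-sum — the
total probability of all tables whose probability does not exceed the
observed table's (with the customary 10⁻⁷ relative tie tolerance). It is
computed directly from `dhyper` so the association stage can evaluate
many tables cheaply, and is cross-checked in the test suite against
`stats::fisher.test` and against an independent `choose()`-based
enumeration. Odds ratios are sample odds ratios with the Haldane 0.5
correction when a cell is empty. Per-factor p-values are reported
uncorrected, matching per-factor significance reporting; a
Benjamini–Hochberg column is emitted alongside.

**Depletion ratios.** Depletion is experimental/knockdown (values above 1
mean the knockdown removed signal), which makes both filtering criteria
one-sided and consistent. When the knockdown window count is zero, one
normalized unit is added to numerator and denominator — this avoids
infinite ratios while preserving ordering, and is logged. The reference
depletion defaults to 10/7 (a reference locus retaining less than 70% of
its signal after knockdown) and is configurable as an explicit ratio; it
is computed per condition when derived from a locus, since basal and
induced signal at an anchor locus need not deplete identically.

**Summits.** The plumbing caller works on 5′ ends shifted 75 bases in the
strand direction and reports the summit as the mean shifted-tag position
within 30 bases of the modal 10-base bin. A raw modal bin has 10–20 bases
of jitter at realistic coverage; the local mean brings summit error to a
few bases, which matters because motif assignment distances are
interpreted on a 20-base scale.

**Clustering.** Columns are z-scored (switchable) so marks with different
intensity scales contribute equally; missing 400-base intensities are
imputed with the column mean (k-means needs complete rows) and flagged.
Rows are canonically ordered internally before `stats::kmeans`, making
the partition invariant to motif input order under a fixed seed. `k`
equal to the number of motifs returns the degenerate zero-objective
partition explicitly.

**Tie-breaks.** Equidistant motif assignments go to the higher score, then
the lower coordinate. Opposite-strand scan hits whose footprints overlap
by at least half the motif width collapse to the better-scoring strand
(plus strand, then lower coordinate, on exact ties). Both rules are
deterministic and documented rather than order-dependent.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the study design so
every downstream stage can be checked against exact ground truth.

* **Genome.** A single chromosome (`chrS`, default 1 Mb) of i.i.d. bases,
  AT-rich by default (A = T = 0.29, C = G = 0.21) as in the fly genome.
  Planted motifs come in three classes with at least 2 kb spacing: *bound*
  (each carries one true, knockdown-sensitive peak centered on it), *free*
  (no peak), and *decoy* — direct repeats AGAAN AGAAN AGAAN, the
  orientation the factor does not bind in vivo, which carry the
  knockdown-resistant false-positive peaks. Infeasible packing is a loud
  error, never silent truncation.
* **Planting model.** The default sharp HSE matrix spells the inverted
  arrangement `NTTCT AGAAN NTTCT` — twelve informative positions, i.e.
  four per AGAAN-type unit. Under the AT-rich background a consensus
  instance has p ≈ 1.3×10⁻⁷, comfortably below the 5×10⁻⁶ free-motif
  cutoff; a nine-informative-position layout would sit at ~5.5×10⁻⁶ and
  straddle that threshold, so the twelve-position model is the one the
  generator plants.
* **Tag libraries.** Five libraries (`exp_nhs`, `exp_hs`, `kd_nhs`,
  `kd_hs`, `preimmune`) with Poisson-uniform background (default 0.02
  tags/base). Peak tags are displaced ~Normal(75, 25) bases from the
  center, 5′ ends upstream on the plus strand and downstream on the
  minus strand, so the bimodal 5′-end geometry and tag shifting are
  genuinely exercised. True peaks are enriched (default 40×) only under
  heat shock; their knockdown enrichment is 1 + (fold − 1)/40 under the
  default 40-fold depletion, i.e. signal over background divided by the
  depletion factor with a floor at background. Decoy peaks keep full
  enrichment in every antibody library under both conditions, as
  cross-reaction products do. The displacement mean is a free parameter
  of the generator, not an estimated quantity.
* **Chromatin tracks.** Tiling probes every 50 bases, baseline 1 plus
  Gaussian noise (σ = 0.25). Each bound motif is flagged enriched with
  probability 0.7 for active-mark-like factors (0.1 for free motifs); the
  default factor set includes one repressive-like mark with the
  probabilities reversed in miniature (0.1 bound / 0.2 free). Flagged
  motifs receive a contiguous +3-intensity block of half-width 300 bases
  recorded in the enriched-region list, and the truth's `mark_states`
  bookkeeping is updated so association tests have exact expectations.

**What passing tests do and do not show.** The generator reproduces the
*structure* of the study design — knockdown-sensitive versus resistant
peaks, bound versus free motifs, mark association — with known truth, so
green tests demonstrate that the algorithms recover what they are defined
to recover. Real data differ in ways the generator deliberately omits:
sequencing error, mappability bias, copy-number structure, fragment-length
heterogeneity, correlated probe noise, and motif families beyond a single
planted model. Numbers obtained on synthetic runs (e.g. recovery rates)
therefore validate the code, not the biology of any particular dataset.

## Problem sizes and runtime policy

Default synthetic runs use a 1 Mb genome with 100 bound / 150 free / 50
decoy motifs; property checks use 200–400 kb genomes, the filter-recovery
study 10 replicate simulations of 100 true peaks plus 50 decoys, and the
association study 100 replicate simulations of 200 motifs per class.
These sizes give every statistic comfortable Monte-Carlo headroom (the
type-I calibration of the association test pools 10 equal-probability
factors across the 100 replicates, since a 100-draw Bernoulli rate has a
±2.2% standard error that would be wider than the calibration band being
checked) while keeping a full run on one CPU in tens of seconds.

## Known limitations

* Mappability is exact-match uniqueness; mismatch-tolerant alignability is
  out of scope, so genomes aligned with mismatch tolerance will show
  slightly more unique positions here than a mismatch-aware tool reports.
  Reverse-complement palindromic k-mers are never unique by definition.
* The internal Poisson window caller is plumbing for synthetic runs and
  small studies; production peak calls from dedicated callers can be
  supplied as BED and enter at the reconciliation stage.
* Motif discovery is a deterministic seed-consensus extractor (scan each
  peak-flank window with a degenerate inverted-repeat seed, build the
  matrix from the best occurrence per peak, refine once), not
  expectation-maximisation; it is reproducible and sufficient for a
  single dominant motif family but will not discover unrelated motifs.
* Gene annotation uses every supplied TSS (multi-isoform genes are
  classified against each of their annotated starts) and does not model
  exon structure.
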