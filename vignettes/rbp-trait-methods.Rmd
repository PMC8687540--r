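---
title: "Methods: detecting RBP regulators of mRNA abundance and translational efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting RBP regulators of mRNA abundance and translational efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbptraits)
library(tibble)
```

## The question and the model

RNA-binding proteins (RBPs) shape gene expression after transcription: they
can stabilize or destabilize an mRNA (changing its abundance) or change how
efficiently ribosomes translate it (changing its translational efficiency,
TE). Given matched ribosome-profiling (Ribo-seq) and RNA-seq libraries
across a cohort of individuals, natural expression variation of an RBP acts
as a dose series: if the RBP regulates a target, the target's trait should
co-vary with the RBP's abundance across the cohort.

`rbptraits` implements this dose-response logic end to end:

1. **Quantification.** RNA-seq and Ribo-seq counts are normalized *jointly*
   with one median-of-ratios size-factor estimation over both assays —
   required so that TE, the per-gene per-sample ratio
   `TE = ribo_norm / rna_norm`, compares two quantities on the same scale.
   Genes enter the analysis when their mean FPKM (over CDS length, since
   counting is CDS-restricted) strictly exceeds 1 and both assays show at
   least one read in at least 20 samples.
2. **CLIP target sets.** Candidate targets come from replicated CLIP peak
   tables. Per peak we compute the relative information content
   `p * log2(p/q)` on library-normalized read fractions (with 0.5
   pseudocounts; raw read sums would make the log-ratio depth-dependent), a
   binomial one-sided enrichment p-value, and a fold change. Reproducibility
   across replicates is scored with a simplified copula-mixture IDR (below).
   A peak survives when `IDR < 0.01`, `p <= 1e-5`, and `FC > 8`, with the
   strictness of each inequality exactly as stated. Overlapping survivors
   are pooled by single-linkage, keeping the most significant peak; a gene
   is a target when at least one surviving peak overlaps one of its
   transcripts on the matching strand, and each peak is assigned a binding
   region by its midpoint with priority CDS > 5'UTR > 3'UTR > intron.
3. **Correlation.** For every RBP and every target, the RBP's normalized
   Ribo-seq values (protein output is what the hypothesis is about) are
   correlated with the target's mRNA abundance and TE by pairwise-complete
   midrank Spearman correlation. Per RBP and trait, p-values are
   Benjamini-Hochberg adjusted and targets with `p_adj <= 0.05` are called
   significant.
4. **Enrichment.** Counting significant targets is not enough — a large
   target set accumulates significant correlations by chance. The test
   therefore samples many equally sized gene sets from the translated
   universe (minus the RBP's own gene), counts BH-significant members of
   each under the *identical* family convention, and reports the empirical
   p-value `#{null >= observed} / n_sets` (floored at `1/n_sets`: a fixed
   number of sets cannot certify a smaller value) together with Glass'
   delta `(observed - mean(null)) / sd(null)` as the effect size. Empirical
   p-values are BH-adjusted across RBPs per trait; an RBP significant for
   mRNA abundance, TE, or both is labelled mRNA-RBP, TE-RBP, or
   multifunctional.
5. **Characterization.** Target sets are compared by Venn overlap
   (`100 * |A∩B| / |A∪B|`), correlation profiles are clustered (Euclidean /
   complete linkage; missing correlations imputed as 0 for distance only),
   target-set similarity uses 1 − Jaccard with average linkage, feature
   lengths are compared by Wilcoxon rank-sum tests, and 5'UTR structure by
   length-normalized minimum free energy (MFE).
6. **Replication.** In an independent cohort, the fraction of
   discovery-significant pairs whose correlation keeps its sign is tested
   against a within-RBP permutation null,
   `p = (1 + #{perm >= obs}) / (1 + n_perm)` (the +1 keeps p away from
   zero), BH-adjusted across RBPs.

## The simplified IDR

The reference IDR method models the two replicates' rank-transformed scores
as a two-component Gaussian copula mixture: a reproducible component with a
shifted mean and positive correlation, and an independent standard-normal
background. We implement that structure directly with EM, with three
documented simplifications and guards:

* Pseudo-scores start as normal quantiles of the ranks and are re-spaced
  after each EM fit using the fitted mixture marginal. Without this
  re-spacing the transform forces a standard-normal marginal and the
  shifted component can collapse onto the background (we observed exactly
  this failure mode on small peak tables).
* Convergence is assessed on the per-peak mean log-likelihood (tolerance
  `1e-6`, max 500 iterations per round, 10 re-spacing rounds), so the
  stopping rule does not tighten as peak tables grow.
* Identifiability guards: if the fitted mixture does not beat the
  independence model by at least 5 log-likelihood units, or the
  reproducible component's correlation falls below 0.1, the data contain no
  reproducibility evidence and every peak receives IDR 1.

The reported IDR applies the standard cumulative averaging of local
irreproducibility probabilities in rank order, making it monotone in rank
discordance. This is a deliberately simple estimator meant to be fitted on
dozens-to-thousands of matched peaks; it is not a numerical clone of the
reference implementation.

## The folding engine

5'UTR structure is summarized by a built-in nested-structure dynamic
program: admissible pairs GC/CG (−3), AU/UA (−2), GU/UG (−1), a minimum
hairpin loop of 3 unpaired bases, structure energy equal to the sum of pair
energies, no pseudoknots. The MFE is the minimum over all nested structures
(e.g. `GGGAAAACCC` folds to −9 via three GC pairs) and is normalized by
length (energy per nucleotide); sequences shorter than 20 nt are excluded
from comparisons. Two properties worth knowing:

* The model is exactly symmetric under sequence *reversal* (pair energies
  are order-symmetric and the loop constraint is distance-based), but *not*
  under reverse complementation: a GU wobble maps to the unpairable CA, so
  the two strands of a duplex can fold differently under this model.
* The engine is pluggable (`fold_mfe(..., engine = )`), e.g. to substitute
  a thermodynamic folder; all packaged analyses and tests use the built-in
  model so results are engine-pinned.

This is a base-pair-counting model, not a thermodynamic one: no stacking,
dangles, or loop penalties. It orders structured against unstructured
sequences correctly, which is all the sign-group comparison consumes.

## What the synthetic cohort emulates

The generator plants a known regulatory map and produces every input the
pipeline reads, so recovery can be scored against truth:

* RBP expression varies across samples through a standard-normal latent
  `z`; a planted target's log mean mRNA gains `beta * z` (mRNA targets) or
  its log TE gains `beta * z` (TE targets). Effects are additive on the log
  scale across RBPs, which keeps counts positive and composes cleanly.
* RNA counts are negative-binomial around `sf * mu`, Ribo counts around
  `sf * mu * TE`, with a common dispersion (default 0.1) and per-library
  size factors drawn from the configured depth range.
* CLIP peaks: true targets carry 1–3 binding sites with high IP:input
  ratios whose latent strength is shared across replicates; decoy genes
  receive input-like peaks at the false-positive rate with independent
  replicate scores — so the IDR and enrichment filters are genuinely
  exercised rather than fed pre-labelled peaks. Null RBPs get bound genes
  with no expression effect, which is what makes type-I error measurable.
* 5'UTRs are emitted at annotated lengths with a structured class (GC
  palindromic stem-loops) and an unstructured class (A/C background, in
  which no admissible pair exists).
* Splicing: designated cassette exons follow
  `logit(PSI) = b0 + 2 * coupling * z` with Poisson junction counts, plus a
  TE offset for the inclusion isoform.

Defaults are the study conditions used throughout the tests: 80 samples,
dispersion 0.1, unit effect sizes, dual-trait RBPs with disjoint target
sets (an overlap knob exists), CLIP false-positive/negative rates of 5%.
The cohort's real dispersion and effect-size distribution are unknown, so
these are realistic free parameters, not calibrated values. Features of
real data the generator does *not* emulate include batch structure,
gene-gene correlation beyond shared RBP regulation, length-dependent
coverage bias, and multi-mapping artifacts — passing tests demonstrate the
statistics recover a planted signal under the model's assumptions, not that
any particular biological dataset satisfies those assumptions.

## Numerical and design choices

* **Spearman p-values**: t approximation for n ≥ 10, exact permutation
  null (all n! arrangements) below; two-sided everywhere. Pairwise-complete
  records need at least `min_pairs = 10` observations.
* **BH family**: one RBP × one trait across its targets, matching the
  per-RBP retention language of the procedure; the null sets use the same
  convention (a consistency requirement for the enrichment test).
* **Empirical-p floor**: `1/n_sets`, the smallest value a fixed set count
  can certify.
* **Universe**: the RBP's own gene is excluded from the sampling universe
  to avoid self-correlation.
* **Pooling ties**: smallest p, then larger information content, then
  leftmost start — fully deterministic.
* **PSI**: `mean(inclusion up, down) / (mean + exclusion)` with a coverage
  floor of 10 junction reads; the floor also rules the degenerate 0/0 case
  out. The exact reference formula for PSI varies between tools; this
  variant is documented as the package's choice and is configurable.
* **Principal isoform**: highest mean abundance, ties to the longer
  transcript, then lexicographic id.
* **Length-matched subsampling**: all groups draw one shared per-decile
  allocation targeting the pooled length distribution, capped by the
  scarcest group per bin; draws are rejected until all pairwise length
  Wilcoxon p-values exceed 0.1 (up to 100 attempts).
* **Clustering linkages**: complete for correlation profiles, average for
  Jaccard overlap trees; both configurable, neither dictated by the
  procedure itself.
* **Degenerate inputs** raise typed errors (`rbptraits_config_error`,
  `rbptraits_degenerate_null`) rather than propagating NaN: zero-sd nulls,
  constant replicate scores, empty universes, malformed intervals.

## Problem sizes used in the packaged checks

The test suite and acceptance script run the whole machinery at desk scale,
chosen so each check finishes in minutes while keeping the statistical
properties measurable: the enumeration oracle uses a 20-gene universe
(15,504 sets), the type-I study 200 null RBPs × 1,000 genes × 2,000 null
sets, the recovery study 24 planted RBPs × 2,000 genes × 5,000 null sets,
the replication-null uniformity check 500 RBPs × 1,000 permutations, and
the default fixture 8 RBPs × 600 genes. The full-scale configuration
(100,000 null sets, 10,000 permutations) is the default of
`study_thresholds()` and runs unchanged, just longer.

## Known limitations

* The IDR estimator is simplified; on real eCLIP data with heavy-tailed
  score distributions the reference implementation should be preferred for
  numerical fidelity.
* The binomial enrichment p-value treats input reads as a fixed rate; an
  overdispersed or Fisher-type test is a drop-in alternative.
* The empirical enrichment test is purely sampling-based by design; no
  analytical approximation is attempted.
* Correlation does not imply causation: the pipeline ranks candidate
  regulators and quantifies effect sizes, and the collinearity filter
  (rank partial correlations within co-expression clusters) guards against
  the most common confounder, but experimental validation remains the
  arbiter for individual targets.
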