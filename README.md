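# rbptraits

Detects RNA-binding proteins (RBPs) whose expression level predicts the
mRNA abundance and/or the translational efficiency (TE) of their target
genes across a cohort of matched ribosome-profiling (Ribo-seq) and RNA-seq
libraries, classifies "multifunctional" RBPs that act on both layers, and
characterizes their targets (binding regions, feature lengths, 5'UTR
secondary structure, splicing).

**For whom:** computational biologists with (i) gene-level RNA-seq and
Ribo-seq count matrices over the same cohort, (ii) CLIP peak tables
defining candidate RBP targets, and (iii) a transcript annotation. A
synthetic-cohort generator with planted regulatory truth is a first-class
part of the package, so the whole pipeline can be benchmarked without any
controlled-access data.

## The statistics at the core

For RBP *r* with CLIP target set *T* and trait *y* ∈ {mRNA, TE}:

* Pairwise-complete Spearman correlation ρ(xᵣ, y_g) of the RBP's
  normalized Ribo-seq expression against each target g ∈ *T*, with
  Benjamini–Hochberg control per RBP × trait; targets with p_adj ≤ 0.05
  are *significant*. TE is the per-gene, per-sample ratio of jointly
  normalized Ribo-seq over RNA-seq values (one median-of-ratios size-factor
  estimation across both assays).
* The observed significant count *k* is compared against N equally sized
  gene sets sampled from the translated universe *U*:

      empirical p = #{ k_null ≥ k } / N        (floored at 1/N)
      Glass' Δ    = (k − mean(k_null)) / sd(k_null)

  with the identical BH family convention inside every sampled set.
  Empirical p-values are BH-adjusted across RBPs per trait; RBPs
  significant for mRNA, TE, or both are labelled mRNA-RBP, TE-RBP, or
  multifunctional.
* CLIP peaks are filtered upstream on a simplified copula-mixture IDR
  (< 0.01), a binomial enrichment p (≤ 1e-5), and fold change (> 8);
  5'UTR structure is summarized by a built-in Nussinov-style pair-energy
  minimum free energy, normalized by length; cross-cohort replication uses
  the fraction of sign-concordant correlations against a within-RBP
  permutation null.

See the methods vignette (`vignettes/rbp-trait-methods.Rmd`) for the model,
every tunable parameter, and the design decisions.

## Worked example

Simulate a small study (4 RBPs: one mRNA-regulator, one TE-regulator, one
dual-trait, one null) and run the full pipeline on its files:

```r
library(rbptraits)
library(tibble)

cfg <- sim_config(300, n_samples = 40,
                  rbps = tibble(rbp_id = sprintf("G%05d", 1:4),
                                trait = c("mRNA", "TE", "both", "null"),
                                n_targets = 30, effect_size = 1),
                  seed = 7)
simulate_study(cfg, "demo")
st <- run_study("demo",
                thresholds = study_thresholds(n_null_sets = 2000,
                                              n_perm = 1000,
                                              min_samples = 10),
                seed = 3)
st$summary[, c("rbp_id", "label", "p_adj_mrna", "p_adj_te", "overlap_pct")]
#> # A tibble: 4 × 5
#>   rbp_id label           p_adj_mrna p_adj_te overlap_pct
#>   <chr>  <chr>                <dbl>    <dbl>       <dbl>
#> 1 G00001 mRNA-RBP             0.001    0.128        3.57
#> 2 G00002 TE-RBP               1        0.001        3.85
#> 3 G00003 multifunctional      0.001    0.001        3.70
#> 4 G00004 none                 1        1           NA
```

Each planted class is recovered: the adjusted empirical p-values flag the
correct trait(s), the null RBP stays unlabelled, and the dual RBP's
significant mRNA and TE target sets barely overlap (3.7% of their union —
its two regulatory roles act on distinct genes). Drilling into one test:

```r
st$enrichment_objects[["G00002 TE"]]
#> Empirical target-set enrichment: G00002 / TE
#>   28 targets, 26 significant (null 5.48 +/- 2.40 over 2000 sets)
#>   empirical p = 0.0005, Glass' delta = 8.56
```

26 of 28 CLIP-derived targets correlate significantly with the RBP's
expression, against 5.5 ± 2.4 expected in random same-sized gene sets: the
observed count sits 8.6 null standard deviations above the null mean
(Glass' Δ), and no sampled set reached it (empirical p at the 1/N floor of
the 2,000-set run). `autoplot()` on that object draws the null histogram
with the observed count; `tidy()`/`glance()` return the per-target records
and the one-row summary. `score_recovery(st, read_table_tsv("demo/rbps.tsv"))`
scores the labels against the planted truth.

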