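# paircn

Absolute copy-number analysis for **paired diagnosis/relapse tumour
cohorts** profiled by shallow (~0.1×) whole-genome sequencing. High-grade
serous ovarian carcinoma is the motivating setting: a disease defined by
extensive copy-number alteration, where the scientific questions are
whether the genome changes between diagnosis and relapse, which focal
events (e.g. *CCNE1*, *KRAS* amplification) mark poor outcome, and how
copy-number signature exposures shift between patient groups.

`paircn` is aimed at statistical genomicists who want the whole chain as
tested, composable R functions — from binned read counts to cohort-level
inference — plus a synthetic paired-cohort generator with known ground
truth so that every stage can be validated without access-controlled
patient data.

## What it computes

Starting from per-bin read counts $c_b$ (30 kb bins with GC and
mappability annotations), the package:

1. **Corrects bias and segments** — median-binning GC/mappability
   correction to relative copy number $r$ (median 1), then penalised
   changepoint segmentation (PELT, L2 cost on $\log_2 r$, implemented in
   C++).
2. **Fits purity and ploidy** — grid search over $\rho \in [0.2, 1]$,
   $\psi \in [1.6, 8]$ minimising the length-weighted squared distance of
   $$n_s = \frac{r_s[\rho\psi + 2(1-\rho)] - 2(1-\rho)}{\rho}$$
   to non-negative integers, with continuous refinement, ploidy-parsimony
   tie-breaking and quantitative QC.
3. **Quantifies copy-number signature exposures** — six feature
   distributions (segment size, breakpoints per 10 Mb and per arm,
   change-point magnitude, copy-number state, oscillating chain length)
   encoded as sum-of-posteriors vectors against a mixture-component model,
   decomposed by non-negative least squares against a column-stochastic
   signature matrix; exposures are non-negative and sum to 1.
4. **Scores intra-tumour heterogeneity** — the length-weighted average
   distance of segment copy numbers from integer states, and its paired
   change ΔITH.
5. **Runs cohort statistics** — genome-wide paired subtraction with
   per-bin Mann–Whitney tests and chromosome-wise Benjamini–Hochberg
   correction; ploidy-aware focal gene event calling with Fisher exact
   comparisons; per-signature rank tests; Kendall/Spearman
   exposure–immune-density correlations; and a global
   differential-abundance test of exposures using isometric log-ratio
   coordinates with a patient-level mixed model and a small-sample
   calibrated Wald test.

A full description of the models, parameter defaults and numerical
choices is in the methods vignette
(`vignettes/paircn-methods.Rmd`).

## Worked example

```r
library(paircn)

layout   <- genome_layout("toy")            # 3 chromosomes, 300 Mb, 30 kb bins
bins     <- layout_bins(layout, seed = 1)   # GC + mappability annotations
segments <- simulate_cn_profile(layout, exposures = c(.3,.1,.2,.1,.1,.1,.1),
                                event_budget = 15, baseline_ploidy = 3, seed = 11)
counts   <- emit_binned_counts(segments, bins, purity = 0.65, depth = 60, seed = 12)

fit <- call_absolute(counts)   # correct_bias() |> segment_profile() |> fit_purity_ploidy()
glance(fit)
#> # A tibble: 1 × 7
#>   purity ploidy grid_ploidy   score frac_integer qc_pass n_segments
#>    <dbl>  <dbl>       <dbl>   <dbl>        <dbl> <lgl>        <int>
#> 1  0.646   3.76        3.75 0.00249        0.998 TRUE            47
compute_ith(fit)
#> [1] 0.03081347
```

The generator's truth for this sample was purity 0.65 and ploidy 3.755:
the fit lands at 0.646/3.765 with a goodness-of-fit score of 0.0025 and
99.8% of the genome within 0.3 of an integer state, and the ITH of 0.031
reflects count noise only (the simulated genome is clonal). `tidy(fit)`
returns the absolute segment table, `autoplot(fit)` draws it.

Cohort-level compositional testing, on a simulated 47-pair cohort with a
planted 0.15 shift in signature 5 at relapse:

```r
exposures <- simulate_exposure_cohort(47, shift_signature = 5, shift = 0.15, seed = 1)
comp <- fit_global_abundance_model(exposures, group_col = "role")
comp
#> <ilr_fit> diagnosis vs relapse on 6 coordinates (closed-paired)
#>   Wald W = 155.321, p = 1.064e-11
inverse_ilr_group_means(comp)   # fitted group compositions on the simplex
compare_exposures_univariate(exposures, "role", paired = TRUE)  # per-signature tests
```

Excluding a signature suspected of tracking fixation artefact and
re-testing is `fit_global_abundance_model(exposures, exclude = "s5")`.
`run_pipeline(list(n_patients = 8, seed = 1), out_dir)` chains every stage
(simulate → fit → signatures → ITH → subtraction → gene events →
composition test) and writes TSV outputs plus a JSON summary,
byte-identically under the same seed.

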