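---
title: "Methods: paired shallow-WGS copy-number analysis with paircn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired shallow-WGS copy-number analysis with paircn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircn)
```

`paircn` implements the copy-number arm of a paired diagnosis/relapse tumour
genomics analysis: from binned shallow whole-genome sequencing (sWGS) read
counts to absolute copy number, copy-number-signature exposures,
intra-tumour heterogeneity (ITH), genome-wide paired subtraction, focal gene
event comparisons, and compositional differential-abundance testing. This
vignette documents the models, the tunable parameters, the numerical
choices, and — because every stage is exercised against a bundled synthetic
cohort generator — exactly what the passing test suite does and does not
demonstrate about real data.

## The measurement model

sWGS copy-number profiling counts reads in fixed genomic bins (30 kb by
default). For a bin with tumour copy number $n$ in a sample of purity
$\rho$ (tumour fraction) and tumour ploidy $\psi$ (length-weighted mean
copy number), with diploid non-tumour contamination, the expected count is

$$\mu \;=\; d \cdot \frac{\rho\,n + 2(1-\rho)}{\rho\,\psi + 2(1-\rho)}
\cdot b_{gc} \cdot m,$$

where $d$ is the mean reads per bin, $b_{gc}$ a smooth GC bias and $m$ the
bin mappability. The default depth of 60 reads per 30 kb bin corresponds to
a 0.1&times; coverage target with 50 bp single-end reads. At that depth bin
counts are close to Poisson; the generator draws Poisson counts by default,
with a negative-binomial option (`dispersion`) and an exact-expectation
mode (`noise = "none"`) for noiseless recovery experiments.

The inverse of the mixture expectation is the absolute-copy-number map
used throughout (`to_absolute()`):

$$n \;=\; \frac{r\,[\rho\psi + 2(1-\rho)] - 2(1-\rho)}{\rho},$$

with $r$ the bias-corrected, normalised relative copy number. It can be
negative for noisy low $r$; values are clipped only at reporting time.

## From counts to absolute copy number

**Bias correction** (`correct_bias()`). Bins with mappability below
`map_min` (default 0.25) are masked. Counts are divided by a two-stage
median-binning fit — per-quantile-group medians against GC, interpolated
linearly, then the same against mappability — and median-normalised so the
unmasked bins have median $r = 1$. Median binning was chosen over LOESS for
determinism and robustness; with 20 quantile groups it inverts smooth
planted biases to within 2% median absolute deviation in the tests.

**Segmentation** (`segment_profile()`). Piecewise-constant fitting by
penalised exact changepoint search (PELT, implemented in C++) with an L2
cost on $\log_2 r$, run per chromosome on unmasked bins. The penalty per
changepoint is `penalty`$\cdot\hat\sigma^2\log n$ with $\hat\sigma$ a
robust (median-absolute-difference) noise estimate; `penalty = 4` is
deliberately conservative for the heteroscedastic log-scale noise of
Poisson counts, and a minimum segment length of 3 bins suppresses
single-bin outliers. As the penalty grows the segmentation collapses to one
segment per chromosome. Segment values are means of member bins on the
linear scale, and segments tile each chromosome exactly (masked bins are
absorbed into the enclosing segment).

**Purity/ploidy fitting** (`fit_purity_ploidy()`). A grid search over
$\rho \in [0.20, 1.00]$ and $\psi \in [1.6, 8.0]$ (0.05 steps) scores each
candidate by the length-weighted mean squared distance of the transformed
segment values to their nearest non-negative integer state. Three numerical
choices matter here, and all stem from one identifiability analysis:

1. **Relative profiles only identify $(\rho, \psi)$ up to affine
   relabelings of the integer states.** A 50%-pure genome with states
   $\{n\}$ produces exactly the same relative profile as a pure genome with
   states $\{n+2\}$; scaling relabelings ($n \to 2n$) are likewise exact.
   Near-optimal candidates (scores within `tie_tol` of the optimum) are
   therefore resolved by *ploidy parsimony*: lowest ploidy first, then
   highest purity. Down-shifted relabelings are excluded automatically by
   the non-negativity penalty whenever the genome carries a zero-copy
   segment — which is why the generator plants one focal homozygous
   deletion per genome by default (`anchor_deletion`): tumour-suppressor
   homozygous deletions are near-universal in high-grade serous carcinoma,
   and without any low-copy state no fitter, however implemented, could
   distinguish the true fit from a shifted one.
2. **The top grid candidates are refined continuously** (L-BFGS-B) before
   comparison. The optimum rarely falls on the 0.05 grid, and a relabeled
   solution can land closer to *its* nearest grid point than the truth does
   to its own; after refinement, relabeled solutions amplify the residual
   error by their state-scale factor and lose on score whenever the data
   carry any noise.
3. **Segments supported by fewer than `min_fit_bins` (5) bins are excluded
   from the score.** Sub-resolution segments average neighbouring states;
   their fractional means (e.g. thirds of integers) can make scaled
   relabelings look spuriously exact.

The reported ploidy is the length-weighted mean of the fitted absolute
segment values, which makes it consistent with the generator's definition
of tumour ploidy. Because the bias correction fixes the *median* of $r$ at
1 while the mixture model assumes unit length-weighted *mean*, the fit
renormalises segment values to unit weighted mean internally.

Quantitative QC: a fit passes if its score is at most `qc_max_score` (0.1)
and at least half the genome lies within 0.3 of an integer state. This is a
declared, testable stand-in for the combined quantitative/qualitative
review a production pipeline would apply; it intentionally cannot detect
state-relabeled fits (those are exactly as integer-like as the truth),
which is another reason low-purity samples warrant manual review. On
noiseless cohorts spanning $\rho \in \{0.3, 0.5, 0.7, 1.0\}$ and baseline
ploidies 2–4 the fitter recovers both parameters within one grid step in
&ge; 95% of 120 runs; with Poisson noise at 0.1&times; depth, fits below
$\rho \approx 0.35$ become unreliable — consistent with practice, where
such samples are excluded by review.

**Ploidy change** (`call_ploidy_change()`) is a thresholded comparison of
the two fitted ploidies (default 0.5 copies) and refuses failed-QC input.

## Copy-number signatures

Six feature distributions are extracted per genome
(`extract_features()`): segment size; breakpoint counts per 10 Mb window
and per chromosome arm; change-point magnitude between adjacent segments;
integer copy-number state (capped at 10); and lengths of oscillating
chains, defined as maximal runs of at least three segments alternating
between exactly two states. States are integer-rounded first (ties at x.5
to the lower state), adjacent equal states merged, and segments split at
centromeres so breakpoints and chains are counted within arms.

A sample is encoded against a mixture-component model as a
sum-of-posteriors vector $v$ ($v_k$ = total posterior probability of
component $k$ over all observed values of its feature, with equal
component priors). Exposures are the non-negative least-squares solution of
$\min_x \|S x - \hat v\|_2$ on the sum-normalised vector, renormalised to
the simplex; the decomposition is scale-invariant and recovers exact
column mixtures to 1e-6 and noisy mixtures to a mean absolute error below
0.05.

The component model and the signature definitions $S$ are *external
inputs* in this design: the bundled defaults are synthetic stand-ins with
the same shape as published definitions, and users with real definitions
supply them as TSV. The bundled $S$ is produced by
`calibrate_signature_definitions()`, which regresses encoded component
vectors on known exposures over a training set of simulated mixed genomes
(row-wise NNLS). Calibrating on mixtures rather than pure-signature
genomes matters: co-occurring events interact (stacked events create
breakpoints no single event class produces), and regression absorbs those
average interaction effects the way data-derived definitions do.

**What end-to-end recovery shows — and does not.** With calibrated
definitions, quantification from true genomes recovers exposures with an
overall correlation of ~0.85 and identifies the dominant signature in
~75% of sparse-exposure samples; the rank correlation of the dominant
signature's exposure across samples is ~0.7. The residual error is
broadband noise from the multinomial assignment of events to classes,
random event sizes, and event interactions — not systematic confusion
between particular signatures. The property test therefore asserts
overall correlation > 0.75, dominant-identity recovery &ge; 60% and
dominant rank correlation > 0.4; stronger per-sample claims would not
survive reseeding and we prefer an honest bound.

## Intra-tumour heterogeneity

$$\mathrm{ITH} = \frac{\sum_s \ell_s\,\bigl|a_s - [a_s]\bigr|}
{\sum_s \ell_s},$$

the length-weighted (bp, not bin-count) average distance of segment copy
numbers from the nearest non-negative integer; it is 0 for fully clonal
profiles, bounded by 0.5, invariant to splitting segments at equal value,
and verified against a brute-force bin-level oracle to 1e-9. Ties at x.5
resolve to the lower state, which affects only the reported nearest state,
never the distance. ΔITH is the paired relapse-minus-diagnosis difference.

## Cohort statistics

**Paired subtraction** (`subtract_pairs()`). Per-sample absolute segments
are projected onto the common bin grid; per bin, diagnosis and relapse
values across patients are compared with a two-sided Mann–Whitney U test
(normal approximation with continuity correction; fully tied bins get
$p = 1$), with Benjamini–Hochberg correction applied *within each
chromosome* and the profile reported as median(relapse) −
median(diagnosis). Complete-case handling drops patients bin-wise. Swapping
the role labels negates the profile exactly.

**Focal gene events** (`call_gene_events()`). Gene copy number is the
length-weighted mean over overlapping segments; amplified iff
$CN \ge \max(5,\, 2\hat\psi)$, deleted iff $CN \le \max(\hat\psi - 1.87,
0)$ — ploidy-aware thresholds in the style of HGSC copy-number studies,
fully overridable to match any external convention. Group comparisons are
two-sided Fisher exact tests with BH correction across the gene family
tested; per-signature univariate tests (Mann–Whitney unpaired, Wilcoxon
signed-rank paired) are reported unadjusted by default, matching common
reporting practice for signature panels.

**Compositional differential abundance**
(`fit_global_abundance_model()`). Exposures live on the simplex, so group
comparisons use isometric log-ratio (pivot) coordinates; zeros are handled
by multiplicative replacement with floor `eps` (1e-3). Per coordinate the
model has a fixed group effect and a random patient intercept; the global
test asks whether all group slopes are jointly zero. For the Wald
statistic we estimate the *joint* covariance of the slopes and use a
small-sample F reference: in the balanced paired design the mixed-model
slope estimate reduces exactly to the mean within-patient difference
vector, giving the Hotelling form with $F_{p,\,n-p}$; with one sample per
patient the two-sample pooled form applies (the random intercept is not
identifiable and the fit records the fixed-effects fallback); genuinely
unbalanced designs fall back to per-coordinate `lme4` fits with a
residual-correlation-coupled covariance and a chi-square reference. The
F calibration is deliberate: referring the 6-coordinate Wald statistic to
chi-square at $n = 47$ pairs has an analytic type-I error of ~0.11 at
$\alpha = 0.05$, whereas the F form is exact under normality — the
permutation-null simulation in the test suite measures ~0.03–0.06.
Excluding a signature (e.g. one suspected of tracking fixation artefact)
renormalises the subcomposition before the transform, and
`inverse_ilr_group_means()` maps fitted group means back to the simplex.

**Immune correlations** (`correlate_exposures_immune()`): Kendall and
Spearman rank tests per signature/marker/compartment, unadjusted; constant
inputs are reported as missing rather than as a correlation.

## The synthetic cohort generator

`simulate_paired_cohort()` produces what the analysis consumes: per
patient, one diagnosis and one relapse genome (integer copy-number tilings
built from signature-linked structural events: large gains/losses, arm
losses, focal amplifications at two amplitudes, chromothriptic-like
shattering, oscillating chains), binned counts under the mixture model, and
clinical labels following the platinum rule (resistant iff relapse under
6 months since last platinum; ~24% resistant, ~10% primary platinum
resistant by default; one prior line in ~60% of patients). Purities are
uniform on 0.2–1.0, baseline ploidies 2–4, exposures Dirichlet(0.7) —
sub-1 concentration because real samples are dominated by one or two
mutational processes. Relapse genomes equal diagnosis genomes under the
default `perturbation = "none"` (the stable-genome null), or receive a
declared planted region or a whole-genome doubling for power studies.

What it does *not* emulate: allele-specific signal and LOH, real GC/
mappability tracks, replication-timing and wave artefacts, fixation
artefacts, multi-region sampling, subclonality (all simulated states are
clonal integers, so planted ITH is zero up to fit noise), and the
correlated event co-occurrence of real tumours. Passing tests therefore
demonstrate internal correctness and statistical calibration of the
methods under a controlled model — not performance on real sWGS libraries.

## Problem sizes and determinism

Tests and the acceptance script run on a reduced 3-chromosome, 300 Mb toy
genome (10,000 bins at 30 kb; `genome_layout("toy")`); a GRCh37-scale
22-autosome layout is available for realistic runs. Simulation sizes used
by the stochastic suites: 120 noiseless purity/ploidy recovery runs; 500
permutation replicates (47 pairs) for Wald calibration and 200 for power;
20 pairs for the planted-region subtraction; 100 replicates for noisy
exposure recovery. Every stochastic operation takes an explicit seed and
restores the caller's RNG state; pipelines re-run byte-identically under
the same configuration.

## Known limitations

* Low-purity ($\rho \lesssim 0.35$) fits at 0.1&times; depth are
  unreliable and can alias to state-relabeled solutions that pass
  quantitative QC; real pipelines add qualitative review.
* The bundled component model and signature definitions are synthetic;
  exposures from them are only comparable within this package's
  simulations. Supply real definitions for real data.
* The subtraction test treats bins independently (as the per-bin test
  family does); spatial correlation of segments means the effective number
  of independent tests is smaller than the bin count.
* ITH conflates subclonality with fit noise; it is a distance-from-integer
  summary, not a clone-number estimate.
* Sub-diploid genomes (ploidy < 1.6) fall outside the fitting grid and are
  reported as the nearest in-grid solution.
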