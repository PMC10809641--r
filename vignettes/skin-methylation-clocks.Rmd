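---
title: "Methylation clocks for skin aging phenotypes: models, conventions, and the synthetic stated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation clocks for skin aging phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`skinclock` trains and validates second-generation epigenetic clocks:
ridge-regression predictors of panel-rated skin phenotypes (wrinkle
grade on a 1–100 scale, visual facial age in years, and visual age
progression = visual age − chronological age) from DNA-methylation
beta-value matrices. Around the clocks sit the supporting stages a real
analysis needs: probe QC and quantile normalization, low-methylated
region (LMR) calling from WGBS-like counts, region-level feature
aggregation, validation statistics, preranked gene-set enrichment, and a
multi-source pathway consensus. A synthetic-cohort generator stands in
for restricted study data.

This vignette records the model conventions, every numeric default and
why it was chosen, what the generator does and does not emulate, and the
places where the design was genuinely open.

## The ridge clock

Features (CpG or LMR beta values) are standardized to mean 0 and
**population** SD 1 (divide by n, not n − 1); zero-variance features are
dropped and recorded. With centred outcome, coefficients solve

$$(\tilde X^\top \tilde X + \lambda n I)\,\beta = \tilde X^\top (y - \bar y),$$

with the intercept $\bar y$ unpenalized. Two consequences worth stating:

* **λ values are convention-bound.** The same fit under a different
  scaling (e.g. penalty not multiplied by n, or sample-SD
  standardization) produces a different numeric λ. Printed λ values are
  therefore never comparable across implementations, and none are used
  as acceptance values here.
* The solver uses the singular-value decomposition,
  $\beta = V\,\mathrm{diag}(d_i/(d_i^2+\lambda n))\,U^\top(y-\bar y)$,
  which is exact for λ > 0 and falls back to the minimum-norm
  (pseudoinverse) solution along rank-deficient directions at λ = 0.
  This makes the p ≫ n case (all array CpGs) and the λ = 0 limit both
  well-defined. Tests verify equivalence against an independent direct
  normal-equations solve to 1e-8.

**Lambda path.** A 100-point geometric sequence from $\lambda_{max}$
down to $\lambda_{max}\cdot r$. $\lambda_{max}$ is doubled until the
largest standardized coefficient is below 1e-3 of its unpenalized value
(an effectively null model). The terminal ratio default is **1e-9**, not
the glmnet-style 1e-4: with 1e-4 the smallest λ still shrinks
coefficients by ~9%, so a noiseless linear problem cannot reach
near-zero CV error, which contradicts the intended behaviour of the
path. Nine decades over 100 points still gives a dense grid (≈ 23%
spacing).

**Cross-validation.** Seed-determined k-fold assignment (sizes within
one); per fold, standardization is re-estimated on the training part
only. Selection minimizes mean held-out MAE — MAE, not deviance, because
MAE is the reported performance metric and using one criterion
throughout keeps selection and reporting consistent. Ties go to the
larger λ (more regularization at equal error). The final model is refit
on all training data at the selected λ.

**Stratified partition.** Samples are binned into `n_bins = 10` outcome
quantile bins; within bins a floor allocation plus a seeded,
remainder-weighted draw makes the training size exactly
$\lfloor p\,n\rfloor$ (378 samples at p = 0.8 → exactly 302) while each
bin's train fraction deviates from p by at most one sample. The bin
count is a package choice; the reference partitioning utility does not
document its binning.

## LMR calling

Input is per-CpG (position, methylated count, total count), 0-based
positions internally, strictly increasing per chromosome (counts from
replicates are assumed pooled by summation). Stages:

1. **Smoothing**: pooled-count ratio over a centred window of
   `smoothing_window = 3` CpGs (truncated at chromosome ends). Pooling
   counts rather than averaging ratios keeps low-coverage CpGs from
   dominating.
2. **Segmentation**: maximal runs of consecutive CpGs with smoothed
   methylation `< m` containing at least `n` CpGs. Region span is first
   CpG position to last CpG position + 1 (half-open); the alternative of
   extending to flanking-CpG midpoints was rejected because it makes
   coordinates depend on sparse, coverage-dependent neighbours. Region
   methylation is the pooled meth/total over members.
3. **Classification**: segments with at most `lmr_max_cpgs = 30` CpGs
   are LMRs, larger ones UMRs (unmethylated regions, typically
   promoters). The boundary is inclusive on the LMR side. `m = 0.5`,
   `n = 4`, and the 30-CpG split follow the conventions of the
   established segmentation method this stage emulates; they are
   faithful defaults, not values printed in any study.
4. **FDR calibration**: for each (m, n) on a grid (m ∈ {0.3…0.7},
   n ∈ {3…6}), the FDR estimate is the mean segment count over
   methylomes with (meth, total) pairs permuted within chromosome,
   divided by the observed count, capped at 1. The permutation null
   preserves coverage and the global methylation level while destroying
   spatial structure — exactly the feature segmentation exploits. The
   **least stringent** passing grid point is selected: largest m first,
   ties to smallest n, so the method detects as much as the FDR budget
   allows. If nothing passes (e.g. the input has no spatial structure)
   calibration raises an error rather than returning a cutoff.
5. **Probe intersection**: only LMRs containing at least one array
   manifest CpG are kept (UMRs are excluded by class, however many
   probes they span), and CpG betas are averaged per region
   (unweighted) to form LMR-level features.

## Preprocessing conventions

* **Detection-p filter**: a probe is removed if its detection p exceeds
  0.01 in *any* sample. The any-sample rule is the strictest
  deterministic reading; fraction-of-samples variants require an extra
  parameter nothing in the analysis pins down. Blocklisted probes
  (SNP-affected, cross-hybridizing) are removed next; a probe failing
  both is counted under detection.
* **Quantile normalization** is plain full quantile normalization: each
  sample's sorted vector is replaced by the across-sample mean of order
  statistics; ties receive the mean of their tied reference quantiles.
  The probe-type-stratified variant used with raw array data needs
  probe-chemistry metadata that is out of scope here; this is a
  deliberate simplification. One subtlety: the tie-averaging rule feeds
  averaged values back into the next pass's reference, so strict
  idempotence holds only for tie-free matrices — the generic case for
  continuous beta values. With ties, a second application perturbs
  values at the order of the tie-induced reference distortion, not at
  machine precision.
* **Missing betas** are rejected at ingest; silent imputation hides
  upstream problems.
* **Coordinates**: manifest positions are read as 1-based
  (array-manifest convention) and converted to the internal 0-based
  half-open convention; BED output is natively 0-based half-open.

## Validation statistics

Pearson correlation with the two-sided t test
($t = r\sqrt{(n-2)/(1-r^2)}$, n − 2 df). The Wilcoxon rank-sum test uses
pooled mid-ranks; the exact two-sided p (full enumeration over group
assignments, computed by subset-sum dynamic programming and verified
against brute-force enumeration) applies when both groups have ≤ 25
observations and the pooled data are tie-free — 25 covers the
Youngster/Oldie-style group sizes (10 and 15). Ties always route to the
normal approximation with tie and continuity corrections; exact
enumeration under ties is out of scope. All tests are two-sided; the
analyses being emulated do not state sidedness, and two-sided is the
reference tools' default. Progression-clock reports include the
correlation of predictions with chronological age as a secondary
diagnostic: a progression clock that merely re-predicts age is a
failure mode worth surfacing. Constant predictions are flagged instead
of producing an undefined correlation.

## Enrichment and consensus

Three rankings feed preranked enrichment:

1. **Coefficients**: each model feature's coefficient is assigned to
   every gene annotated to any of its member CpGs; per-gene weights are
   the **signed sum**. Signed (not absolute) summing is the natural
   reading of a linear model: opposing coefficients on one gene cancel.
2. **Methylation correlation**: per-CpG Pearson r against the clock
   predictions; CpGs with p > 0.05 discarded; surviving CpGs annotated
   to genes; per-gene weight is the **mean** r.
3. **Expression correlation**: the same, with genes native and
   duplicate rows averaged after filtering.

The enrichment statistic is the weighted Kolmogorov–Smirnov running
sum: walking the ranking top to bottom, hits add
$|w|^{1}/\sum_{set}|w|$, misses subtract $1/(N-|set|)$; the ES is the
running-sum value of maximal absolute deviation (first such position on
ties). "Permutations of gene sets" means random same-size gene sets
drawn from the ranked genes — sample permutation is impossible for a
preranked list. NES divides ES by the mean |null ES| of matching sign;
the nominal p is the plus-one estimator over the same-signed null, so
p ≥ 1/(n_perm + 1). Permutation seeds derive from the gene-set index
only, so identical rankings given as two sources produce identical
tables. Per source, results truncate to the 20 largest |NES| (ties by
nominal p, then name) — |NES| rather than p because it is the quantity
the consensus averages; FDR q-values are deliberately not computed, as
the consensus uses overlap and |NES| only. The consensus keeps pathways
in ≥ `min_sources` truncated lists, sorted by mean |NES| over
supporting sources.

## The synthetic stated world

The generator emulates the cohort structure the analysis assumes, with
defaults fixed once:

| Parameter | Default | Rationale |
|---|---|---|
| `n_subjects` | 378 | emulated cohort size |
| `age_range` | 29–84 y | emulated cohort range |
| `rater_count` | 30 | panel size |
| `rater_sd_wrinkle` | 11.85 | median per-subject rating SD, wrinkle scale |
| `rater_sd_age` | 6.55 y | median per-subject rating SD, visual age |
| `wgbs_mean_coverage` | 14 | stated average strand-specific coverage |
| `progression_sd` | 5 y | matches the ±5 y "looks older/younger" contrast used for group studies |
| `effect_size` | 0.005 beta/y | ~0.05 beta across a 10 y progression swing — the size of reproducible aging DMR effects |
| `beta_noise_sd` | 0.02 | typical array technical noise for mid-range betas |
| wrinkle map | −20 + 1.2·visual + N(0, 5), clipped to [1, 100] | maps ages 29–84 onto roughly 15–80 wrinkle units, correlated with but distinct from visual age |

Structure: chronological age uniform on its range; progression Gaussian
and by default independent of age (`age_coupling` can introduce the
weak observed coupling; the joint distribution is not documented
anywhere, so it stays configurable rather than fixed). Visual age is
exactly age + progression, and progression is re-derived from the
stored sum so the identity holds bit-exactly. Planted LMRs are runs of
5–10 CpGs with baseline beta in [0.05, 0.25] against a [0.65, 0.95]
background; progression-linked CpGs fill whole planted LMRs (in seeded
random order, truncating the last) so that region-averaged features
carry the signal. WGBS totals are Poisson(coverage) — the simplest
count model consistent with a stated mean — with binomial methylated
counts and zero-coverage CpGs omitted. Expression is log-normal with a
latent Gaussian component correlated with progression at `effect_r`,
signs alternating. Ratings are truth plus i.i.d. Gaussian rater noise,
clipped to [1, 100] on the wrinkle scale before averaging. Each CpG
carries 0–2 gene symbols, multi-gene CpGs included deliberately to
exercise the duplicate-gene aggregation rules.

**What the generator does not emulate** — and therefore what a green
test does not establish: probe-type (I/II) chemistry bias, batch
effects, cell-composition heterogeneity, age-linked methylation drift
independent of progression, spatial correlation of array noise, and
realistic genome geometry (two synthetic chromosomes, uniform CpG
spacing 20–200 bp). Tests passing on this world show the pipeline's
logic is correct, not that any real-data performance number is
reproduced; the emulated study's headline numbers are bound to
restricted data and are explicitly not acceptance targets.

## Error handling and determinism

Errors are classed (`skinclock_config_error`, `skinclock_data_error`,
`skinclock_model_error`, plus specific classes for empty rankings,
empty overlaps, undefined NES, and calibration failure) and map to
distinct CLI exit codes (2/3/4). Every random operation takes an
explicit seed, uses it through an RNG-state-restoring wrapper, and
derives child seeds for sub-streams, so identical configurations give
byte-identical outputs; the pipeline writes a `run_manifest.json`
sidecar with the config hash, seed, timings, and per-file MD5s.
Stages resumed from on-disk TSV intermediates can differ from in-memory
execution in the last floating-point digit (text round-trip); the
byte-reproducibility guarantee applies to identical execution paths.

## Known limitations

* LMR calling is cutoff segmentation with permutation-FDR calibration —
  deliberately simpler than the hidden-Markov/partially-methylated-
  domain machinery of full methylome segmenters; no CpG-island masking.
* Exact Wilcoxon p is unavailable under ties (approximation used).
* Quantile normalization is unstratified (see above).
* No elastic-net/lasso (α is fixed at 0 by design), no chronological-age
  clocks, no confidence intervals on r, no FDR across gene sets.
* The CpG-level clock accepts any CpG matrix; no opinion is taken on
  which probes a real analysis should feed it.
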