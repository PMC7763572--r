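---
title: "Salivary NMR metabolomics with multilevel PLS and OPLS-DA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salivary NMR metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivanmr)
```

## The analysis problem

Non-surgical periodontal therapy (scaling and root planing) changes the
composition of saliva. One-dimensional ^1^H-NMR spectroscopy of unstimulated
saliva gives a fingerprint of the low-molecular-weight metabolome, and the
question this package addresses is twofold: *does the salivary metabolic
profile of generalized-periodontitis patients shift after therapy*, and
*does the treated profile become indistinguishable from that of
periodontally healthy individuals*? The design is paired and three-armed:
each patient contributes a baseline sample (`B`) and an after-treatment
sample (`AT`), and an independent group of healthy individuals (`HI`)
contributes one sample each.

`salivanmr` implements the full analysis chain for this design:

1. **Preprocessing** — chemical-shift calibration on the TMSP reference,
   0.02 ppm bucketing with exclusion of the residual water region
   (4.3–6.5 ppm), total-area normalization, and metabolite signal-area
   integration over assignment windows.
2. **Chemometrics** — PLS-DA by NIPALS; multilevel (paired) PLS on the
   within-subject variation for the B-vs-AT contrast; OPLS-DA with
   orthogonal signal correction for the three-group comparison.
3. **Validation** — Monte Carlo cross-validation with pooled confusion
   matrices, and permutation tests on cross-validated accuracy.
4. **Univariate statistics** — Kruskal–Wallis across the three groups,
   paired Wilcoxon signed-rank for B vs AT, Mann–Whitney for HI vs AT,
   each family corrected by Benjamini–Hochberg FDR.
5. **Synthetic cohorts** — a generator that emulates the study design from
   a packaged 31-metabolite reference panel, so every downstream stage is
   testable without clinical data.

## Preprocessing model

A spectrum is a pair of equal-length vectors: a strictly ascending ppm axis
and real intensities. The preprocessing parameters live in
`preprocess_config()`:

| parameter | default | meaning |
|---|---|---|
| `reference_ppm` | 0.00 ppm | target position of the TMSP reference line |
| `reference_search_window` | ±0.2 ppm | window searched for the reference apex |
| `bin_width` | 0.02 ppm | bucket width |
| `ppm_range` | −0.5 to 10.0 ppm | region tiled by buckets |
| `exclusion_regions` | 4.3–6.5 ppm | residual water resonance |
| `normalization_total` | 1.0 | row total after normalization |

Calibration rigidly shifts the axis so the apex of the reference peak lands
exactly on the target; ties between equal apexes break toward the candidate
nearest the target, making the operation deterministic and idempotent.

Several choices here were genuinely open and are fixed as follows:

* **Bucket anchoring and edge convention.** Buckets are half-open
  intervals `[low, low + 0.02)` anchored at the low end of `ppm_range`.
  This tiles the axis without overlap and makes the layout independent of
  the data.
* **Water-region handling.** A bucket that overlaps an exclusion region by
  any positive length is dropped entirely rather than truncated; partial
  buckets would carry area artifacts that depend on where the boundary
  happens to fall. With `ppm_range = c(0, 10)` this yields 500 candidate
  buckets minus 110 water buckets = 390 features; the slightly wider
  default range (−0.5 to 10 ppm, chosen to cover the standard ^1^H
  metabolite window including TMSP) yields 415.
* **Integration rule.** Bucket values and metabolite signal areas are
  trapezoidal integrals on the native (possibly irregular) ppm grid, with
  linear interpolation at window edges so that contiguous windows add
  exactly; bucket sums therefore reproduce the whole-range integral when
  nothing is excluded.
* **No centering or variance scaling in preprocessing.** Only total-area
  normalization is applied to the data matrix; centering (and optional
  scaling) belong to the model-fitting stage.

## The synthetic cohort generator

No spectra or feature tables from the original cohort are redistributable,
so the package carries the published per-group means and standard
deviations of 31 salivary metabolites (`salivary_metabolite_panel()`, in
arbitrary integrated-signal-area units) and generates cohorts from them.
For subject $i$ and metabolite $m$ the paired samples share a latent
bivariate-normal draw with correlation $\rho$:

$$ z_{iB}, z_{iAT} \sim N(0, 1), \quad \mathrm{cor}(z_{iB}, z_{iAT}) = \rho, $$
$$ x_{igm} = \max\!\big(\mu_{gm}^{(\kappa)} + \sigma_{gm}\, z_{ig},\ 0\big), $$

with healthy samples drawn independently. The effect multiplier $\kappa$
moves every group mean about the metabolite's grand mean,
$\mu^{(\kappa)}_g = \bar\mu + \kappa(\mu_g - \bar\mu)$, so $\kappa = 1$
reproduces the published moments and $\kappa = 2$ gives a strongly
separated regime used to probe the classifiers' ceiling. Choices:

* **Marginal family.** Salivary metabolite concentrations are not normal;
  the default is a zero-truncated (clipped) normal, which keeps the
  published moments nearly intact wherever $\mu > 2\sigma$, and a
  moment-matched lognormal (paired through a Gaussian copula) is available
  via `distribution = "lognormal_matched"`.
* **Within-subject correlation.** $\rho$ is not estimable from published
  summaries; the default 0.8 reflects the strong subject-level component
  typical of repeated saliva sampling, and the sensible sensitivity range
  is roughly 0.5–0.95.
* **Null cohorts.** `generate_null_dataset()` replaces all three group
  means with the grand mean *and* all three SDs with the pooled SD. The
  second step goes beyond "no mean difference": without it the groups are
  not exchangeable and rank tests or classifiers can legitimately detect
  scale differences, which would defeat the generator's purpose as a
  type-I-error harness.
* **Spectrum rendering.** `render_spectrum()` draws each metabolite as one
  or two Lorentzian singlets at typical ^1^H shifts
  (`default_peak_library()`), adds a TMSP line at 0.00 ppm, one global
  per-sample shift jitter, and white noise. The peak library is
  illustrative: J-coupling multiplets, pH-dependent shift drift and matrix
  effects are deliberately out of scope, so passing end-to-end tests show
  that the *pipeline plumbing* is correct, not that real saliva spectra
  are this simple.

## Latent-variable models

All three models are fitted by NIPALS with deflation of both blocks,
convergence tolerance $10^{-10}$ on the weight vector and at most 500
iterations per component. Columns of the data matrix are mean-centred
inside the fit; class membership is encoded as a single ±1 column for two
classes and a 0/1 indicator matrix for three. Each weight vector's
largest-magnitude element is made positive, which fixes the sign
indeterminacy of PLS and makes fits bit-reproducible (a consequence worth
knowing: relabelling the two classes returns the *same* scores with
swapped predictions, rather than negated scores).

**Multilevel PLS.** The paired contrast first splits each sample as
$x = \bar{x} + (\bar{x}_i - \bar{x}) + (x - \bar{x}_i)$ (grand mean,
between-subject, within-subject). For a two-sample pair the within rows
are $\pm d_i/2$, with $d_i$ the subject's B−AT difference, so fitting
PLS-DA on the within part isolates the treatment effect from
between-subject variation. The between part is retained for diagnostics
only; held-out subjects are decomposed with their own pair mean before
prediction, so a subject's two samples never straddle a CV split.

**OPLS-DA.** Before fitting predictive components, variation orthogonal to
the class encoding is removed: each orthogonal weight is the current first
X-loading projected off the column space of $X^\top Y$ and renormalised,
which makes every orthogonal score *exactly* uncorrelated with every
encoding column; the data are deflated and the step repeated. With zero
orthogonal components the model coincides with plain PLS-DA. Defaults are
2 predictive components (both models) and 1 orthogonal component,
matching a two-dimensional score plot for the three-group comparison;
multi-class decisions take the class of the maximal predicted encoding,
ties breaking to the first class level.

**Variance scaling.** By default only mean-centering is applied, because
bucket tables arrive total-area normalized and hence on a common scale.
For *metabolite-concentration* tables the features span four orders of
magnitude (acetate ≈ 10^5^ area units, hypoxanthine ≈ 30), and unscaled
PLS is dominated by the largest-area metabolites; unit-variance scaling is
the field-standard treatment for such tables and is exposed everywhere as
`scale = TRUE` (training-set SDs are stored in the model and reapplied to
new samples; constant training columns are left unscaled). The synthetic
accuracy analyses in `scripts/acceptance.R` use this option for exactly
that reason.

## Validation

`monte_carlo_cv()` repeats a stratified random split `n_runs` times
(default 100), holding out one third of the *subjects* per stratum —
paired subjects form one stratum, healthy singletons another — refits the
model on the remainder, predicts the held-out samples, and pools the
confusion matrix; the reported accuracy is trace over total of the pooled
matrix. Draws that leave a class out of training, or a training set too
small for the requested components (possible under permuted labels), are
re-drawn up to 10 times. Run $r$ uses the seed substream `seed + r`, so
results do not depend on execution order. Singleton strata, which can
arise when labels are permuted, are pooled before drawing so the
per-stratum ceiling cannot inflate the test fraction.

`permutation_test()` uses cross-validated accuracy as its statistic and
the add-one estimator $p = (b + 1)/(N + 1)$ with ties counted in $b$, so
$p$ is never zero and its floor with $N = 100$ permutations is
$1/101 = 0.0099$. For paired models each permutation independently swaps
(or not) the B/AT labels within each subject, preserving the pairing;
otherwise the group labels are fully shuffled. Two degenerate draws are
excluded and redrawn: the identity relabelling, and — for paired
two-class models — the total inversion, under which the model is
invariant and therefore reproduces the observed accuracy by symmetry
rather than by chance. The exhaustive-enumeration oracle in the test
suite enumerates the same non-degenerate pattern space.

## Univariate layer

`build_metabolite_stats_table()` reproduces the three-family comparison
table: per metabolite, group means and SDs, Kruskal–Wallis across
B/AT/HI, paired Wilcoxon signed-rank B vs AT, Mann–Whitney HI vs AT, with
Benjamini–Hochberg adjustment applied separately within each family
(m = number of metabolites). Conventions: all tests two-sided;
zero-difference pairs are dropped from the signed-rank test (their count
is reported) rather than ranked; exact p-values by enumeration are used
when the sample is tie-free and small (signed-rank: effective n ≤ 25;
Mann–Whitney: n₁n₂ ≤ 400 — both satisfied at the study's n of 11–12),
otherwise mid-rank normal approximations with tie-variance correction and
no continuity correction. The two-group Kruskal–Wallis statistic then
equals the squared tie-corrected normal U statistic, a consistency the
tests verify. Note that the BH map is *not* idempotent — re-adjusting
already-adjusted values inflates them — so the table stores raw and
adjusted columns side by side and the adjusted columns are recomputable
from the raw ones.

## Numerical and testing choices

* Degenerate inputs have defined behaviour: all-identical groups give
  H = 0, p = 1; all-zero paired differences, zero-variance t-tests and
  empty reference windows are errors that name the offending entity.
* The test suite sizes its simulations to stay fast while keeping
  statistical assertions meaningful: moment/correlation recovery at
  500–800 subjects, null rejection rates over 40–200 replicates against
  binomial 99% bands, permutation super-uniformity over 100 small null
  cohorts, and exhaustive oracles at 4 subjects (16 swap patterns) and
  pooled n = 12 (924 labelings).
* `run_pipeline()` persists every intermediate (features, metadata,
  scores, validation JSON, statistics TSV) and a `report.json` that
  regenerates byte-identically under the same master seed.

## Known limitations

* The renderer's peak library is a caricature of real multiplet
  structure; it validates plumbing, not spectral realism.
* The clipped-normal marginal biases moments upward for metabolites with
  $\sigma \gtrsim \mu$ (several panel rows), which is documented and
  bounded in the tests rather than corrected.
* Multi-class OPLS-DA mechanics (dummy encoding, class-of-maximum rule)
  follow common practice; other decision rules (Mahalanobis on scores,
  PLS-DA posterior probabilities) are not implemented.
* Q²/R² diagnostics, VIP rankings, S-plots and nested component-number
  selection are out of scope; component counts are configuration.
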