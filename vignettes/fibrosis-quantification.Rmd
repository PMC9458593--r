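---
title: "Quantifying interstitial fibrosis on Sirius red sections: methods and design"
author: "sriaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interstitial fibrosis on Sirius red sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sriaquant)
```

## The measurement problem

Kidneys offered for transplantation are often biopsied at implantation, and
the biopsy is read intra-operatively on a frozen section. Interstitial
fibrosis (IF) — collagenous expansion of the cortical interstitium — is a
key element of that reading, but frozen sections are a poor substrate for
it: stain contrast is reduced, the interstitial matrix appears broader, and
ice-crystal artefacts punch holes into the tissue. The reference morphology
only becomes available later, after formalin fixation and paraffin
embedding (FFPE) of the same tissue.

`sriaquant` implements a computer-assisted version of this assessment. On a
Sirius red-stained section image it measures the **Sirius red-stained
interstitial area (SRIA)**: the stained pixel count as a percentage of the
analysed cortical area, after excluding glomeruli, prominent vessels, folds
and artefacts. Applied to frozen/paraffin pairs of the same biopsy, the
package quantifies the frozen-section inflation of the interstitial area,
translates the continuous percentage into the semi-quantitative Remuzzi IF
grade, and uses the paraffin SRIA as a predictor of delayed graft function
(DGF) in a logistic model.

Since no patient images travel with the package, a synthetic-histology
module generates paired cortex images with pixel-exact ground truth, plus
synthetic clinical cohorts, so every stage is testable end to end.

## SRIA quantification

### Colour separation

`collagen_channel()` turns the RGB raster into a collagen intensity in
[0, 1]. The default, `"deconvolution"`, is two-stain optical-density
unmixing in the Ruifrok–Johnston style: each pixel's optical density
`-log10((I+1)/256)` is decomposed in a basis formed by the unit OD vectors
of Sirius red (reference colour RGB 185/40/55) and the picric-yellow
counter-stain (230/205/110) plus their orthogonal complement; the collagen
concentration is rescaled so a pure collagen pixel maps to 1 and unstained
white to 0. `"hue_saturation"` is the alternative: HSV saturation weighted
by the circular closeness of the hue to the red pole, which separates red
collagen from yellow background without an OD model. Both methods are
deterministic and preserve image dimensions; on synthetic sections both
rank collagen above background essentially perfectly (AUC > 0.99 is a test
invariant).

### Thresholding

The original workflow tuned an intensity threshold visually for each
section pair; that step is not reproducible, so the package replaces it
with Otsu's criterion as the automatic default and keeps manual overrides.
`select_threshold()` maximises the between-class variance on a 256-bin
histogram of the masked channel values; when several splits tie (an empty
histogram gap between classes), the plateau midpoint is returned, which is
also what "bisecting" two well-separated classes yields. Because the
published procedure thresholded "each section pair individually" — which is
ambiguous between per-pair and per-section — `quantify_pair()` defaults to
one pooled Otsu threshold over the masked intensities of both members
(`pooled = TRUE`) and offers per-section Otsu and fixed values as
overrides.

### Counting, exclusions, inclusion rule

`compute_sria()` counts pixels with `channel >= threshold` inside the
cortex-minus-exclusions mask. Polygon rasterisation uses the pixel-centre
rule in 0-based coordinates (x right, y down): a pixel belongs to a region
iff its centre lies inside the polygon (even-odd rule). This convention is
stated so that GeoJSON annotations are portable across implementations.
The analysed area is `cortex_px * (µm/px)^2 / 10^6` mm²;
`check_pair_inclusion()` drops a pair when either member offers less than
1 mm² of analysed cortex, boundary inclusive. "Overlaying area" is read as
the analysed cortical area of each member; spatial registration of
adjacent sections is out of scope.

### Remuzzi translation

`remuzzi_if_grade()` bins the percentage into grades 0–3 with cutpoints
(default 5, 20, 50 %): grade 0 strictly below the first cutpoint, each
subsequent grade from its cutpoint upward. The defaults are package
defaults, not values taken from any published mapping — the percentage
boundaries behind the semi-quantitative grade are not standardised — and
they are configurable everywhere they are used. A literal grade 0 ("absent")
essentially never occurs for a computer, which measures fractions of a
percent where an observer reports none; hence the first cutpoint, not zero,
defines grade 0.

## Agreement statistics

* `bland_altman()` — differences are frozen − paraffin; limits of agreement
  are `mean ± 1.96·SD` with the sample SD and the literal 1.96 (not a
  t-quantile), so the structural identities
  `loa_low + loa_high = 2·mean_diff` and
  `loa_high − loa_low = 2·1.96·sd_diff` hold to machine precision.
  Proportional bias is tested by OLS regression of the difference on the
  pair mean, the standard Bland–Altman practice. One caveat is worth
  stating: when the artefact carries independent per-pair variance
  comparable to the between-subject spread, this regression has a positive
  *structural* slope (≈ var(d)/2 divided by the variance of the pair
  means) even though the artefact is additive; the slope converges to zero
  only when the artefact is (nearly) constant relative to the subject
  spread, and the test suite exercises the invariant in that regime.
* `icc_consistency_average()` — the two-way consistency, average-measures
  intraclass correlation for two raters: `ICC = 1 − 1/F` with
  `F = MS_subjects/MS_error` on (n−1, n−1) degrees of freedom, and the
  F-quantile confidence interval `[1 − F*/F, 1 − 1/(F·F*)]` with
  `F* = qf(1 − α/2, n−1, n−1)`. `icc_from_f()` applies the same identities
  to a printed F value without raw data; the published pair
  F(72,72) = 3.212 → ICC 0.69 (CI 0.504–0.805) reproduces exactly, which
  is an acceptance test. Consistency ignores a constant rater offset, so a
  pure additive artefact leaves ICC = 1.
* `weighted_kappa()` — quadratic-weighted Cohen's kappa,
  `1 − Σw·O / Σw·E`, disagreement weights `((i−j)/(K−1))²`; on two
  categories it coincides with unweighted kappa.
* `subgroup_difference()` — compares frozen−paraffin differences between
  two groups; a Shapiro–Wilk gate (α = 0.05, both groups) selects the
  unpaired t-test, otherwise a Mann–Whitney U (exact for combined n ≤ 12
  without ties, normal approximation with tie and continuity correction
  otherwise). The gate itself is a package choice: the source procedure
  states the test alternatives but not the decision rule.
* `relevant_difference_flags()` — flags a pair whose SRIA values differ by
  ≥ 10 percentage points, or whose IF grades differ at all.

## Outcome modelling

`fit_logistic()` is maximum likelihood via IRLS (`stats::glm`, binomial,
relative convergence 1e−8, ≤ 100 iterations) behind a stable surface:
per-term Wald z p-values, odds ratios `exp(β)` and 95% CIs
`exp(β ± 1.96·se)` — matching the arithmetic of a published OR/CI table —
plus VIFs on the design matrix excluding the intercept. Boundary fitted
probabilities are reported as suspected (quasi-)complete separation with
`converged = FALSE`. `univariate_screen()` fits one single-covariate model
per candidate and retains those with Wald p below `alpha_in` (default 0.1,
the entry rule for the multivariate model); `dgf_model()` chains the screen
into the multivariate fit, degenerating to an intercept-only model when
nothing is retained. Continuous covariates enter untransformed per unit
(per %, per hour, per year); no multiplicity correction is applied across
the screens, since none is described for the original analysis. With
29 events in 71 patients the intercept-only model returns
`logit(29/42) ≈ −0.37`, which the tests pin against the published
intercept.

## The synthetic world

`simulate_section_pair()` emits one frozen/paraffin pair with ground truth:

* **Cortex**: an irregular smooth blob polygon (low-frequency radial
  harmonics) rasterised to a mask; glomeruli (circles, white Bowman space
  around a muted-red tuft) and vessels (red-walled ellipses with white
  lumina) are embedded and also emitted as exclusion annotations.
* **Collagen geometry**: a Gaussian random field (FFT-smoothed white noise,
  correlation length 10 µm by default) thresholded inside the analysed
  cortex at the order statistic that realises the target fraction exactly
  (to one pixel). The paraffin truth therefore equals the configured
  `true_fraction_pct` to well within ±0.5 pp.
* **Frozen artefact**: the paraffin collagen skeleton is morphologically
  dilated (8-neighbourhood, partial final ring subsampled at random) until
  the stained fraction is `true_fraction_pct + frozen_delta_pct` — an
  additive, not proportional, inflation, which is how the broadened
  interstitial matrix of frozen sections behaves; elliptical white
  ice-crystal holes (default 2 per mm² of cortex) are punched first, and
  all tissue colours are blended 20% toward the tissue mean to emulate the
  stain-contrast loss of unfixed tissue.
* **Colours**: collagen ≈ RGB(185, 40, 55), background picric yellow
  ≈ (230, 205, 110), lumina/holes white, ±10 uniform channel noise —
  chosen so both separation methods have signal without being trivial.
* **Geometry defaults**: 2048×2048 px at 1 µm/px ≈ 4.2 mm², so the 1 mm²
  inclusion rule is exercisable on realistic areas. The test-suite and
  acceptance runs use 1024 px at 2 µm/px (the same physical field) and
  768 px at 2 µm/px for the 30-pair run, purely to fit pure-R runtimes.

All randomness flows from the single config seed and the caller's RNG state
is restored, so identical config + seed is bit-reproducible.

`generate_cohort()` draws a clinical table whose DGF indicator follows
`logit(p) = α + ln(OR_SRIA)·SRIA_paraffin + ln(OR_CIT)·CIT`, with α
calibrated by root-finding so the mean event probability equals the target
prevalence (default 0.41, the published cohort's DGF rate). Defaults embed
OR 1.1 per percentage point of paraffin SRIA; covariate distributions are
centred on the published medians (donor age ≈ 69 y, CIT ≈ 17 h, paraffin
SRIA ≈ 32–33%) with invented spreads, and the frozen SRIA adds
N(7.8, 7.9²) pp of artefact — the mean is the published mean difference and
the SD is implied by the published limits of agreement
((23.4 + 7.57)/(2·1.96) ≈ 7.9). The pipeline's simulated section pairs
draw their per-pair artefact from the same distribution; the published
range (−7 to +29 pp) reports the artefact's spread but not its shape, so a
normal with those first two moments is the package's choice, exposed as
parameters rather than asserted.

What the generator does **not** emulate: photorealistic histology, nuclei
and tubular cytology, section thickness and staining chemistry, scanner
colour variation, or true serial-section registration offsets. A green
recovery test therefore establishes that the measurement pipeline is
correct on cleanly stained, well-annotated tissue with a known answer — not
that it is robust to every real-world staining artefact.

## Numerical choices and degenerate inputs

* Rasterisation: pixel-centre, even-odd, half-open edge rule at vertices.
* Otsu ties resolve to the plateau midpoint; constant masked intensities
  are an error directing the user to a fixed threshold.
* Inclusion boundary (exactly 1 mm²) is inclusive.
* Bland–Altman with zero variance of pair means flags the slope as
  undefined rather than fabricating one; a constant offset yields slope 0.
* Zero ANOVA error mean square yields ICC = 1 with a degenerate CI and a
  flag; a single rating category makes kappa undefined (error).
* Exact Mann–Whitney only without ties and combined n ≤ 12; otherwise the
  tie-corrected normal approximation.
* Exact collinearity reports infinite VIF rather than failing.
* The intercept calibration root-find brackets α in [−60, 60], ample for
  any realistic prevalence/covariate combination.

## Limitations

The package measures area fraction, assuming it proxies interstitial
volume; it does not correct for interstitial oedema (none was reported in
the motivating material), does not normalise stains across scanners, and
scores only the IF component — tubular atrophy, glomerulosclerosis and
vascular lesions, and the composite donor-suitability grade, are out of
scope. The Remuzzi cutpoints are configurable defaults, and conclusions
that depend on them (kappa, score matrices) should be read with the chosen
cutpoints in mind.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(output_dir = "run1", n_pairs = 10L,
                       width_px = 768L, height_px = 768L,
                       microns_per_pixel = 2, n_patients = 2000L, seed = 1L)
run <- run_pipeline(cfg)
run$agreement
run$dgf$multivariate
```

The run writes `pairs.csv`, `agreement.json`, `score_matrix.csv`,
`dgf_models.json`, a `run.log`, and a `manifest.json` whose seed,
parameters and artefact checksums fully determine the outputs; running the
same config twice yields identical artefacts, which is itself an
acceptance test.
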