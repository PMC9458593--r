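# sriaquant

Computer-assisted quantification of interstitial fibrosis in renal
implantation biopsies.

Donor kidneys are assessed intra-operatively on frozen sections, where
interstitial fibrosis (IF) — the strongest routinely scored predictor of
chronic graft injury — is notoriously hard to judge: unfixed tissue has low
stain contrast, the interstitial matrix looks artificially broadened, and
ice crystals punch holes into the section. `sriaquant` is for renal
pathologists and transplant researchers who want that assessment to be
quantitative and reproducible. It measures the **Sirius red-stained
interstitial area (SRIA)** of the cortex on a section image,

```
SRIA (%) = 100 · stained pixels / analysed cortical pixels,
```

with stained pixels classified by colour deconvolution (or HSV gating) plus
an Otsu threshold, inside an annotated cortical region from which
glomeruli, prominent vessels and folds are excluded. On frozen/paraffin
pairs of the same biopsy it quantifies the frozen-section artefact with
Bland–Altman limits of agreement (mean ± 1.96·SD, with an OLS test for
proportional bias), the two-way consistency average-measures intraclass
correlation (ICC = 1 − 1/F, F-quantile CI), and the quadratic-weighted
Cohen's kappa on Remuzzi IF grades; and it models delayed graft function
(DGF) with a univariate logistic screen (entry rule p < 0.1) feeding a
multivariate fit with Wald odds-ratio CIs and variance-inflation-factor
checks.

A synthetic-histology module replaces patient data: it generates paired
frozen/paraffin cortex images with pixel-exact ground truth (thresholded
Gaussian random-field collagen, additive dilation artefact, ice-crystal
holes, contrast loss) and synthetic clinical cohorts with a known embedded
DGF odds ratio, so the whole pipeline is testable offline.

## Worked example

```r
library(sriaquant)

# one synthetic frozen/paraffin pair: 32% true fibrosis, +7.8 pp artefact
cfg <- section_sim_config(width_px = 1024L, height_px = 1024L,
                          microns_per_pixel = 2,
                          true_fraction_pct = 32, frozen_delta_pct = 7.8,
                          seed = 7L)
pair <- simulate_section_pair(cfg, biopsy_id = "demo")
q <- check_pair_inclusion(quantify_pair(pair$frozen, pair$paraffin))
q
#> <srq_pair> demo: frozen 39.80% vs paraffin 32.00% (diff +7.80 pp), included
remuzzi_if_grade(c(q$frozen$fraction_pct, q$paraffin$fraction_pct))
#> [1] 2 2
```

The measured SRIA recovers the simulated truth (32%) and the configured
frozen inflation (+7.8 percentage points) exactly at this image scale; both
members map to Remuzzi IF grade 2 under the default 5/20/50% cutpoints.

```r
# reconstruct an average-measures consistency ICC from a reported F value
icc_from_f(3.212, 72, 72)
#> ICC (two-way consistency, average measures): 0.689, 95% CI [0.504, 0.805],
#>   F(72,72) = 3.212, p = 7.78e-07

# screen-then-fit DGF model on a synthetic cohort with embedded OR 1.1/pp
cohort <- generate_cohort(cohort_sim_config(n_patients = 2000L, seed = 1L))
dgf_model(cohort, c("sria_paraffin_pct", "cit_hours", "donor_age"))$multivariate
#> Logistic model for dgf (n = 2000): intercept = -4.47
#>               name odds_ratio          ci       p      vif
#>  sria_paraffin_pct      1.101 1.085-1.118 4.8e-36 1.000656
#>          cit_hours      1.050 1.034-1.065 8.2e-11 1.000656
```

The fitted odds ratio per percentage point of paraffin SRIA (1.101) matches
the generating value 1.1; `donor_age` is dropped by the p < 0.1 screen.

`run_pipeline(pipeline_config(...))` chains everything — simulate or read
images, quantify, apply the 1 mm² pair-inclusion rule, agreement
statistics, IF score matrix, DGF models — and writes machine-readable
artefacts plus a manifest whose seed and parameters fully determine every
output. A thin CLI over the same functions ships in
`inst/cli/sriaquant.R` (verbs: `simulate-pair`, `simulate-cohort`,
`quantify`, `pair`, `pair-stats`, `predict-dgf`, `run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline analysis from scratch: it runs the full
synthetic pipeline (10 section pairs at 768 px / 2 µm per pixel with the
+7.8 pp frozen artefact, and a 2000-patient cohort), prints the agreement
report and DGF models it computed, and writes the JSON report to `--out`.
All randomness derives from `--seed`.

## Further reading

The methods vignette (`vignettes/fibrosis-quantification.Rmd`) documents
the measurement model and its assumptions, the synthetic world and its
limits, every numerical convention (rasterisation rule, threshold
tie-breaks, inclusion boundaries, test gates), and the design decisions
taken where the underlying procedure was ambiguous.
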