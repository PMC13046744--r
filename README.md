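# rhythmage

Rest-activity rhythms from wrist accelerometry, Gompertz-based biological
age, and inflammation-mediated mortality risk — as one tested, seeded,
tidyverse-native R pipeline.

## What it does, and for whom

Minute-level wrist-accelerometer recordings (ENMO, in milli-g) carry a
readable signature of the behavioral circadian rhythm. `rhythmage` is for
epidemiologists and digital-biomarker researchers who want to go from such
recordings to three linked results:

1. **Rhythm features.** A per-subject feature vector: single-component
   cosinor parameters (MESOR *M*, amplitude *A*, acrophase, up-mesor,
   pseudo-F) from the linearized least-squares fit of
   *Y(t) = M + A·cos(2πt/τ + φ) + e(t)*; day-to-day coefficients of
   variation; nonparametric circadian metrics (interdaily stability IS,
   intradaily variability IV, relative amplitude (M10−L5)/(M10+L5));
   MVPA/sedentary time at the 100/40 mg cut-points and the intensity
   gradient; detrended-fluctuation (DFA) exponents on short (<2 h) and
   long (>2 h) scales; fPCA scores of the average 24-h profile; and
   simplified sleep metrics. Wear-time QC (≥72 h, full diurnal coverage)
   and the IS/IV percentile screen are included.
2. **CosinorAge.** Two sex-specific Gompertz proportional-hazards models —
   rhythm parameters + chronological age, and age alone — are fitted by
   maximum likelihood; biological age (BA) is the age at which the
   age-only model matches the full model's 5-year cumulative mortality
   hazard (closed form), and age acceleration is AA = BA − CA. The
   accelerated/decelerated label feeds an interpretable classifier (MRMR
   feature selection after Spearman-correlation pruning at |ρ| > 0.7;
   logistic/RF/SVM/tree/XGBoost backends; AUC, accuracy, MCC on a
   65/15/20 split) with in-house exact and permutation-sampling Shapley
   attributions.
3. **Inflammation and mediation.** Z-scored systemic immune-inflammation
   index (SII = platelets × neutrophils / lymphocytes) regressed on
   quartile-coded rhythm exposures with BH-FDR; joint-exposure
   (interaction) models; and weighting-based natural-effects mediation of
   all-cause mortality through SII, reporting total, natural direct and
   natural indirect hazard ratios with percentile-bootstrap intervals and
   the mediated proportion ln(NIE)/ln(TE), sex-stratified.

Cohort-scale accelerometry is access-restricted, so the package ships a
seeded synthetic-cohort generator (`simulate_cohort()`) with known ground
truth — cosinor-structured activity with realistic day-to-day variability,
covariates, blood counts satisfying the SII identity exactly, and Gompertz
survival — which makes every stage testable by parameter recovery.

## Worked example

```r
library(rhythmage)

co <- simulate_cohort(generator_config(n_subjects = 4, seed = 11))
co
#> <rar_cohort> 4 subjects, 7 days, seed 11
#>   deaths: 0 (0.0%)

f <- fit_cosinor(co$epochs[[1]])
f
#> <cosinor_fit> MESOR 36.26 mg, amplitude 37.37 mg, acrophase 13.01 h, period 24.00 h, pseudo-F 3984.9

nonparametric_metrics(co$epochs[[1]])
#>   interdaily_stability intradaily_variability relative_amplitude   m10    l5
#> 1                0.741                  0.337              0.946 64.90  1.81
```

The subject's fitted amplitude (37.4 mg) is half the peak-to-trough extent
of the daily rhythm; the acrophase (13.0 h) says activity peaks shortly
after 1 pm; IS of 0.74 means about three quarters of the hour-to-hour
variance is explained by a stable 24-h profile; RA near 0.95 reflects the
deep day-night contrast of a clean rhythm. `autoplot(f)` overlays the
fitted cosine on the hourly profile.

The whole chain runs from one seeded config and writes CSV/JSON artifacts
plus an MD5 manifest (re-running the same config reproduces identical
hashes):

```r
m <- run_pipeline(pipeline_config(n_subjects = 2000, seed = 1,
                                  out_dir = "demo_run"))
#> [rhythmage] simulate: 2000 subjects, 105 deaths (5.2%)
#> [rhythmage] features: 2000 in, 1878 retained after regularity screen
#> [rhythmage] cosinorage: 1878 subjects, 37.5% accelerated
#> [rhythmage] ml (xgboost): AUC 0.984, MCC 0.852; top attribution: cosinor_amplitude
#> [rhythmage] assoc: 10 main-effect rows, 9 interaction rows
#> [rhythmage] mediate: 18 rows (B=200)
#> [rhythmage] report: 15 descriptive rows, 23 strata rows
```

On this synthetic cohort the classifier separates accelerated from
decelerated aging almost entirely from the rhythm-amplitude family (as the
generator's mortality truth dictates), insufficient MVPA raises SII by
~0.31 SD in males with no effect in females, and the male mediated
proportions (up to ~20%) exceed the female ones — the structural pattern
the method is built to expose.

See the methods vignette (`vignettes/rhythmage-methods.Rmd`) for the
models, parameter defaults, numerical conventions, and the generator's
calibration and limitations.

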