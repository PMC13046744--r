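---
title: "Rest-activity rhythms, biological age, and inflammation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest-activity rhythms, biological age, and inflammation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rhythmage)
```

# The problem this package addresses

Wrist accelerometry measures behavioral rest-activity rhythmicity at
population scale. Three claims motivate the pipeline implemented here:
(1) features of the daily rest-activity rhythm — its amplitude, timing,
regularity, and the volume of moderate-to-vigorous physical activity
(MVPA) — predict an accelerated biological age; (2) weaker and less stable
rhythms are associated with higher systemic inflammation, measured by the
systemic immune-inflammation index (SII = platelets × neutrophils /
lymphocytes); and (3) part of the mortality risk carried by disrupted
rhythms runs through that inflammation, quantifiable by counterfactual
mediation. `rhythmage` implements every stage — feature extraction,
Gompertz-based biological age, interpretable classification, inflammation
regressions, and natural-effects survival mediation — together with a
seeded synthetic-cohort generator with known ground truth, so the whole
chain is testable without access to restricted cohort data.

# Rhythm features

## The cosinor model

Activity is modeled as $Y(t) = M + A\cos(2\pi (t - t_{peak})/\tau) + e(t)$:
$M$ (MESOR) is the rhythm-adjusted mean in mg, $A$ the amplitude (half the
peak-to-trough extent), $t_{peak}$ the acrophase (clock time of peak
activity), $\tau$ the period. Expanding the cosine turns the nonlinear
problem into ordinary least squares on $\{1, \cos\omega t, \sin\omega t\}$;
amplitude and acrophase are recovered from the two linear coefficients.
The acrophase is reported as clock hours in $[0, 24)$; the up-mesor (the
rest-to-active transition) is the upward MESOR crossing of the fitted
cosine, a quarter period before the acrophase — consistent with the ~6 h
gap between typical adult up-mesor (~7.8 h) and acrophase (~13.9 h).
Goodness of rhythm fit is the pseudo-F statistic,
$(\mathrm{MSS}/2)/(\mathrm{RSS}/(n-3))$.

When `period_search = TRUE` the best-fitting period in [23, 25] h is found
by a 0.05 h RSS grid followed by golden-section refinement. A constant
series yields amplitude 0, pseudo-F 0, and an explicit undefined-acrophase
flag rather than an arbitrary angle.

Day-to-day variability is quantified by fitting each midnight-to-midnight
day separately at a fixed 24 h period and reporting the coefficient of
variation (population SD over mean, in percent) of the day-level
estimates. Circular quantities (acrophase, up-mesor) are unwrapped —
shifted by multiples of 24 h to within 12 h of their median — before the
SD is taken; a fully circular SD (resultant-length based) is a documented
alternative we did not adopt because nightly timing jitter in adults is
far from the wrap-around regime. Days with under 20 h of wear are dropped;
fewer than 3 valid days yields NA with a warning.

## Nonparametric metrics

Interdaily stability (IS) and intradaily variability (IV) use the standard
hourly-binned forms with p = 24 hour-of-day bins. IS is the fraction of
hourly variance explained by the mean 24-h profile (computed with
count-weighted between-group sums so it stays in [0, 1] even with
incomplete days); IV is the normalized mean squared successive difference
of the hourly series — 2(1 − cos(2π/24)) ≈ 0.068 for a pure daily
sinusoid, ≈ 2 for white noise. M10 and L5 are the most and least active
10-h and 5-h circular rolling means of the average 24-h profile at epoch
resolution, and relative amplitude is RA = (M10 − L5)/(M10 + L5). The
cohort inclusion screen retains subjects with IS at or above the sample
5th percentile and IV at or below the 95th (linear-interpolation
percentiles); below 20 subjects the screen is skipped with a warning.

## Physical activity, DFA, fPCA, sleep

MVPA and sedentary time use the validated 100 mg and 40 mg minute-level
ENMO cut-points; "insufficient MVPA" is under 150 weekly minutes, with
exactly 150 counting as sufficient. The intensity gradient is the slope of
ln(minutes in bin) on ln(bin midpoint) over 25-mg bins spanning 0-4000 mg
with empty bins dropped — the conventional formulation.

DFA integrates the mean-centered minute series, splits the profile into
non-overlapping windows (log-spaced, 4 min to 2 h for the short exponent,
2 h to 27 h for the long one, capped at a quarter of the series), removes
a linear trend per window, and regresses log fluctuation on log window
size. White noise gives α ≈ 0.5, 1/f structure α ≈ 1, a random walk
α ≈ 1.5.

fPCA decomposes the subjects × 1440 matrix of average 24-h profiles
(column-centered) by `stats::prcomp`. The first component tracks overall
activity level and is strongly correlated with cosinor amplitude, so the
downstream feature vector keeps only components 2-4. Signs are fixed by
making each component's largest-magnitude loading positive, so scores are
reproducible across runs and platforms.

The sleep detector is deliberately simple (the research-grade algorithms
require raw sub-second data): per noon-to-noon window, the main sleep
period is the longest block whose 5-minute rolling ENMO stays below 10 mg,
merging sub-threshold runs separated by at most 20 minutes. Onset is
reported as hours since the midnight starting the window's calendar day,
so post-midnight onsets exceed 24. Efficiency is the fraction of raw
epochs below threshold inside the window. All three thresholds are
arguments. Nightly duration SD above 90 minutes flags irregular sleep.

# CosinorAge: Gompertz biological age

Two Gompertz proportional-hazards models are fitted per sex: a full model
with MESOR, amplitude, acrophase and chronological age, and an age-only
model. The censored log-likelihood
$\ell = \sum_i \delta_i(\ln b + a t_i + \eta_i) - \sum_i (b/a)(e^{a t_i}-1)e^{\eta_i}$
is maximized in the unconstrained parameterization $(\ln b, a, \beta)$ by
BFGS with analytic gradients and Newton polishing to a gradient
infinity-norm below 1e-8; covariates are standardized internally and
coefficients returned on the original scale. $|a| < 10^{-8}$ switches to
series expansions of $(e^{at}-1)/a$, so the exponential model is the
smooth $a = 0$ limit rather than a singular point.

Biological age (BA) equates the five-year cumulative mortality hazards of
the two models and solves for age; because the age-only cumulative hazard
is log-linear in age, the solution is closed-form. Age acceleration is
AA = BA − CA, with AA > 0 labeled accelerated (the horizon is an argument;
5 years is the default). Whether the two models should share the shape
parameter is not determined by the method itself; both modes are provided
(`shape =` fixes it), with free shapes as the default since nothing forces
the rhythm-adjusted and marginal age gradients to coincide.

# Classification and attribution

Features are standardized, pruned by pairwise Spearman correlation above
0.7 (greedy, highest-|ρ| pairs first, dropping the member with the lower
mutual information with the label; the literal "keep only correlated
features" reading of that rule is available behind
`reading = "literal_keep"` but is not the default), then ranked by MRMR
with the greedy MID criterion $I(f;y) - |S|^{-1}\sum_{s \in S} I(f;s)$.
Mutual information uses the plug-in estimator on 8 equal-frequency bins —
a documented dialect; MRMR rankings are comparable only within one MI
convention. All ties break by feature name for reproducibility.

The 65/15/20 train/validation/test split is label-stratified, seeded, and
exact (largest-remainder apportionment). Hyperparameters are chosen on the
validation split by AUC; the chosen configuration is retrained on the
combined 80% and evaluated once on the untouched test split with AUC (the
rank/Wilcoxon estimator), accuracy, and the Matthews correlation
coefficient at a 0.5 cutoff. Five backends are supported (logistic
regression, random forest, SVM, decision tree, gradient boosting); the
built-in grids are small on purpose and can be replaced via `hyper_grid`.

Shapley attributions are computed in-house. The coalition value marginalizes
out-of-coalition features over a background sample. Exact mode enumerates
all $2^p$ coalitions (capped at p = 12); sampling mode is the permutation
estimator with per-feature Monte Carlo standard errors. Both satisfy the
efficiency axiom exactly (the permutation estimator telescopes), which the
tests assert to 1e-8. The global ranking is by mean |attribution|, with a
direction given by the sign of the feature-attribution correlation.

# Inflammation associations

SII is z-scored (sample SD), so coefficients are in SD units. Exposures
are quartile groups cut at linear-interpolation sample percentiles with
ties going to the lower group; Q4 (high amplitude / good regularity) is
the reference and the trend code runs 0 (Q4) to 3 (Q1), so positive trend
coefficients mean "more adverse quartile, higher inflammation". Models are
Gaussian identity-link fits by least squares (the outcome is z-scored and
no other link is implied), complete cases only, with Wald 95% intervals.
Amplitude and stability models additionally adjust for MVPA; MVPA models
(sex-stratified) adjust for interdaily stability. Joint-exposure models
cross two binary adverse exposures into a four-level factor referenced at
the doubly favorable cell, with the reduced covariate set used for
convergence. BH-FDR is applied within the main-effects family. Covariates
constant within a (sub)sample are dropped rather than allowed to break the
factor expansion.

# Mediation

The natural-effects estimator is weighting-based: each subject is
duplicated with a hypothetical exposure level $x^*$, weighted by the
Gaussian mediator-model density ratio $f(M \mid x^*, C)/f(M \mid X, C)$,
and a proportional-hazards model (via `survival::coxph`) is fitted on the
expanded weighted data with terms $(x, x^*, C)$. NDE = exp(coef on $x$),
NIE = exp(coef on $x^*$), TE = NDE × NIE, so the log-scale decomposition
is exact by construction; the proportion mediated is
ln(NIE)/ln(TE). A weighting (rather than imputation) variant was chosen
because it composes directly with a survival outcome — no counterfactual
outcome needs to be imputed on the hazard scale — and validation is by
simulation: null-mediation generators concentrate NIE at 1, full-mediation
generators concentrate NDE at 1, and percentile-bootstrap coverage of
log-NDE sits at the nominal level in the test suite. A parametric Gompertz engine (weighted maximum likelihood via the same
fitter used for CosinorAge) is available for tiny constructed examples
where the partial likelihood degenerates. Weights can be
winsorized at a quantile (`truncate_weights`, off by default; a warning
fires when max/min exceeds 1e3). Confidence intervals are percentile
bootstrap over subjects, seeded per replicate, with failed replicates
dropped and counted (more than 10% failing is an error). Exposure
dichotomizations follow the quartile framing: lowest amplitude quartile,
lowest IS quartile, and the 150 min/week MVPA rule.

# The synthetic cohort generator

The generator emulates the structure of a 7-day minute-ENMO cohort of
middle-aged adults: a subject-level cosinor (lognormal amplitude, normal
acrophase near 13.9 h, MESOR proportional to amplitude), lognormal
day-to-day amplitude multipliers and Gaussian acrophase jitter, an 8-h
damped rest window centered on the cosine trough, episodic MVPA bouts near
the acrophase, and 1/f ("pink") Gaussian noise truncated at zero. Pink
rather than white noise is a deliberate choice: minute-level human
activity shows short-scale DFA exponents near 1, which white noise (α =
0.5) cannot reproduce. The sustained circadian baseline is capped at 75 mg
so that MVPA-range minutes come from bouts and noise spikes, as in real
wrist data, rather than from hours of elevated smooth baseline.

Defaults were calibrated once against published descriptive anchors for
this population: median fitted amplitude ~40 mg (within the 34-56
interquartile band), median acrophase 13.9 h, roughly half the cohort
under 150 weekly MVPA minutes, short-scale DFA near 1, and a 3-5% death
rate over 8 years under the Gompertz truth (shape 0.09/y). SII is linear
in ground-truth behavior (lower amplitude, fragmentation, and — in males —
insufficient MVPA raise it) plus Gaussian noise, floored at a small
positive value; platelet and lymphocyte counts are drawn at typical adult
values and the neutrophil count is solved from the SII identity, which
therefore holds exactly row-wise. Survival times come from the inverse-CDF
of the Gompertz survival function with administrative censoring at 8
years. Every draw descends from per-quantity and per-subject seed streams,
so cohorts are byte-reproducible and individual subjects do not change
when the cohort is subsetted.

Two aspects of real data the generator does not emulate, and which passing
tests therefore do not certify: day-level amplitude variability is
compressed by the baseline cap (realized day-level amplitude CV ~20-30%
versus ~60% in adults — fragmenting a smooth baseline enough to reproduce
both that CV and realistic MVPA simultaneously would require a bout-level
activity model outside this scope), and there is no device noise spectrum,
non-wear structure, or postural artifact. Parameter-recovery results on
synthetic cohorts demonstrate estimator correctness, not robustness to
those artifacts.

# Numerical conventions and degenerate inputs

Percentiles are always type-7 (linear interpolation). CVs use the
population SD (divisor n). Ties in selection and pruning break by name;
quartile boundary ties go to the lower group. Gompertz convergence is a
gradient infinity-norm below 1e-8 (error if not reached after Newton
polishing); |a| below 1e-8 uses the exponential-limit series. Constant
activity series yield explicit NA/flagged outputs (undefined acrophase,
undefined IS/IV/DFA) rather than numerical noise. Empty joint-exposure
cells, zero-variance outcomes, single-class labels, rank-deficient
designs, and event-free exposure arms raise informative errors.

# Problem sizes used in the checks

The packaged tests and the acceptance script run, by choice, at sizes
where Monte Carlo error is small relative to the tolerances being
asserted: cosinor recovery over 100 seeded noisy series; Gompertz recovery
on cohorts of 5000 over 20 seeds; GLM coverage at n = 2000 over 100
replicates; mediation nulls at n = 2000 over 50 seeds with bootstrap
coverage at 200 replicates of B = 200; and an end-to-end demonstration
cohort of n = 2000 with B = 200 bootstrap mediation. Larger sizes change
none of the logic.

# Known limitations

Single-component cosinor only (no anti-logistic extended variant); the
simplified sleep detector is threshold-based and not validated against
polysomnography; mediation assumes a correctly specified Gaussian mediator
model, no exposure-mediator interaction, and no unmeasured
exposure-mediator-outcome confounding; CosinorAge coefficients shipped by
a user (rather than refitted) are applied as-is, with no transfer
calibration; the generator's realism limits are described above.
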