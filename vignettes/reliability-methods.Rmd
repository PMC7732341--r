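---
title: "Reliability of single hormone measurements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability of single hormone measurements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormrel)
```

## Scope

`hormrel` asks a narrow, consequential question about peripheral hormone
measurements: is one baseline sample a stable characteristic of the
individual? It answers with two complementary reliability metrics, then
turns the estimates into design guidance — how many samples to average, and
how large a correlation study must be once measurement unreliability has
attenuated the effect. This vignette records the models, the assumptions
behind them, and the numerical decisions taken where the methodology
admitted more than one defensible choice.

## The measurement model

All analyses start from a long-format table (`sample_table`): one row per
subject × visit × fluid × time-point × treatment, concentrations in pg/ml.
Two invariants are enforced at construction: concentrations are positive or
missing (a natural-log transform must exist), and the five-field key is
unique. Complete-case extraction (`to_wide`) yields the n × k
subjects-by-occasions matrix the estimators need; subjects missing any
requested occasion are dropped and reported, never imputed. Imputation is
deliberately out of scope — the downstream variance decomposition assumes
observed, not reconstructed, within-subject spread.

Concentrations are right-skewed and bounded below by zero, so inferential
statistics operate on natural-log concentrations. The within-subject CV is
the one exception: a percent coefficient of variation is only meaningful on
the raw scale, and typical hormone CVs (tens of percent) are raw-scale
magnitudes. The reliability fit therefore uses log values for the ICC and
raw values for the CV; both scales are exposed via `icc_scale` should a user
want otherwise. Natural log (not log10) is used throughout; the choice
cancels from the ICC, which is scale-invariant within a monotone linear
family, but matters for reported log-scale variances.

## Outlier screening

Screening uses the boxplot labelling rule: a value is an outlier if it lies
more than `g` = 1.5 interquartile ranges outside the quartiles. Quartiles
are computed by linear interpolation of order statistics (`quantile`
type 7, the default of mainstream statistical software); the convention is
configurable because published analyses rarely state one, and near small-n
quartile boundaries the flag set can differ between conventions. The rule is
applied within each fluid × time-point × treatment stratum, since treatment
shifts would otherwise masquerade as outliers; strata with fewer than four
observed values are left unscreened. Screening defaults to raw
concentrations, with `on_log` to screen log values instead — the field's
reports are ambiguous on this point, and the choice is surfaced rather than
hidden. A constant stratum (zero IQR) flags nothing.

## Relative reliability: the intraclass correlation

The two-way layout decomposes the complete matrix into subject (rows),
occasion (columns) and residual mean squares. The reported coefficient is
the single-measures, absolute-agreement form

$$ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},$$

which charges systematic occasion shifts against reliability — appropriate
when the question is whether the *same number* would be obtained on another
day, not merely the same ranking. The consistency form
(`icc_consistency`) is provided for comparison; absolute agreement never
exceeds it when occasion variance is at least residual variance and the
subject variance is positive.

Three numerical decisions:

- **F-test.** `F = MS_R/MS_E` on `(n−1, (n−1)(k−1))` df, with a one-sided
  p-value for H0: ICC = 0 — the conventional direction for a reliability
  null.
- **Confidence interval.** The McGraw–Wong F-based construction for the
  absolute-agreement single-rater coefficient, with the Satterthwaite-style
  df for the occasion term. The two-way "mixed" and "random" readings give
  the same point estimate here; only the population interpretation of the
  interval differs, which documentation notes rather than resolves.
- **No truncation.** Negative estimates (possible when subject variance is
  small) are reported as computed; truncating at zero would bias means of
  replicate estimates and hide degenerate designs. Degenerate inputs fail
  loudly: zero total variance is an error, and a zero residual mean square
  (perfect within-subject agreement) collapses the CI to the point estimate
  with a warning.

## Absolute reliability: the within-subject CV

Per subject, `CV_i = 100·sd_i/mean_i` with the sample (n−1) standard
deviation; the summary is the mean and SD of the per-subject CVs. An
alternative pooled root-mean-square form (`pooled = TRUE`) is available —
published tables usually print "CV mean (SD)", which the default matches,
but the RMS form is the variance-weighted aggregate some laboratories
prefer.

## Spearman–Brown projection and power planning

The prophecy formula `m = X(1−ICC)/(ICC(1−X))` is reported *unrounded*:
whether 13.39 samples means 14 visits is a design decision, not an
estimation one. The forward form `m·ICC/(1+(m−1)·ICC)` is its exact inverse
over the whole positive-m domain (values of m below 1 are admitted so the
inverse identity holds when the target lies below the observed reliability).

Sample-size planning composes the attenuation relation
`r_obs = r_true·√(ICC_x·ICC_y)` with a Fisher-z power function:

- power(n) = Φ((z_r − z_c)·√(n−3)), with z_r = atanh(r) + r/(2(n−1)) and
  z_c the atanh of the critical correlation from the t distribution on n−2
  df. The bias term and t-based critical value match the standard
  correlation power calculator in common use; a plain Fisher-z variant
  (no bias term) is available via `bias_correction = FALSE`.
- The required n is found by upward integer scan from 4 — power is monotone
  in n, and scanning avoids the off-by-one ambiguity of inverting and
  rounding the closed form.
- `power_surface` defaults the outcome reliability to 1: the planning
  question isolates the cost of the *predictor's* unreliability.

A Monte-Carlo oracle in the test suite (bivariate-normal simulation, 50,000
replicates per point) confirms the approximation's required n to within one
subject at moderate effect sizes.

## Inferential companions

**Repeated-measures ANOVA.** The one-way within-subject F uses
MS_condition / MS_(condition × subject), with the Greenhouse–Geisser epsilon
computed from the covariance of orthonormal contrast scores (Huynh–Feldt
via flag; epsilon is exactly 1 at k = 2, where the F is the squared paired
t). The two-way fully-within analysis tests each effect against its own
subject-interaction error term, so the treatment × time interaction has
`((A−1)(B−1), (A−1)(B−1)(n−1))` df. Fractional (corrected) dfs are reported
alongside uncorrected ones; the two-way fit defaults to uncorrected
p-values, the common convention when the factor of interest has few levels,
with the correction one argument away. The implementation is a direct
sums-of-squares decomposition; the test suite cross-checks every F and the
epsilon against `car::Anova`'s multivariate-model route.

**Post-hoc contrasts.** Baseline-vs-post paired t per treatment, each on its
own error term (df = n−1), with family-wise adjustment through the
studentized-range distribution: `p_adj = ptukey(|t|·√2, nmeans, df)` with
`nmeans` the number of cell means spanned (eight for four treatments).
Pairing a within-subject design with a Tukey correction involves a genuine
ambiguity — a pooled error term would assume sphericity across contrasts —
and the per-contrast error term was chosen as the more conservative,
assumption-light reading. A contrast with identically zero differences is
reported as t = 0, adjusted p ≈ 1, rather than 0/0.

**Correlations.** Bootstrap Pearson uses percentile intervals (1000
resamples by default) with a fixed, recorded seed; the p-value is the
parametric t-based one, and both it and the interval are emitted because
reports rarely say which was used. The multilevel (repeated-measures)
correlation centres both variables on subject means and correlates the
residuals with df = N − n_subjects − 1; this is the within-subject
correlation under a random-intercept model, an approximation to the full
likelihood that is exact when slopes are common, and is invariant to
per-subject constant shifts (verified by property test). Subjects
contributing one observation carry no within-subject information and are
dropped.

**Bayes factor.** For H0: ρ = 0 against a stretched-beta alternative
(shape 1/width on (−1, 1); width 1 is uniform), the marginal likelihood uses
Jeffreys' exact integrated correlation likelihood — including its Gauss
hypergeometric term, evaluated by series — integrated over the prior by
adaptive quadrature. The integrand's peak is factored out on a grid first so
near-degenerate data (|r| → 1) stay in floating-point range, with a
trapezoidal fallback if the adaptive rule still balks. The factor is
reported null-first (`bf01`, with `bf10` alongside) and labelled on the
conventional anecdotal/moderate/strong ladder; the 1–3 band is labelled
anecdotal-for-the-null, and exact boundary values take the milder adjacent
label. The test suite checks the quadrature against an independent
Monte-Carlo prior-draw estimate of the same integral.

## The synthetic-data generator

The generator exists so that every stage is testable at desk scale, and its
defaults are fixed study conditions, not tuning knobs. On the log scale,

$$y_{ijf} = \mu_f + b_{if} + v_{ijf} + e_{ijf},$$

with subject effects b (sd `sigma_between`, correlated across fluids by
`cross_fluid_rho`), session-state effects v (sd `sigma_visit`, independent
across fluids), and residuals e (sd `sigma_within`). The implied true
reliability `ICC = σ_b²/(σ_b²+σ_v²+σ_w²)` is derived, read-only.
Defaults:

- 17 subjects × 4 visits; medians ~2.5 pg/ml (saliva) and ~4 pg/ml
  (plasma), inside the 1–10 pg/ml physiological range of extracted-sample
  assays;
- `sigma_between/visit/within = 0.34/0.30/0.44`, giving true ICC 0.290 and
  a raw within-subject CV near 57% — the regime reported for baseline
  plasma oxytocin;
- assay noise 8% CV (multiplicative log-normal, mean-one), under the <10%
  intra-assay bound of radioimmunoassay; a 0.1 pg/ml detection floor, with
  censored values becoming missing (never floor-imputed) so complete-case
  logic downstream is exercised honestly;
- `cross_fluid_rho = 0.10`, the weak saliva–plasma coupling seen at
  baseline; visit spacing ~N(8.8, 5.7²) days truncated to 3–28;
- crossover treatment ratios (spray/nebuliser ×12 on saliva, intravenous
  ×2.8 on plasma, placebo neutral) are *qualitative*: published
  post-administration figures are graphical, so the defaults encode the
  direction and rough magnitude of the pattern — intranasal routes flood
  saliva with unabsorbed peptide, intravenous reaches plasma only — not
  fitted values. Treatment order is counterbalanced by a seeded Latin
  square.

The pulsatile module superimposes Poisson-timed pulses (default 3/h,
exponential amplitudes of mean 2 pg/ml, 10-min decay half-life) on a basal
level. It exists to demonstrate a mechanism: samples minutes apart off one
trace agree far better than samples on different simulated days, which is
exactly the within-visit versus between-visit reliability gap a pulsatile
secretagogue produces even with a perfect assay.

What the generator does *not* emulate: circadian or seasonal structure,
assay batch effects, degradation during storage, dependence of saliva
capture on flow rate, or pharmacokinetic time-courses after administration
(post-administration levels are one-point ratio effects). Passing tests
therefore validate the *estimators* under the stated variance-components
model; they do not certify that real oxytocin data satisfy that model.

## Problem sizes and calibration

The package's own calibration runs (`recovery_suite`, and the deeper checks
in the test suite) use sizes chosen to make sampling error negligible
relative to the tolerance being asserted: estimator-vs-oracle identities on
200 random small matrices at 1e-10; parameter recovery at n = 200 subjects,
k = 4, 200 replicates within ±0.05; CI coverage at n = 30, k = 4 over 1000
replicates against a 93–97% band; Monte-Carlo power checks at 50,000
replicates. Seeds are fixed in tests; the generator records its seed in the
table metadata and restores the caller's RNG stream, so simulation never
perturbs user code.

## Known limitations

- The ICC machinery covers the two-way complete-case layout only; no
  generalizability-theory decompositions, unbalanced-data likelihoods, or
  Bland–Altman companions.
- The multilevel correlation is the centring approximation, not a full
  mixed-model likelihood; with very few observations per subject its df
  convention is the dominant approximation error.
- Power planning covers a single bivariate correlation; no regression or
  ANOVA power.
- The CI for the ICC is asymptotic-F; its coverage is verified by
  simulation at moderate n, not proven exact.
- Real assay pipelines (extraction, recovery correction) are upstream of
  this package: concentrations are taken as reported.
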