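---
title: "Estimating skeletal age from the percentage of adult height"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating skeletal age from the percentage of adult height}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelage)
```

## The model

Skeletal age (SA), scored from hand-wrist radiographs, is the reference
indicator of biological maturation in adolescents, but it is impractical to
collect routinely in training environments. The percentage of adult height
(PAH) — current stature as a share of predicted adult stature — is a
somatic maturity indicator that can be measured with a stadiometer, a
scale and the parents' heights. Because SA and PAH both track the same
underlying maturation process, SA is well approximated by a simple linear
model

$$\widehat{SA} = \beta_0 + \beta_1 \cdot PAH,$$

fitted here with the published coefficients for male soccer players aged
10–15: a general equation ($\beta_0 = -17.043$, $\beta_1 = 0.336$,
residual SD 0.606 y) and three maturity-stage-specific equations (late
$-18.445 + 0.348\,PAH$, on-time $-15.742 + 0.321\,PAH$, early
$-11.106 + 0.275\,PAH$). The intended two-stage workflow is: classify the
athlete's maturity status from PAH via the age-specific cut-offs, then
predict SA with the stage's own equation; when only SA itself is needed,
the general equation suffices.

The stage-specific lines are ordered — for any PAH below roughly 100 %,
the early-maturer equation predicts a higher SA than the on-time equation,
which exceeds the late one — so classification and prediction are mutually
consistent across the fitted range (PAH ≈ 78–99 %).

### Assumptions

* SA is linear in PAH within an age band of 10–15 years, with
  homoscedastic, approximately normal residuals (the fitting diagnostics
  below check exactly this).
* The equations are male-specific and were developed in a professional
  academy population; applying them to females or markedly different
  populations is extrapolation.
* PAH itself depends on an adult-height prediction. Using a TW3-supplied
  adult height and using an anthropometric (Khamis–Roche style) prediction
  give similar but not identical PAH values; the package keeps the two
  sources (`pah_tw3`, `pah_kr`) separate throughout.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| SA−CA on-time band | years | ±1.0, boundary inclusive | the standard definition of on-time maturation by skeletal age |
| PAH cut-offs | % | published per-age table, ages 10–15 | ROC-derived late/early thresholds; on-time is the *open* interval, ties go to late/early, following the "> 86.7 to < 91.3" phrasing of the age-13 example |
| Age grouping | years | round half-up | group means of the development sample (e.g. 9.9 ± 0.3 in the "10 years" group) indicate bands symmetric around integers, not floors |
| Plausible-PAH guard | % | (50, 110) | the equations were fitted on PAH ≈ 78–99; extrapolation should fail loudly (strict) or warn (lenient) |
| Bio-bands | % | < 85, [85, 90), [90, 96], > 96 | the conventional pre-pubertal / early pubertal / growth-spurt / post-pubertal bands; the literature's growth-spurt span (85–96 %) overlaps the pubertal bands, so the package resolves them into four non-overlapping bands and treats the growth-spurt label as the [90, 96] core |
| KS bootstrap replicates | count | 1999 | parametric-bootstrap calibration of the normality p-value |
| ROC cut-off criterion | — | Youden J | see below |

## Adult-height coefficients are an asset, not code

The Khamis–Roche method is a set of age-binned (half-year) smoothed
regression coefficients on current stature (inches), body mass (pounds)
and mid-parental stature (inches). Those published values are not bundled
here; the package ships a clearly labelled **synthetic** table
(`inst/extdata/kr_coefficients_synthetic.csv`) whose coefficients are
smooth and plausible in sign and magnitude, so every code path is
exercised without asserting numerical agreement with the original
publication. `load_kr_coefficients()` validates and installs a
user-supplied table; bins are half-open `[lower, next)` with the last bin
closed at `lower + 0.5`, so every age in the span maps to exactly one row.

Parents' statures are stored as given: no self-report correction is
applied, because whether the source values were measured or self-reported
is a property of the data set, not of the method.

## Numerical choices

* **Rounding.** Predictions are carried unrounded through the two-stage
  workflow; one-decimal (half-up) rounding happens only at reporting, so
  rounding error never compounds.
* **PAH above 100 %** is possible when adult height is under-predicted.
  It is flagged with a message but never clipped — clipping would bias the
  SA prediction downstream.
* **Boundary conventions.** SA−CA exactly ±1.0 is on-time (the band is
  "within ± 1.0"); a PAH exactly at a cut-off goes to the outer class
  (late/early), because on-time is defined as the open interval.
* **Durbin–Watson ordering.** Cross-sectional data has no natural time
  order; the statistic is computed in input-row order by default, with an
  option to sort by fitted value first.
* **KS normality of residuals.** The test compares residuals against a
  normal with mean 0 and the *estimated* residual SD. Estimating the scale
  invalidates the classical KS null distribution, so the p-value is
  calibrated by a seeded parametric bootstrap (default 1999 replicates),
  in the spirit of the Lilliefors correction.
* **ICC variant.** "ICC" alone is ambiguous; the package fixes the
  two-way, single-measure, absolute-agreement form ICC(2,1), the standard
  choice for method agreement because it penalizes systematic offsets —
  consistent with pairing it with Bland–Altman analysis.
* **ROC cut-offs.** Candidate thresholds are midpoints between consecutive
  distinct scores plus ±∞ (symmetric treatment of both classes and
  reproducible regardless of which class attains a value); the Youden
  index J = sensitivity + specificity − 1 selects the threshold, with ties
  broken toward higher sensitivity, then the lower threshold. AUC uses the
  Mann–Whitney formulation (ties count ½) with a DeLong closed-form CI; a
  seeded bootstrap CI is available as an alternative.
* **Degenerate inputs fail loudly**: constant predictors, all-zero
  residuals, single-class ROC inputs, empty stage subgroups and
  zero-variance paired t-tests all raise errors or flags rather than
  returning silently wrong numbers.

## Deriving cut-offs from new cohorts

`derive_cutoff_table()` labels each record late/on-time/early from
SA − CA, then per integer age group runs two one-vs-rest ROC analyses on
PAH: late-vs-rest with *low* PAH as positive (inferior cut-off) and
early-vs-rest with *high* PAH as positive (superior cut-off). Two guard
rails keep the output table coherent:

* a side with fewer than `min_cases` (default 3) class members is left
  unset with a warning — a one-case ROC threshold is noise, not a cut-off;
* if the two sides still cross (possible when the classes overlap
  heavily), the side with the lower AUC is unset with a warning, so a
  returned table always satisfies inferior < superior.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` draws, per age group, the development sample's sizes
(76, 119, 93, 120, 97, 65 for ages 10–15) and per-age PAH means/SDs
(79.2 ± 0.7 up to 96.1 ± 3.0). PAH is the generative primitive — the
downstream equations consume PAH, so its distribution is controlled
exactly — and stature is derived as PAH/100 × a drawn adult height
(Normal(181, 6.5) cm). SA follows the general equation plus
Normal(0, 0.606) residuals, rejected outside |SA − CA| ≤ 3 years
(mirroring the study's exclusion criterion). Mid-parental stature is
Normal(172, 4.5) cm, split into mother/father as ±6.5 cm with 1 cm noise
(only the mean enters any computation); body mass follows a linear
stature relation (0.9 kg/cm, intercept −90.5 kg, noise SD 5 kg) matched
to the sample's stature and mass summary statistics. All draws are
deterministic given the seed; truncation uses rejection sampling with a
hard iteration cap.

What it does **not** emulate: longitudinal trajectories and peak height
velocity; the joint distribution of SA−CA offsets per age (the real
cohort's maturity mix is unknown — the simulator's mix is whatever the
general equation plus noise implies, which is why its categorical
agreement statistics are qualitatively, not numerically, comparable to
the study's); measurement error in anthropometry; and population
differences. Passing tests on synthetic data therefore demonstrate that
the machinery is correct under the stated generative model, not that the
published real-data agreement numbers (ICC 0.97, kappa 0.58) are
reproduced — those require the original radiographic cohort.

## Problem sizes used in the checks

The test suite and acceptance script work at the development-sample scale
(570 records per cohort, 200 seeded replicates for the recovery rate),
with smaller fixed instances (n ≤ 50) wherever a statistic is compared
exhaustively against a brute-force oracle, and 199–999 bootstrap
replicates for KS p-values in repeated checks. These sizes give stable
checks at sub-minute runtimes.

## Known limitations

* Male-only equations; no female coefficients exist in this model family.
* The shipped adult-height coefficient table is synthetic; PAH-from-KR
  results are structurally correct but not numerically comparable to the
  published Khamis–Roche predictions until the real table is installed.
* The printed per-age PAH means are rounded to one decimal, so composing
  them with the general equation reproduces the printed per-age mean SA
  at one decimal for ages 10–14 but misses by one rounding unit at 15 —
  an artifact of input rounding, documented in the tests.
* TW3 radiograph scoring itself (and therefore "true" SA) is out of
  scope; `observed_sa_years` is always an input.
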