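---
title: "Validating a cardiac-output monitor: agreement, robustness and trending"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a cardiac-output monitor: agreement, robustness and trending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagree)
```

## The problem

A new noninvasive cardiac-output (CO) monitor is useful only if its readings
agree with an accepted reference — in perioperative practice, typically
transthoracic echocardiography (TTE) — and if it *tracks changes* in CO when
haemodynamics are deliberately perturbed (induction of anaesthesia,
pneumoperitoneum, Trendelenburg tilt). `coagree` implements the complete
statistical pipeline for such a validation study on paired cardiac-index
measurements: agreement (Bland–Altman with confidence intervals), a battery
of robustness checks, and trending analysis (four-quadrant and polar
plots), together with a synthetic-study generator that stands in for
clinical data.

All statistics operate on the **cardiac index** CI = CO / BSA
(L min⁻¹ m⁻²), with the Mosteller body surface area
`sqrt(height_cm × weight_kg / 3600)` applied identically to both methods so
that indexing cannot create spurious disagreement. The reference CO is
derived from echo primitives by the Doppler chain
SV = π (d/2)² × VTI, CO = SV × HR / 1000, with the nine VTI traces (three
sets of three) aggregated as the mean of set means — equal, in the balanced
case, to the grand mean, but robust if a set is incomplete. A median option
exists because the aggregation rule is a convention, not a law.

## Agreement model and assumptions

For paired observations the difference d = CI_test − CI_ref is summarised
by its mean (*bias*), its sample sd (*precision*, n−1 denominator), and the
limits of agreement bias ± z·sd with z = 1.96. The parametric limits assume
approximately normal, homoscedastic, independent differences; each of those
assumptions gets its own check:

1. **Normality** — Shapiro–Wilk on d (`normality_check()`, valid for
   3 ≤ n ≤ 5000). Non-normality does *not* switch the parametric analysis
   off; the percentile limits are always reported alongside
   (`nonparametric_loa()`, 5th/95th empirical percentiles).
2. **Repeated measures** — five timepoints per patient are not independent.
   Because the protocol deliberately changes the true CO between
   timepoints, the appropriate correction is the "true value variable"
   variant: a one-way method-of-moments ANOVA of d by patient gives
   σ²_between and σ²_within, and the corrected limits use
   sd_total = sqrt(σ²_between + σ²_within). With one pair per patient the
   decomposition collapses and the result equals the naive analysis
   exactly (tested). A negative moment estimate of σ²_between is truncated
   at zero, the standard convention.
3. **Reference imprecision** — the mean percentage error
   MPE = z·sd/mean CI × 100 is judged against the 30% interchangeability
   bound, but also against the **combined repeatability**
   sqrt(rep_ref² + rep_test²), where each method's repeatability is
   z × within-subject replicate sd / grand mean × 100 from a one-way ANOVA
   of replicates within patient-timepoint. If MPE ≤ combined repeatability,
   replicate noise alone can explain the observed error.
4. **Proportional bias** — the mixed model d ~ CI_ref + (1 | patient),
   fitted by REML (`lme4`), with a normal approximation on slope/se for the
   p-value; at validation-study sizes (hundreds of pairs) the approximation
   error is negligible, which is why no finite-sample df method is used.

### Confidence intervals

The bias CI uses the exact t interval. Each LoA CI uses the standard-error
form sd·sqrt(1/n + z²/(2(n−1))) with a t(n−1) multiplier — this choice
reproduces published bias CIs at n = 273 to printed precision. The MPE CI
propagates the χ²(n−1) distribution of the sample sd through the MPE
formula with the mean held fixed; it is explicitly an approximation (it
ignores the sampling variability of the mean and the repeated-measures
correlation) and is labelled as such because no canonical MPE interval
exists in the literature.

## Trending analysis

Between-timepoint change pairs (Δ_ref, Δ_test) are extracted per patient.
The default policy uses **consecutive timepoints only**: the five protocol
states are ordered interventions, so consecutive transitions are the
physiologically meaningful ones; a `bridge` policy spanning a single
missing timepoint is available for sensitivity analysis.

- **Four-quadrant concordance**: a pair is excluded when *both* |Δ| fall
  strictly inside the central square of half-width 15% of the mean CI
  (small changes are direction-noise-dominated). Among the rest,
  concordant means Δ_ref·Δ_test > 0 — a zero change on either axis counts
  as discordant. The square-both rule and the strict product rule are
  documented conventions (the central-square exclusion matches the usual
  graphical presentation); an either-axis rule would exclude more pairs
  and typically raise the rate slightly.
- **Polar statistics**: angle = planar angle of (Δ_ref, Δ_test) − 45°, so
  the identity line maps to 0° and a test change smaller than the
  reference change gives a negative angle; radius = |Δ_ref + Δ_test|/2
  (the mean change — the Euclidean norm/√2 alternative is a
  `polar_transform` one-liner away but the mean-change radius is what the
  zone is scaled against). Points with negative mean change are rotated by
  180° onto one sheet (half-circle convention) so that ordinary arithmetic
  means and sds of angles are meaningful; no circular statistics are
  needed because post-rotation angles concentrate far from the ±180°
  wrap. The polar exclusion disc is the quadrant zone divided by 1.5,
  reflecting that the radius is a mean of two deltas. The mean polar angle
  is unweighted by default (radius weighting is exposed as an option but
  no published weighting rule exists).
- **Verdict**: reliable trending iff concordance > 90%, |mean angle| < 5°,
  angular sd ≤ 15°, and radial LoA (mean ± 1.96 sd) within ±30°. The MPE
  verdict is MPE < 30%, strict.

## The synthetic world

`generate_study()` emulates a 55-patient, five-timepoint perioperative
study. Its defaults *are* the stated world, chosen once from the study
design, not tuned to test outcomes:

| parameter | default | units | why |
|---|---|---|---|
| `n_patients` | 55 | — | cohort size |
| `timepoint_means` | 2.76, 2.38, 2.50, 2.54, 3.02 | L min⁻¹ m⁻² | published reference means at the five states |
| `sigma_between` | 0.30 | L min⁻¹ m⁻² | patient level shift; induces the within-patient correlation (reported rank correlation > 0.31) that motivates the repeated-measures correction |
| `sigma_ref`, `sigma_test` | 0.14 | L min⁻¹ m⁻² | per-method noise; gives theoretical MPE 1.96·sqrt(2·0.14²)/2.65·100 ≈ 14.6%, inside the published MPE CI |
| `device_bias` | 0.02 | L min⁻¹ m⁻² | published bias |
| `prop_coefficient` | 0 | — | published slope ≈ 0 |
| `replicate_cv` | 0.15 | — | per-trace VTI CV; implies per-method repeatability ≈ 29% and combined ≈ 41% (published: 40.6%), and — averaged over 3×3 traces — set-mean noise ≈ 5% of the mean, self-consistent with `sigma_ref` 0.14 |
| `missing_rate` | 2/275 | — | two sets lost of 275 scheduled |

Biometrics are truncated normals (rejection-sampled, so the published
ranges are respected exactly): height N(163.7, 6.3) on [149, 176] cm,
weight N(66.5, 11.4) on [44, 93] kg, age N(44.1, 10.8) on [23, 77] yr; the
cohort is all-women by definition. CO is back-computed as CI × BSA so the
long CSV exercises the full indexing chain on read.

Each component (biometrics, level shifts, noise, missingness, echo traces)
draws under its own sub-seed derived from the master seed in a fixed
order, so adding a feature never silently shifts an existing stream;
regeneration under the same seed is bit-exact (tested).

**What the generator does not emulate** — and therefore what a green test
does not establish: physiological pharmacokinetics (timepoint means are
exogenous), heteroscedastic or CO-level-dependent noise, heavy-tailed
device error (differences are Gaussian unless you plant otherwise),
correlated missingness, drift within a timepoint, or the device's internal
signal processing. Parameter-recovery tests validate the *estimators*
against this stated world, not the device.

### A note on proportional-bias recovery

In the generative model the test reading is
true + bias + β·true + noise, while the regressor is CI_ref = true +
e_ref. Reference noise therefore both attenuates the estimated slope
(classical errors-in-variables) and contributes a *negative* covariance
term, because e_ref enters the difference with a minus sign: the
population slope of d on CI_ref is roughly
(β·Var(true) − σ²_ref) / (Var(true) + σ²_ref). At σ_ref = 0.14 a planted
β = 0.1 is unrecoverable in principle — the population slope itself is
near zero or negative. The recovery tests therefore plant β in a world
with small reference noise (σ_ref = 0.02), where the population slope is
within about 0.008 of β. Conversely, on the default world the fitted slope
is mildly negative even though β = 0; users should read a small negative
slope in real data with the same caveat in mind.

## Numerical choices and degenerate inputs

- Percentile limits use the linear-interpolation quantile at position
  1 + (n−1)p (R type 7), stated so tests are bit-stable; other types are
  an argument away.
- Shapiro–Wilk is undefined for constant samples, so the robustness
  battery cannot run on an exactly noiseless dataset; the noiseless limit
  is validated through `bland_altman()` and `trending_analysis()` (bias 0,
  MPE 0, concordance 100%, mean angle 0°).
- `polar_transform(0, 0)` is an error (undefined direction), and
  change pairs that are (0, 0) are dropped before the polar stage by the
  pipeline.
- A single patient cannot support the repeated-measures decomposition, a
  constant reference vector cannot support the proportional-bias model,
  and an empty post-exclusion set cannot define a concordance rate — each
  is an explicit error, never a silent NA.
- Generated cardiac indices are floored at 10⁻⁶ to keep them physical;
  at realistic noise levels the floor is never hit.
- Timepoints are labelled 1–5 user-visibly; missing values are empty CSV
  cells; unpaired rows are kept in a side table with a warning.

## Known limitations

- The MPE confidence interval is a χ²-propagation approximation; published
  intervals computed by unstated (possibly bootstrap or
  repeated-measures-aware) methods will differ slightly.
- The repeatability definition (z × within-subject sd / grand mean) is one
  of several conventions in circulation; it is exposed per method so a
  coefficient-of-error variant can be composed by the user.
- Angular statistics are linear, not circular; they are appropriate under
  the half-circle convention with well-tracking devices but would misbehave
  if angles approached ±180°.
- At the stated default noise, the trending verdict sits near the
  15° angular-sd boundary and flips between seeds — a faithful property of
  a borderline world, not a bug.
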