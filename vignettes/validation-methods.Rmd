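---
title: "Methods: count-to-EE calibration, agreement statistics, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-to-EE calibration, agreement statistics, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eecalib)
```

## The measurement problem

Accelerometer-based devices — research actigraphs and, increasingly,
smartphones — report dimensionless "activity counts" per epoch. To be
useful in physical-activity research those counts must be mapped to
energy expenditure (EE, kcal/min) and validated against a criterion
(indirect calorimetry) and a convergent reference (an established
accelerometer). This package implements that entire validation workflow,
with synthetic-data generators standing in for the unavailable raw study
data.

## The calibration model

The core estimator is a linear two-predictor regression,

$$EE = \beta_c \cdot \text{counts/min} + \beta_m \cdot \text{mass} + \beta_0 + \varepsilon,$$

fitted by ordinary least squares (`fit_calibration()`). Assumptions: EE
is linear in counts over the observed range, mass enters additively, and
residuals are homoscedastic. The reported SEE uses the $n-3$ denominator
for fitted models; cross-validation on an independent sample
(`cross_validate()`) uses the plain RMSE, because no parameters are
estimated there — the two formulas differ and the choice matters at small
$n$, so both are documented.

Predictions can be negative at low counts and low body mass (extrapolation
below the calibration range); they are returned raw rather than clamped,
since clamping would bias daily EE totals.

## MET conversions and cut-point derivation

Intensity bands are anchored at 3/6/9 MET. The package's default
conversion is the compendium definition 1 MET = 1 kcal·kg⁻¹·h⁻¹, i.e.
kcal/min = MET × mass / 60; the oxygen-based alternative
(3.5 mL O₂·kg⁻¹·min⁻¹ at 5 kcal/L) is available via
`convention = "vo2"`. The reference mass defaults to 70.5 kg, the
calibration sample mean.

`derive_thresholds()` inverts the calibration equation at each MET
boundary. Note a deliberate design choice: the *published* cut-point
table (light < 1253, moderate 1253–1272, hard 1273–6987, very hard
> 6987 counts/min) is shipped as a frozen constant
(`published_thresholds()`) and used for classification by default.
Inverting the published equation at 3 MET and 70.5 kg yields ≈ 1130
counts/min, not 1253, and no standard MET convention reproduces the
20-count-wide moderate band; the derivation behind the published table is
not recoverable. The implementation therefore does not force agreement:
the table is authoritative for classification, the inversion is provided
for methodological transparency, and the two are never silently mixed.

Classification uses inclusive integer lower bounds (a count exactly at a
boundary belongs to the higher band); non-integer counts obey the same
inequalities, so 1252.5 counts/min is light.

The smartphone-to-reference count scale-congruence factor is 2121 and is
applied by multiplication (`apply_scale_correction()`): smartphone counts
sit on the smaller scale. The direction is configurable because only the
factor's value, not its direction, is conventionally reported.

## Averaging windows

Steady-state extraction averages the trailing window of each bout —
half-open on the left, closed on the right — with a 2-min default. For
5-min bouts an alternative convention averages minutes three and four;
`bout_steady_state_mean()` takes explicit window arguments so either
anchoring can be expressed, but the trailing-2-min reading is the
default. Breath-sample averaging is a simple arithmetic mean of samples
in the window (not time-weighted): with near-uniform breath spacing the
two differ negligibly, and the simple mean is the more reproducible
reading of "data were averaged".

## Free-living cleaning rules

* Nonwear: maximal runs of consecutive zero-count epochs **strictly
  longer than 60 min** are removed. The rule is evaluated on the native
  epochs (10 s free-living) before minute resampling, and a single
  nonzero epoch breaks a run — the strictest reading, with no spike
  tolerance. Runs of exactly 60 min are retained.
* Valid day: at least 600 wear minutes (10 h), inclusive.
* Minute resampling sums constituent epochs; a trailing partial minute is
  dropped with a warning, conserving all other counts.

## The agreement battery

Method agreement requires equivalent group estimates, association, and
absence of systematic or heterogeneous bias. `agreement_report()`
computes:

* **Bias**: one-sample t-test of paired differences against zero, with a
  95% CI.
* **Limits of agreement**: bias ± 1.96 × SD of differences. The 1.96
  multiplier (not a small-sample t quantile) follows the classic
  Bland–Altman convention.
* **Pearson r** with the t-transform p-value.
* **ICC(A,1)**: two-way random-effects, single-measures, absolute
  agreement, computed from the two-way mean squares. Single-measures is
  used because each observation is a single device reading, not an
  average of repeated ratings.
* **Bias-by-intensity ANOVA**: one-way on the difference scores with
  intensity level as the only factor. Pairwise follow-ups are
  least-significant-difference t-tests using the ANOVA pooled variance,
  Bonferroni-corrected by multiplying each p by N(N−1)/2 and capping at
  1. Group-level degrees of freedom in published validation tables
  depend on unstated pooling and exclusions, so printed F/df values are
  not treated as reproduction targets — only the procedure is.

## The synthetic world

The generators' defaults are fixed statements of the conditions the
analysis assumes, not tuning knobs:

* **Calibration data**: counts uniform on [0, 15000]/min; mass Gaussian
  (70, SD 12, truncated ≥ 40 kg); EE = model prediction + Gaussian noise
  with SD 1.94 kcal/min — additive and homoscedastic because a single SEE
  is the only reported residual scale.
* **Laboratory sessions**: 1-s epochs; counts linear in speed
  (1000 counts/min per km/h — a round value placing 4–12 km/h in the
  light-to-vigorous EE range under the published equation) with
  multiplicative lognormal noise (CV 0.15); V̇O₂ follows a first-order
  exponential approach to each segment's steady state with τ = 35 s, a
  typical adult on-kinetics value — the literature-default stand-in for a
  latency that is only described qualitatively. RER ramps linearly from
  0.85 at rest to 1.00 at the fastest speed so simulated calorimetry
  spans light-to-vigorous substrate mixes; any fixed RER would satisfy
  the same tests.
* **Free-living days**: 10-s epochs; a persistent five-state Markov
  mixture over sedentary-to-vigorous minutes. The real distribution of
  free-living activity is unknown — this mixture is a stand-in with the
  right gross structure (mostly sedentary/light, occasional vigorous
  bouts), not a claim about any study sample. Outside nonwear blocks the
  reference series is kept strictly positive so the configured blocks are
  provably the only nonwear; the phone series differs by a multiplicative
  scale mismatch (default 1.05) plus noise and is silenced during
  noncarry blocks.
* **GPS tracks**: 1-min sampling while moving, 30-min while stationary
  (the power-aware logging rule); accuracy radii drawn from the
  field-observed bin mixture (32.3 / 40.3 / 3.8 / 5.9% across the four
  ≤ 100 m bins) with a 17.6% gross-outlier fraction (lognormal radii,
  median 2370 m); positional noise is isotropic Gaussian with
  SD = radius/2, so outliers also carry kilometre-scale displacements.

What a green test establishes: the pipeline's algebra, boundary handling,
and statistical machinery are correct on data with this structure. What
it does not establish: validity of any real device, realism of the bout
mixture, or robustness to pathologies the generators omit (count
plateaus at running speeds, heteroscedastic EE noise, GPS multipath
structure, device clock drift).

## Numerical and geometric choices

* Equirectangular local projection centred on the track centroid
  (R = 6371 km), chosen over UTM for simplicity at city scale; the
  length error against great-circle distance is under 0.5% for tracks
  spanning < 20 km below 60° latitude (tested), and the projection
  refuses centres within 5° of a pole.
* Suspect-fix heuristic: a fix is flagged if both adjacent implied
  speeds exceed 40 m/s, or its turning angle exceeds 120° *and* the
  detour ratio (d_in + d_out)/d_skip exceeds 3. The thresholds are
  engineering defaults for a qualitative criterion ("significant
  deviation over a short time and sharp turning angle"): they isolate a
  5-km spike on a walking track while sparing a genuine 90° street
  corner (detour ratio ≈ 1.4). Endpoints are never flagged.
* Space-time trajectory segments take the modal intensity of the wear
  minutes they span; ties break toward the higher intensity, and
  segments with no overlapping wear minutes inherit the previous
  segment's category with an `inherited` flag.
* Degenerate inputs are first-class: zero-variance differences give an
  infinite t with a warning (or t = 0, p = 1 for the all-zero case),
  constant observed EE yields a missing cross-validation r² with a
  warning, and empty GPS input produces an empty accuracy report rather
  than an error.

## Pipeline decisions

Laboratory calibration pools per-bout steady-state means (rest plus each
bout) across participants — one row per participant × window — rather
than per-minute observations; per-minute pooling inflates n with
autocorrelated samples. The phase-2 protocol is preceded by a 5-min rest
(its published description starts at the first bout; some settling period
must exist for the kinetics to start from rest). Device time alignment in
the pipelines is by construction (shared clocks); for real data the I/O
layer reads ISO 8601 UTC timestamps and alignment is the caller's
responsibility. Every exclusion (participant, day) is logged with a
machine-readable reason, because attrition under the 10-h rule is itself
a finding.

## Known limitations

No protein-corrected calorimetry (the zero-urinary-nitrogen equation is
applied uniformly), no spike-tolerant nonwear algorithms, no
regression-based limits of agreement for proportional bias, no
map-matching. The published headline group statistics depend on raw data
that are not public; this package reproduces the *methods* and verifies
them on synthetic cohorts where ground truth is known, including
injected-bias scenarios at the published magnitudes.
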