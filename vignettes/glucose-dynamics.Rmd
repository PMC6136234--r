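---
title: "Glucose dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glucose dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucodyn)
```

This vignette is the package's own account of the methods it implements:
what each estimator computes, which tunables matter and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and where the genuinely open design choices were decided.

## The data model

A `glucose_series` is a uniformly sampled CGM trace: glucose in mmol/l at
a fixed interval (5 min by default, 576 points for a 48-h window).
All estimators operate on the sample index; wall-clock timestamps matter
only for I/O and gap handling. mg/dl values are converted on read by
division by 18.016 (the molar mass of glucose), an exact bijection.

Quality control mirrors ambulatory sensor practice: a recording is valid
when it has at least three paired sensor/meter readings whose mean
absolute relative difference is at most 28% (`qc_validity()`); gaps up to
`max_gap_min = 30` (six samples) are linearly interpolated and flagged,
longer gaps are a hard QC error. The 30-min default is a conservative
convention — interpolation over longer spans would fabricate the very
short-term structure the dynamical indices measure.

## Geometric domain: lagged Poincaré plots

For the pair cloud \((x, y) = (G_t, G_{t+\Delta t})\) over all overlapping
pairs, the descriptors are the rotated-coordinate dispersions

\[
SD1 = \mathrm{SD}\!\left(\tfrac{x - y}{\sqrt 2}\right),\qquad
SD2 = \mathrm{SD}\!\left(\tfrac{x + y}{\sqrt 2}\right),\qquad
SFE = \frac{SD2}{SD1},\qquad AFE = \pi \cdot SD1 \cdot SD2 .
\]

Rotated-coordinate variances were chosen over geometric ellipse fitting
because they are exactly reproducible, satisfy
\(SD1^2 + SD2^2 = \mathrm{Var}(x) + \mathrm{Var}(y)\) identically (a unit
test asserts this to 1e-10 relative), and coincide with the usual
fitting-ellipse definitions. Sample (n−1) variance is used throughout the
package; whether the original descriptor literature used n or n−1 is not
decidable from the definitions, so the denominator is exposed as a toggle
(`denominator = "n"`). Overlapping pairs (stride 1) maximize data use; the
default lag is 60 min, with 30 and 120 min as standard probes. For a
constant series SD1 = SD2 = AFE = 0 and SFE is reported as undefined
(`sfe_undefined`), never as a surrogate number.

## Information domain: multiscale sample entropy

Scale-τ coarse-graining averages non-overlapping windows,
\(u_j^{(\tau)} = \frac1\tau \sum_{i=(j-1)\tau+1}^{j\tau} x_i\), giving
⌊N/τ⌋ points (576 → 115 at τ = 5). Sample entropy is
\(-\ln(A/B)\) with B the number of ordered pairs (i ≠ j) of length-m
templates within Chebyshev distance r, and A the same for length m+1.
Conventions, fixed so that an independent brute-force counter reproduces
the counts integer-exactly:

- templates at every index where both the m- and (m+1)-template exist
  (i = 1..N−m), the convention of the standard multiscale-entropy tool;
- distance comparison `<= r`; natural logarithm;
- ordered pairs with i ≠ j (a factor of 2 that cancels in A/B);
- zero matches give an *undefined* flag, never a substituted constant.

Defaults m = 2, r = 0.15·SD, scales 1..5. The tolerance is computed once
from the original series and held fixed across scales: recomputing r from
each coarse-grained series would remove the variance-reduction effect of
averaging, which is part of what the multiscale curve measures. Because r
scales with the series SD, every SampEn value is invariant to amplitude
rescaling — the complexity index is a pure structure measure, which is why
synthetic groups differing 2-fold in SD can still be ordered by it. The
complexity index is the sum of the per-scale entropies; if any scale is
undefined the result is marked `partial` rather than silently summing a
shorter vector.

## Fractal domain: detrended fluctuation analysis

The mean-centred series is integrated,
\(y(k) = \sum_{i \le k} (B_i - \bar B)\) (so y(N) = 0 identically), cut
into ⌊N/n⌋ non-overlapping boxes of n points anchored at the series start
(remainder discarded, no reversed second pass — a both-ends variant would
change F(n) only marginally and the single-pass form matches the defining
equation), each box is linearly detrended by OLS, and

\[
F(n) = \sqrt{\tfrac{1}{N'} \textstyle\sum_k \left(y(k) - y_n(k)\right)^2}
\]

over the N′ covered points. Exponents are OLS slopes of log₁₀F on log₁₀n
over a ~12-points-per-decade integer grid: α1 over n = 4–16, α2 over
n = 16–144 (capped at ⌊N/2⌋), with the crossover n = 16 included in both
fits since the conventional short and long ranges overlap there.

Two deliberate deviations from the textbook ranges:

- **`min_box = 4`.** With first-order detrending a 2-point box is fitted
  exactly (zero residual) and a 3-point box is near-degenerate, so the
  nominal short range "n = 2–16" would put log F(n) = −∞ on the grid. The
  short fit therefore starts at n = 4; `min_box = 2` restores the literal
  range with zero-residual boxes excluded from the fits.
- At 5-min sampling, 16 points is 80 min, not the 1.25 h (75 min)
  sometimes used as the short-range label; the package follows the point
  counts, which are what the algorithm actually uses.

Calibration: fractional Gaussian noise with Hurst exponent H has DFA
exponent α = H, and integrated white noise has α = 1.5. The acceptance
suite verifies both — the mean of `dfa_alpha()` (single slope over
n = 8–256) across 100 replicates of length 4096 falls within ±0.1 of H
for H ∈ {0.3, 0.5, 0.7, 0.9}, and within ±0.1 of 1.5 for random walks.
The short-range fit n = 4–16 is used for per-subject α1 because that is
the conventional window; for calibration against fGn the wider 8–256
window is used since small-n DFA1 carries a known finite-size bias.

## The synthetic CGM generator

`generate_cgm()` builds a trace as

mean + circadian sinusoid (24-h period) + Gaussian meal excursions
(07:00 / 12:00 / 18:00) + fractional Gaussian noise + white sensor noise,

then applies **one affine correction**: the pooled zero-mean fluctuation
is rescaled so the realized mean and %CV equal the profile targets exactly
before clipping. A deterministic single pass was preferred over iterative
search — it is fast, auditable, and makes the seed → series mapping
trivial. Values are floor-clipped at 2.2 mmol/l (below the
hypoglycemia-relevant region); the clipped fraction is recorded and a
warning flag set when it exceeds 5%, since clipping then visibly erodes
the %CV target. The fGn component uses the exact Davies–Harte circulant
embedding, so its autocovariance is exact at every lag — a requirement for
using it as the DFA calibration oracle, not just a convenience.

The three presets encode published cohort-level targets (mean glucose
5.4 / 7.8 / 8.0 mmol/l and %CV 15.7 / 20.2 / 36.9 for ND / T2D / T1D) and
a qualitative structure chosen once, during model design, to reflect how
such traces differ:

| preset | H | fgn_sd | noise_sd | meal_amp × width | circadian |
|---|---|---|---|---|---|
| ND | 0.60 | 0.5 | 0.50 | 0.6 × 45 min | 0.3 |
| T2D | 0.80 | 0.8 | 0.25 | 1.8 × 60 min | 0.6 |
| T1D | 0.93 | 1.3 | 0.12 | 3.0 × 75 min | 1.0 |

Because the affine pass rescales everything, only relative weights matter:
the non-diabetic profile is dominated by rough, quickly decorrelating
fluctuation (high white-noise share, H near 0.5), the type-1 profile by
large persistent excursions. This reproduces the characteristic group
orderings — complexity index ND > T2D > T1D, Poincaré SD1/SD2/AFE
T1D > T2D > ND, DFA exponents increasing with diabetes severity — which
the acceptance suite checks on 50 study-sized cohorts (12/143/22). The
T1D profile needs both smooth bulk (low entropy) *and* substantial
short-term dispersion (high SD1); H = 0.93 with a strong fGn weight
delivers both, whereas a nearly-Brownian profile (H → 1, weak fGn) ties
with T2D on SD1.

`generate_cohort()` adds two layers: covariates drawn from distributions
centred on published group demographics (age, sex ratio, BMI, carbohydrate
intake, HbA1c, therapy code 1–4, log-normal diabetes duration), and
between-subject heterogeneity — each subject's personal mean/%CV targets
are drawn with the published between-subject SDs (0.5/2.0/1.7 mmol/l and
3.5/7.4/8.6 %). Without that spread every subject in a group would realize
the identical %CV, which degenerates group t-tests and cross-subject
correlations.

**What the generator does not emulate:** sensor drift and calibration
artifacts, meal-time variation between days and subjects, hypoglycemia
countermeasures (eating in response to lows), treatment feedback, and any
insulin–glucose physiology. Consequently, passing cohort tests show that
the *pipeline* recovers orderings from series whose structure differs in
the intended direction — they are not evidence about real patients, and
absolute index values (e.g. complexity ≈ 10 for the ND preset) need not
match clinical values (real traces are smoother than the noise-rich ND
preset). Matching published time-in-range values simultaneously with
mean/%CV was not attempted; TIR is an emergent property of the simulated
distribution shape.

## Statistics layer

- Group comparisons: one-way ANOVA plus all pairwise two-sided Student
  t tests (pooled variance; Welch available) with Holm step-down
  adjustment over the pairwise family. A simulation test confirms
  family-wise error ≤ 5% under the global null.
- Spearman correlations with mid-ranked ties and asymptotic p-values.
- `standardized_regression()` z-scores the response and all terms, so
  coefficients are standardized β (for a single term, β equals the
  Pearson correlation exactly). Sex enters as 0/1 (F = 1), antidiabetic
  therapy as a single ordinal code 1–4 (1 none, 2 diet ± oral agents,
  3 oral agents ± insulin, 4 insulin alone) — ordinal rather than dummy
  coding, matching how such therapy scales are usually entered. VIF
  (`car::vif`) and Durbin–Watson (`lmtest::dwtest`, computed in table row
  order, which is a seeded, recorded property of a simulated cohort) are
  reported per model; perfect collinearity and constant terms raise
  errors naming the offending columns.
- `tir_models()` regresses time-in-range on the core covariate model
  (age, sex, duration, BMI, carbohydrate intake, therapy) plus %CV plus
  one dynamical index. Diabetes duration is undefined for non-diabetic
  subjects, so the default analysis set is patients only; with
  `subjects = "all"` the duration term is dropped instead. Optional
  forward selection of covariates uses p-to-enter 0.05, a conventional
  threshold.

## Numerical and degenerate-input conventions

- Sample (n−1) SD/variance everywhere (metrics, Poincaré, MSE tolerance).
- A constant series: SD = CV = 0, SD1 = SD2 = AFE = 0 with SFE flagged
  undefined, SampEn 0 at every scale (complexity 0), DFA F(n) ≡ 0 with
  undefined exponents.
- Undefined quantities are flagged (`NA` + flag fields), never replaced by
  large constants; partial MSE results are marked `partial`.
- All simulation is seeded; generators derive per-subject sub-seeds from
  the master seed, so cohorts are bitwise reproducible and independent of
  the caller's RNG state.

## Problem sizes used by the test and acceptance suites

Chosen to make the checks statistically meaningful while keeping a full
run comfortable on one CPU: SampEn oracle on 100 series of length ≤ 300;
DFA calibration on 100 replicates × 4 Hurst values at length 4096;
group-ordering recovery on 50 cohorts of 177 subjects × 576 samples;
Holm family-wise error on 1000 simulated three-group tables. The full
suite runs in roughly five minutes.

## Known limitations

- DFA1 small-scale bias: α1 over n = 4–16 is a biased estimator for
  rough series; it is reported as the conventional index, not as an
  unbiased Hurst estimate.
- SampEn is undefined for series with no template matches (very short or
  very irregular series at small r); the package reports rather than
  imputes.
- The CSV dialect is deliberately minimal (no time zones, no proprietary
  export formats); timestamps are optional and analyses use sample index.
- The generator's stationary fGn cannot produce the α > 1.5 short-range
  exponents seen in very smooth clinical traces; the built-in profiles
  reach α1 ≈ 1.1–1.2.
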