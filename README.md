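# glucodyn

Variability and complexity analysis of continuous glucose monitoring (CGM)
time series.

Conventional glycemic-variability metrics (SD, %CV) summarize only the
*amplitude* of glucose excursions. Two CGM traces with the same mean and
%CV can nonetheless differ profoundly in their *dynamics* — one jittering
rapidly around a tight baseline, the other drifting through long smooth
excursions. `glucodyn` quantifies both sides for clinical researchers
working with sensor glucose data, implementing three complementary
variability domains alongside the conventional metrics:

- **Geometric** — lagged Poincaré plots of the pairs (G(t), G(t+Δt)),
  Δt = 60 min by default. The dispersion perpendicular to the identity
  line is `SD1 = SD((x − y)/√2)`, along it `SD2 = SD((x + y)/√2)`, and the
  fitting ellipse has shape `SFE = SD2/SD1` and area
  `AFE = π·SD1·SD2` (mmol²/l²).
- **Information** — multiscale sample entropy. The series is coarse-grained
  at scales τ = 1..5 (non-overlapping window means, length ⌊N/τ⌋); at each
  scale `SampEn(m = 2, r = 0.15·SD)` = −ln(A/B) is computed with the
  tolerance fixed from the original series, and the **complexity index**
  is the sum over scales. Loss of complexity accompanies impaired glucose
  regulation.
- **Fractal scaling** — detrended fluctuation analysis. The mean-centred
  series is integrated, split into boxes of n points, linearly detrended
  per box, and the RMS residual F(n) is regressed on n in log–log space,
  giving a short-range exponent **α1** (n = 4–16, ≈ up to 1.25 h at 5-min
  sampling) and a long-range exponent **α2** (n = 16–144) split at the
  crossover n = 16.

A synthetic-cohort generator (exact Davies–Harte fractional Gaussian noise
plus circadian/meal structure and sensor noise, affinely rescaled to target
mean and %CV) makes every stage testable end to end, and a statistics layer
reproduces the usual cohort workflow: ANOVA with Holm-corrected pairwise t
tests, Spearman correlation matrices across the index domains, standardized
multiple regression of time-in-range on the indices with VIF and
Durbin–Watson diagnostics, and paired before/after comparisons.

## Worked example

```r
library(glucodyn)

gs <- generate_cgm(cgm_profile_preset("T1D"), n_points = 576, seed = 7)
compute_gv(gs)
poincare_descriptors(gs)
mse_index(gs)
dfa_exponents(gs)
```

```
<gv_metrics> mean 8.02 mmol/l, SD 2.90, CV 36.2%, TIR 11.5 h/day (276/576 in [3.9, 8.9])
<poincare_result> lag 60 min (12 samples), 564 pairs
  SD1 1.748  SD2 3.732  SFE 2.135  AFE 20.497 mmol^2/l^2
<mse_result> m=2, r=0.4355 (0.15 x SD), scales 1..5
  SampEn: 1.740 1.742 1.593 1.872 1.551
  complexity index: 8.497 nats
<dfa_result> 21 box sizes n in [4, 144]
  alpha1 = 1.126 (n 4-16, R2 0.991)   alpha2 = 1.278 (n 16-144, R2 0.976)
```

Read top to bottom: this simulated type-1-diabetes-like trace spends only
11.5 h/day in the 3.9–8.9 mmol/l target band with high amplitude
variability (CV 36%). Its Poincaré cloud is strongly elongated
(SD2 ≫ SD1, ellipse area ≈ 20 mmol²/l²), its complexity index is well
below what a non-diabetic-like profile produces (≈ 10.3 with the `"ND"`
preset), and both DFA exponents exceed 1, i.e. the trace scales like a
strongly persistent process. The same metrics for a whole simulated cohort,
joined to subject covariates, come from:

```r
co  <- generate_cohort(cohort_spec(list(ND = 12, T2D = 143, T1D = 22), seed = 1))
tab <- compute_cohort_table(co$series, co$subjects)
compare_groups(tab, "complexity_index")
tir_models(tab, index_column = "sd2")
```

`run_pipeline()` wires these stages together (simulate → QC → metrics →
statistics → CSV/JSON report with a manifest of every tunable), and
`inst/scripts/glucodyn.R` exposes it to the shell.

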