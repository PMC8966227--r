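---
title: "The QRS/QTc ratio as a ventricular-arrhythmia risk marker: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The QRS/QTc ratio as a ventricular-arrhythmia risk marker: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrsqtc)
```

## The scientific problem

Citalopram and escitalopram block the hERG potassium channel and prolong
ventricular repolarization. A long rate-corrected QT interval (QTc) is the
textbook marker of torsade-de-pointes (TdP) risk, but in practice QTc alone
discriminates poorly: many exposed patients with long QTc never develop
ventricular tachycardia or fibrillation (VT/VF). At higher concentrations
these drugs also block voltage-gated sodium channels, widening the QRS
complex — an effect that appears to be protective, on the same principle as
class-I antiarrhythmics. The ratio of the two durations,

$$\mathrm{ratio} = \frac{\mathrm{QRS\ (ms)}}{\mathrm{QTc\ (ms)}},$$

captures the balance: a *low* ratio (narrow QRS over a long QTc) marks
disproportionate repolarization delay and elevated arrhythmia risk, while a
high ratio marks co-occurring conduction slowing that offsets it.

`qrsqtc` packages a complete, reproducible analysis of this marker on a
cohort of sixteen published case reports of citalopram/escitalopram exposure
(ships as `load_cohort()`), together with the statistical pipeline used on
such small cohorts, a threshold classifier, a synthetic-cohort generator for
calibration and power work, and a minimal ECG synthesis/delineation module
that emulates the measurement step behind the tabulated intervals.

## The cohort and its conventions

The packaged cohort is the entire published dataset: 16 adults (11 F / 5 M,
ages 20–89), 12 intoxications and 4 therapeutic-dose exposures, 7 of whom
developed VT/VF after the admission ECG. Each case carries demographics,
exposure details (dose, serum concentration, co-ingestants — missing values
are `NA`, never zero) and the admission-ECG intervals (QRS, QT, QTc, heart
rate).

Three conventions were fixed by inspecting what reproduces the published
tabulations, and they propagate through every default in the package:

* **Population SD.** The tabulated mean ± SD pairs are reproduced only when
  the SD divides by $n$ rather than $n-1$ (e.g. QTc 606 ± 78 in the VT/VF
  group, QRS 122 ± 23 outside it; the sample SD gives 85 and 25).
  `describe_values()` therefore defaults to `sd_mode = "population"`.
* **Half-up rounding at two decimals.** All sixteen tabulated QRS/QTc values
  equal `round_half_up(QRS/QTc, 2)` of the tabulated QRS and QTc columns
  (85/515 = 0.16504… is reported as 0.17; banker's rounding would give
  0.16 for exact ties). Cohort-level functions default to this "as-published"
  precision (`ratio_digits = 2`); full precision is available everywhere via
  `ratio_digits = NULL` and is the default for synthetic cohorts. Group means
  agree at printed precision under either convention.
* **Reported values take precedence.** Reproduction statistics use the
  tabulated QRS/QTc/HR columns as-is, never recomputed quantities — the
  original analysis was performed on the reported numbers.

### Which correction formula?

The source reports do not name their QT correction. Recomputing QTc from the
tabulated QT and heart rate identifies Bazett ($QTc = QT/\sqrt{RR}$): the
case recorded at heart rate 60 matches exactly, and five further cases match
within about 1 ms. Bazett is therefore the package default; Fridericia,
Framingham and Hodges are included for sensitivity analysis only.

`audit_qtc_consistency()` makes the remaining disagreement explicit. At a
±6 ms tolerance, five of the sixteen reported QTc values cannot be
reproduced from their own QT and heart rate under any of the four standard
formulas (discrepancies of +11 to +98 ms):

```{r audit}
audit <- audit_qtc_consistency(load_cohort(), formula = "bazett",
                               tolerance_ms = 6)
audit[audit$flagged, c("case_id", "qtc_reported", "qtc_recomputed",
                       "discrepancy_ms")]
```

These are inconsistencies inside the source case reports (most plausibly a
transcribed QT, or a QTc measured on a different beat or lead than the QT);
the analysis keeps the reported QTc, per the precedence rule, and the audit
simply documents them. The 6 ms default tolerance is deliberately tight —
about three samples at a routine 500 Hz ECG sampling rate — so that it
separates rounding noise (≤ 1 ms in the consistent cases) from genuine
irreproducibility.

## The statistical pipeline

`compare_groups()` applies, per variable, the pipeline appropriate for a
two-group comparison of a small normally-distributed cohort: per-group
descriptives, Shapiro–Wilk normality per group, a Brown–Forsythe
(median-centred Levene) test of equal variances, and — conditional on that
gate — Student's pooled-variance two-tailed t-test with
$df = n_1 + n_2 - 2$, at $\alpha = 0.05$. Welch's test is available
(`var_equal = FALSE`) but is not the default, because the variance gate is
part of the published procedure.

```{r compare}
compare_all_groups(load_cohort())[, c("variable", "mean_yes", "sd_yes",
                                      "mean_no", "sd_no", "p_value",
                                      "significant")]
```

The ratio separates the outcome groups (p ≈ 0.00037), more decisively than
QRS (p ≈ 0.010) or QTc (p ≈ 0.016) alone, and heart rate does not differ
(p ≈ 0.75). Two recomputation caveats are worth recording:

* the tabulated VT/VF-group ratio SD of 0.02 is not reproducible — the
  population SD of the seven tabulated ratios is 0.027, which rounds to
  0.03; only the group means are treated as reproduction surfaces for this
  variable;
* the blanket claim that *all* variables pass normality does not quite hold:
  QTc in the non-VT/VF group has Shapiro–Wilk p = 0.010 (every other
  group/variable combination passes). The pooled t-test is retained for that
  variable regardless, again because the reproduced procedure is fixed; the
  exact permutation test used as a cross-check in the test suite gives an
  essentially identical p-value, so the conclusion is insensitive to the
  normality assumption.

Degenerate inputs follow explicit conventions rather than NaN propagation:
two identical constant groups give $t = 0, p = 1$ (and Brown–Forsythe
$F = 0, p = 1$); constant groups with different means are an error; groups
with fewer than three cases are rejected with the group named.

Box-plot summaries for the figures use the median, 25th/75th and 5th/95th
percentiles under the linear-interpolation quantile convention
(`stats::quantile` type 7), the most common default; the figures are
presentational and no acceptance decision reads them.

## The threshold classifier

`classify_risk()` predicts high risk when ratio < 0.2, with a *strict*
inequality: a ratio of exactly 0.2 is low-risk. The threshold is imported
from earlier hypothermia work where values below 0.2 marked risk of
hypothermic cardiac arrest; it was **not** fitted to this cohort, and the
strict boundary follows the wording "below 0.2" (it also classifies the one
cohort case sitting exactly at 0.20, who had no VT/VF, correctly).

On the packaged cohort the rule identifies all seven VT/VF cases
(sensitivity 1.0) at one false positive (specificity 8/9 ≈ 0.89).
`threshold_sweep()` traces sensitivity/specificity over any threshold grid;
sensitivity is non-decreasing and specificity non-increasing in the
threshold by construction. With $n = 16$, confidence intervals around these
proportions would be decorative; none are reported, and no claim of external
validity is made.

## The synthetic-cohort generator

`generate_cohort()` exists so every downstream stage can be exercised, and
its calibration checked, without any external data. Its defaults *are* the
cohort's estimated conditions: QRS 90 ± 14 ms and QTc 606 ± 78 ms in the
VT/VF group (n = 7), QRS 122 ± 23 ms and QTc 508 ± 55 ms outside it (n = 9),
heart rate 82 ± 22 bpm shared across groups (it did not differ between
outcomes). Design choices, in decreasing order of consequence:

* **QRS and QTc are drawn independently within group.** The source data
  report no covariance, so independence is the minimal assumption. If the
  true within-group correlation is negative, the ratio's variance is larger
  than simulated and the default generator is mildly optimistic about power.
* **Internal consistency by construction.** QT is back-computed from QTc and
  heart rate by inverting Bazett ($QT = QTc\sqrt{60/HR}$), so a Bazett audit
  of any synthetic cohort flags nothing — synthetic records never
  self-contradict the way five of the real case reports do.
* **Truncated-Gaussian sampling by whole-record rejection** to the interval
  invariants (QRS ∈ [40, 300] ms, QTc ∈ [200, 800] ms, HR ∈ [30, 200] bpm,
  QT ∈ [200, 800] ms and QRS < QT): simple, exact, and cheap at these scales
  (about 10⁴ records per second); a spec that rejects 10⁴ consecutive
  attempts for one record is reported as an error rather than looping
  forever.
* **Labels** follow the generating group by default; a logistic model
  (`label_model = "logistic"`) is available with default coefficients
  anchored so that P(VT/VF) ≈ 0.9 at ratio 0.15 and ≈ 0.1 at ratio 0.24 —
  the two group means. The coefficients are stored in the spec object (a
  JSON-serialisable config), not hard-coded.

What the generator deliberately does **not** emulate: measurement error in
the intervals, the reporting heterogeneity the audit exposes, missingness in
dose/serum, co-ingestant effects, or any dose–concentration–interval
pharmacokinetics. Passing tests on synthetic cohorts therefore demonstrate
that the *pipeline* is correct and calibrated, not that the biological claim
generalises.

Calibration evidence, recomputed by the test suite at fixed seeds:
`power_simulation()` at the default effect size (about 2.4 pooled SDs
separation in the ratio) gives power ≈ 0.98 at n = 7 vs 9 — context for the
very small p-value the 16-case cohort produced; under a null spec with
identical group parameters, the pipeline's type-I error over 2,000 simulated
cohorts is within Monte-Carlo error of 0.05 and the p-values are uniform
(Kolmogorov–Smirnov check); parameter recovery at 500 per group is within
3 standard errors, and recovered SDs at 10⁴ per group are within 5% of the
generating values (truncation compresses the heart-rate SD by about 4%,
visibly but within that band).

## ECG synthesis and delineation

The case reports computed their intervals from attached ECG recordings; no
algorithm is given. The `synthesize_ecg()` / `delineate()` /
`measure_case()` trio reconstructs that step at desk scale so the
measurement contract is testable. The waveform model is a sum of Gaussian
bumps (P, Q, R, S, T) — deliberately minimal: the module tests measurement,
not cardiac physiology.

Geometry is fixed so the *constructed* intervals are exact: the Q and S
bumps sit 15% and 85% of the way through the nominal QRS (widths QRS/18,
compensating the threshold-crossing bias of the delineator so detected
bounds land on the nominal ones), the R bump at mid-QRS with width QRS/7,
and the T bump is placed so that the tangent at its steepest downslope
crosses baseline exactly at QRS-onset + QT — the tangent method being the
standard manual convention in QT measurement, hence the most faithful
stand-in for case-report readings. Defaults: 500 Hz sampling, eight beats.
Layout requires QT − QRS ≥ 150 ms and QT ≤ 75% of the RR interval; outside
that the T wave is not separable and synthesis refuses.

Delineation uses standard operators and only *relative* thresholds, making
it invariant to amplitude scaling: R peaks above half the signal maximum;
QRS bounds where the absolute first derivative crosses 5% of its within-beat
maximum, a bound being closed by a ≥ 16 ms quiet run; T-end by tangent
extrapolation to baseline. Numerical hardening for noisy signals: the signal
is smoothed with a 5-point binomial kernel (twice), the derivative is a
±3-sample central difference, and the slope threshold is floored at five
times the 25th percentile of the within-beat |dV/dt| (noise-dominated,
because most of a beat is isoelectric). The first and last beats are
dropped; medians are taken across the remaining beats (≥ 3 required) — the
median-over-beats convention is this module's choice, not documented
practice in the source reports.

On a noise-free 4 × 5 grid (QRS 70–160 ms × QT 350–700 ms at heart rate 60)
recovery is within 6 ms for QRS and 2.5 ms for QT, comfortably inside the
±10/±15 ms contract the tests enforce; mean error grows monotonically with
added noise (checked at noise SD 0, 0.02 and 0.05 of the R amplitude).

## Problem sizes and runtimes

All analyses on the 16-case cohort complete in milliseconds. The simulation
studies in the test suite use 200 seeds for the significance-rate check,
1,000 replicates for power, 2,000 seeds for null calibration, and the
20-point delineation grid — sizes chosen so the whole suite runs in about a
minute while leaving Monte-Carlo error well below the margins being
asserted.

## Known limitations

* Sixteen retrospectively collected case reports, with publication bias by
  construction; the package reproduces the analysis, it cannot strengthen
  the evidence.
* The 0.2 threshold is imported, not derived; no external validation is
  implied or tested.
* Five reported QTc values are internally inconsistent with their QT and
  heart rate; the tabulated serum-concentration mean could not be reproduced
  from the tabulated per-case values under any subset we could identify, and
  one "therapeutic" dose (0.08 g) exceeds the regulatory 40 mg ceiling —
  all retained as published, surfaced by the audit and documented here
  rather than corrected.
* The synthetic generator's independence and Gaussian assumptions are
  modelling choices (see above), and the ECG module handles clean synthetic
  morphology only — no baseline wander, muscle artifact, U waves, biphasic
  T waves or multi-lead logic.
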