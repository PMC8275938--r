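---
title: "Computing and evaluating head injury criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing and evaluating head injury criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headcrit)
```

## The problem

When a pedestrian, cyclist or electric-two-wheeler rider is struck by a
car and their head hits the windshield, the injury outcome is graded
clinically on the Abbreviated Injury Scale (AIS, 0–6), with the maximum
over the head region reported as MAIS. Accident reconstruction with
finite-element and multibody human models produces, for each case, the
head centre-of-gravity kinematics (linear and rotational acceleration,
rotational velocity) and — when an FE brain is included — per-element
strain and pressure histories of the brain. Injury criteria compress
these time histories into scalars intended to predict the injury grade.
This package computes the standard criteria of both families and
quantifies how well each one tracks the recorded injury scores.

## Kinematic criteria

All five criteria operate on the head-COG channels stored in a
`kinematics_record`:

* **HIC15** — `max over [t1, t2] of (t2 − t1) · (mean resultant linear
  acceleration in g)^2.5` with window length at most 15 ms. We implement
  the window cap as `≤ 15 ms` (the standard HIC15 definition) rather
  than exactly 15 ms; a `hic_window_max` override gives HIC36. Window
  endpoints are restricted to sample times and no interpolation is
  performed between samples.
* **RIC** — the same functional applied to the resultant rotational
  acceleration, window capped at 36 ms. We use `≤ 36 ms` for symmetry
  with HIC; for unimodal impact pulses the `≤` and `=` conventions
  coincide because the windowed mean is maximised by the widest
  admissible window around the peak.
* **GAMBIT** — `((a_max/a_cr)^n + (α_max/α_cr)^m)^(1/s)` on the peak
  resultants, with `a_cr = 350 g`, `α_cr = 12 000 rad/s²`. The exponents
  are not uniquely standardised in the literature; we default to
  `n = m = s = 2`, the most commonly published form, and expose all
  three in `criterion_constants()`.
* **HIP** — the peak of the instantaneous mechanical power
  `P(t) = m Σᵢ aᵢ(t)∫aᵢ dτ + Σᵢ Iᵢᵢ αᵢ(t)∫αᵢ dτ` with `m = 4.5 kg`,
  `I = (0.016, 0.024, 0.022) kg·m²`, reported in kW. The signed maximum
  is taken: power is negative during rebound and taking an absolute
  value would overstate the inflow of energy.
* **BrIC** — `ω_max/ω_cr + α_max/α_cr` with `ω_cr = 140 rad/s`. This is
  the resultant-peak form; axis-specific critical values are out of
  scope.

Units are declared, never guessed: linear acceleration may be stored in
g or m/s² and each criterion converts lazily through the record's
`g_value` (default 9.81 m/s² per g, overridable to 9.8 to follow sources
using that rounding; the conversion factor used is carried in every
result's `params`).

### Numerical choices

Integrals use the trapezoidal rule — second-order accurate, exact for
piecewise-linear signals, and robust to non-uniform time vectors (which
are accepted everywhere except in frequency-domain filtering). The
HIC/RIC maximisation runs on the cumulative trapezoid integral with one
vectorised pass per left endpoint, which is exactly the exhaustive
sample-aligned window search; the test suite retains a separate
all-pairs outer-matrix implementation as an oracle and requires exact
(tie-aware) agreement of the maximised value on randomised pulses. When
several windows tie, the earliest left endpoint wins; ties only affect
the reported window, never the value.

Channel-class (CFC) low-pass filtering — the crash-test convention of a
2-pole Butterworth run forward and backward for a phaseless 4-pole
response — is provided but **never applied implicitly**: the upstream
simulation outputs this package was designed around are not described as
filtered, so the default class is `none`. The filter pads by odd
reflection at both ends before the forward–backward pass, which removes
edge transients and makes the DC gain exactly 1 on constant signals.

## Deformation criteria

`element_field_history` stores per-element volumes (treated as constant
initial volumes — no time-varying geometry is consumed) with
element × timestep strain and pressure arrays.

* **MPS** is the global maximum of first principal strain over elements
  and times, not a volume percentile: severe windshield-impact cases
  show MPS well above 1.0, which a percentile-capped definition applied
  to typical fields would not produce.
* **CSDM** at threshold `x` is the volume fraction of elements whose
  strain exceeds `x` at *any* timestep (once-exceeded semantics, hence
  invariance to timestep reordering). Conventional thresholds are 0.15
  and 0.25.
* **DDM** is the volume fraction whose pressure drops below −100 kPa
  (tension), with pressure stored positive-in-compression.

Exceedance comparisons are strict (`>` for strain, `<` for pressure):
an element sitting exactly at the threshold is excluded, consistent with
"exceeding" a threshold; both are switchable to inclusive via the
`strict` argument. Strains are consumed as provided by the upstream
solver (first principal Green–Lagrange strain); no tensor computation is
performed here.

## Evaluation against injury records

`pearson_r()` implements the product-moment sample correlation directly
from its definition and refuses constant input rather than returning 0
or NA. `evaluate_criteria()` joins a criterion table with injury records
on `case_id`, correlates each criterion column against MAIS, and ranks
by `|r|`. MAIS is deliberately treated as a numeric 0–6 scale — that is
how such evaluations are conventionally reported — and a Spearman option
is offered for sensitivity analysis but excluded from reproduction runs.
MAIS analyses use all 31 packaged cases; sub-injury analyses (DAI,
contusion) are restricted to the cases whose sub-injury AIS is recorded
(8 and 7 cases respectively), with missing AIS excluded listwise only
there.

Risk curves (`risk_curve()`, logistic or Weibull) map criterion values
to injury probabilities. Their parameters are **configuration data**:
the published brain-injury risk curves this mirrors are cited in the
literature without printed parameter sets, so the package does not
hard-code them. The shipped YAML (`risk_curves_default.yaml`) is
labelled a synthetic approximation of the published shapes, exists only
so `risk_report()` runs out of the box, and is excluded from all
quantitative checks. Consequently the per-case probability figures of a
risk analysis are only as meaningful as the parameterisation supplied.

## Packaged cohort and reproduction

The package ships the 31-case cohort tables as plain-text resources:
accident metadata, AIS/MAIS records, the five kinematic criterion values
per case, and the DAI and contusion sub-tables. They are transcribed
verbatim — including internal oddities such as a case whose MAIS exceeds
every recorded sub-injury AIS (injuries outside the DAI/contusion pair)
— with md5 checksums enforced at load. `reproduce_table5()` recomputes
the criterion-vs-MAIS correlations from the packaged tables and prints
them beside the published coefficients:

```{r}
reproduce_table5()$comparison
```

The recomputed ranking is HIC > HIP > RIC > BrIC > GAMBIT.

## Synthetic data: what it emulates and what it does not

The study's raw reconstruction outputs are not public, so generators
stand in for them with *known ground truth*; every generator is a pure
function of its spec, seed included.

* `synth_pulse()` builds impact-like head pulses (constant, haversine
  `A·sin²(πt/T)`, triangular) with per-channel-group peaks and
  directions. The haversine is the standard smooth idealisation of a
  crash pulse. For noiseless pulses the ground truth attaches closed
  forms where they exist (all five criteria for the constant shape;
  peak-based GAMBIT/BrIC for every shape) and dense-grid numeric truth
  computed from the exact shape integrals (flagged `"numeric"`) for
  HIC/RIC/HIP of smooth shapes. Default pulse scales (~100 g, ~20 ms,
  ~5000 rad/s²) sit in the range spanned by windshield-impact
  reconstructions.
* `synth_element_field()` hits its target CSDM fractions *exactly by
  construction*: elements are partitioned into strain bands and each
  band receives exactly its target share of the total volume (lognormal
  volumes are renormalised within bands; equal volumes require targets
  that are multiples of `1/n`, otherwise the error names the nearest
  reachable fraction). Per-element pressure extremes default to
  `N(−40, 35²)` kPa, placing most of the volume above the −100 kPa
  threshold so DDM stays small — the regime observed in windshield
  impacts.
* `synth_cohort()` draws a standard-normal latent severity, discretises
  it into MAIS at fixed cut-points whose class probabilities mirror the
  packaged cohort's MAIS distribution (3, 7, 5, 2, 5, 5, 4 cases at
  MAIS 0–6), and sets the criterion to `link(MAIS)` plus Gaussian noise
  whose standard deviation is derived from the target correlation, so
  the population criterion–MAIS Pearson correlation equals the target
  exactly for a linear link. The empirical correlation then converges at
  the usual `≈ (1 − r²)/√n` rate.

What passing tests on synthetic data do **not** show: the pulses are
idealised single-lobe shapes, not the multi-impact, non-axial histories
real reconstructions produce; element fields have a shared time profile
rather than spatially propagating waves; and the cohort model imposes a
monotone criterion–severity link by construction. Agreement on synthetic
data validates the *computations*, not the biofidelity of any criterion.

## Problem sizes and tolerances

The test suite exercises: 100 randomised pulses of up to 500 samples for
the window-search oracle equivalence (value agreement to 1e−10
relative); 100 constructed element fields of 10–150 elements for the
deformation invariants (targets exact to 1e−12); a 5000-case synthetic
cohort for association recovery (±0.03, the sampling standard error
scale at that n); and the packaged 31-case tables for the correlation
reproduction (±0.01 of the published coefficients). Closed-form
criterion values are required to 6 significant figures. These sizes were
chosen to make the statistical tolerances meaningful while keeping the
suite quick to run.

## Known limitations

* The packaged cohort is small (31 cases, 8/7 for the sub-studies);
  correlation coefficients at n = 31 carry wide sampling uncertainty,
  and the package deliberately reports none (the evaluation convention
  it mirrors reports none either).
* Risk-curve parameters are user-supplied; no refitting is provided.
* No solver-native binary readers: element fields and kinematics enter
  through the documented delimited-text formats only.
* MAIS-as-numeric is a modelling convention, not a claim that AIS
  intervals are equal; the Spearman option exists to probe that
  assumption.
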