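---
title: "Models and methods behind glucofuzz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glucofuzz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucofuzz)
```

glucofuzz analyses readings from a near-infrared glucose sensor that
measures optical attenuation through the fingertip (and, as a second
channel, through tears). This vignette documents the models, the
defaults and the reasoning behind the choices that were genuinely open.

## Clarke Error Grid classification

A pair (reference *R*, estimate *E*), both in mg/dL, is graded
clinically by the Clarke Error Grid. The grid's zone boundaries are
standard but rarely printed as inequalities, so `ceg_classify()` fixes
the widely used Clarke (1987) set, evaluated in the order A, E, C, D
with B as the fall-through:

- **A**: (E ≤ 70 and R ≤ 70) or 0.8·R ≤ E ≤ 1.2·R
- **E**: (R ≥ 180 and E ≤ 70) or (R ≤ 70 and E ≥ 180)
- **C**: (70 ≤ R ≤ 290 and E ≥ R + 110) or (130 ≤ R ≤ 180 and E ≤ 1.4·R − 182)
- **D**: (R ≥ 240 and 70 ≤ E ≤ 180) or (R ≤ 70 and 70 ≤ E ≤ 180)
- **B**: otherwise.

The fixed evaluation order makes exact boundary points deterministic.
Inputs must be finite, positive and ≤ 1000 mg/dL (a sanity bound well
above the physiological range).

### The continuous severity score

The fuzzy predictor needs more than the discrete label: it needs *how
far* a reading sits from clinical accuracy, as a number in [0, 1] with
0 on the identity line and values near 1 deep in zone E. Only the
endpoints of this scale are externally fixed; the interpolation is a
design choice. glucofuzz uses

$$s = \frac{z + d}{5},$$

where *z* is the zone ordinal (A = 0 … E = 4) and *d* ∈ [0, 1) is the
fractional depth of the estimate within its zone's interval on the
estimate axis at that reference, measured away from the identity line
(`ceg_zone_intervals()` supplies the partition; its default axis
maximum is 600 mg/dL, the conventional plotting range). This choice is
piecewise linear, cheap, and — verified by sweep tests — non-decreasing
along every vertical ray moving away from the identity line, which is
the property the downstream fuzzy rules rely on. Note that severity
jumps where zone ordinals jump (e.g. from the top of an A interval at
s = 0.2 directly into a D interval at s = 0.6); monotonicity, not
continuity, is the contract.

## The Mamdani error predictor

The fuzzy system maps (sensor voltage, CEG severity) to a predicted
relative error in percent — the tolerance to attach to a reading when
no reference meter is present. It is deliberately the canonical
Mamdani construction: triangular membership functions, AND = min,
implication = min (clipping), aggregation = pointwise max, and sampled
centroid defuzzification

$$\hat{e} = \frac{\sum_i x_i\,\mu(x_i)}{\sum_i \mu(x_i)},$$

with 1001 evaluation points over the output domain [0, 100] %. Tests
check the sampled centroid against trapezoidal integration at 100×
resolution (agreement within 0.1) and against analytic triangle
centroids.

The voltage input carries four labels — LoGl, MiGl, MoGl, HiGl (low to
high glucose) — and the severity input and error output five labels
A–E each, mirroring the grid zones. Exact breakpoints are not
published for the instrument this emulates, so the defaults are
declared, not inferred:

- voltage domain [1.0, 4.5] V, four evenly spaced triangles with
  touching feet and shoulders at the ends (the domain covers the
  recorded fingertip span 1.22–3.5 V and tear readings up to 4.46 V);
- severity domain [0, 1], five even triangles peaked at 0, 0.25, 0.5,
  0.75, 1;
- error domain [0, 100] %, five even triangles peaked at 0, 25, 50,
  75, 100.

The rule base is the complete 4 × 5 grid with the consequent equal to
the severity antecedent's label for every voltage label ("if severity
is in zone *Z*, the error is *Z*-sized"), which is the only complete
base consistent with the two published example rules and keeps the
configuration error-free by construction: completeness is validated
when the system is built, not at inference time. With this base the
predicted error is non-decreasing in severity at every fixed voltage
(checked numerically on a 0.01 grid).

Out-of-domain inputs are clamped to the domain rather than rejected —
field measurements can slightly exceed the calibration span — and the
clamp is surfaced to callers (`run_analysis()` counts clamped rows in
its summary). A consequence of centroid defuzzification worth knowing:
the output can never reach 0 or 100 exactly (the centroid of a clipped
corner triangle lies inside its support), so even a perfect reading on
the identity line receives a nonzero tolerance — about 8 % with the
defaults, plus the contribution of neighbouring labels. The per-row ±
values produced with these defaults are therefore systematically wider
than those published for the original instrument, whose membership
breakpoints were tuned on the authors' own measurements and are not
available; the defaults here are honest placeholders that preserve
every structural property (ordering, bounds, determinism), and any
tuned system can be supplied as a YAML/JSON file
(`read_fuzzy_system()`), which round-trips bit-exactly.

## Calibration

The photodetector produces a voltage proportional to received light,
so the minimal calibration consistent with the chain is affine per
channel; `cal_fit()` is ordinary least squares, with a joint fit
`glucose ~ 1 + v_finger + v_tear` when both channels are selected.
How the original device fuses the two channels is not documented, so
both single-channel and joint modes are exposed rather than guessed
at. The default target is the reference meter; fitting against the
device's own displayed estimates is supported to reproduce the
published table (on those 15 rows the finger-channel fit predicts the
device values with a mean absolute residual of 7.7 mg/dL).
Degenerate designs — fewer records than coefficients + 2, constant or
collinear voltages — are rejected with a fit error. Predictions are
clipped below at 1 mg/dL with a warning.

## Sensor simulator

The forward model composes:

1. a linear glucose→absorption map μ_a(g) = μ_a0 + k_abs·g;
2. Bouguer–Lambert attenuation I = I₀·e^(−μ_eff·L) with, by default,
   μ_eff = 2·μ_a·(μ_a + μ_s′) exactly as the instrument's
   documentation states it; standard diffusion theory would use
   √(3·μ_a·(μ_a + μ_s′)), and both forms are implemented
   (`formula = "printed"` / `"diffusion"`), the choice being recorded
   in cohort metadata;
3. a transimpedance responsivity and the non-inverting gain stage
   G = 1 + R₂/R₁.

PWM drive (1 kHz), emitter wavelength (940 nm; the photocoupler part
is specified at 980 nm) and the RC low-pass are hardware-stability
devices, carried as metadata only — they do not affect a steady-state
voltage computation.

The free constants are pinned by anchoring: with μ_s′ = 1 mm⁻¹, path
length 5 mm, μ_a = 0.30 mm⁻¹ at the low anchor and a 10 kΩ/30 kΩ gain
stage, `default_sensor_chain()` solves k_abs, μ_a0 and the responsivity
in closed form so the chain passes exactly through the two extreme
recorded fingertip measurements, (103 mg/dL, 1.22 V) and
(175 mg/dL, 3.50 V). k_abs comes out negative — higher glucose, less
attenuation, higher voltage — matching the direction of the recorded
signals. Over glucose 80–200 mg/dL the resulting chain spans roughly
0.86–4.9 V; the exponential widens the span beyond the anchor
interval, which is why simulated voltages saturate at the 5 V supply
rail in the cohort generator.

### Cohort generation

`cohort_spec()` defaults encode the study protocol: 30 participants,
half diabetic, 12 measurements each at 15-minute intervals (4
pre-meal, 8 post-meal), 360 records. Group glucose distributions are
healthy 115 ± 10 and diabetic 165 ± 10 mg/dL. Participant baselines
are drawn from those normals *truncated at ±1 sd*: the recorded cohort
shows tight per-group spreads (healthy 103–128, diabetic
155–175 mg/dL, non-overlapping), and unbounded normal tails at these
means would not reproduce that separation. The post-meal excursion is
a deterministic decaying profile scaled per group — peak +8 mg/dL for
healthy participants (intact regulation keeps recorded healthy values
in a narrow band even after meals) and +40 mg/dL for diabetic ones —
plus within-participant noise of 2 mg/dL per repeat. Channel noise
defaults: 0.02 V on the finger voltage; the tear channel is affine in
the finger voltage (slope 1.24, offset −0.16 V, fit to the recorded
paired channels) with 0.1 V noise. The simulated reference-device
estimate applies a 5 % relative error to the true glucose. Everything
is reproducible from the spec's seed; the generator restores the
caller's RNG state, and voltages are recorded at 6 decimals so cohorts
compare exactly across platforms.

With these defaults the healthy and diabetic fingertip-voltage ranges
are disjoint, mirroring the recorded separation (1.22–2.25 V vs
2.9–3.5 V). That separation is *not* robust to arbitrarily large noise:
at 0.1 V channel noise the extreme draws of 360 records can bridge the
gap, so the disjointness test runs at the generator's defaults.

What the simulator does not emulate: photon-transport realism
(single-path Beer–Lambert only), spectral effects, sensor drift,
temperature, skin-tone or perfusion covariates, and any correlation
structure beyond the participant baseline + meal profile. Passing
tests on simulated cohorts therefore demonstrate the chain's internal
consistency, not clinical performance on real skin.

## Pipeline conventions

`run_analysis()` processes a measurement table row-wise: estimate
glucose (calibration or pass-through of the device's column), classify
the (reference, estimate) pair, compute severity, predict the error
tolerance, and attach the interval *E* ± *E*·e/100 — the predicted
error is interpreted as a *relative* error, which matches how the
published per-row tolerances are presented, and the convention is
recorded in the run summary. The fuzzy output never shifts the point
estimate; it only widens or narrows the interval. Pass-through mode
reproduces the published tables; calibrated mode fits on the fly or
takes a saved model.

## Problem sizes and numerical choices

Test and acceptance workloads were sized to what the analyses need,
not more: exhaustive classification over the integer grid
[1, 600]² (360,000 pairs), 10,000 random points for the
interval-oracle cross-check, 100× dense integration for the centroid
oracle, 360-record cohorts for calibration recovery. Tolerances: 1e-9
for exact algebraic recovery, 0.1 (of a 0–100 output) for sampled vs
integrated centroids, 5 % for stochastic parameter recovery at
σ = 5 mg/dL noise. Ties and degenerate cases: boundary points resolve
by the fixed A, E, C, D, B order; zero-width severity intervals give
depth 0; an all-zero aggregated fuzzy curve (impossible under the
coverage invariant, reachable only with a broken configuration) raises
a "no rule fired" error rather than returning NaN.
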