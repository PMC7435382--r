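---
title: "Methods: barometer-based wearable spirometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barometer-based wearable spirometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barospiro)
```

This vignette is the package's own account of its methods: the physical
model and its assumptions, what the synthetic-breathing generator
emulates (and deliberately does not), the tunable parameters and their
defaults, the numerical choices, and the limitations a user should keep
in mind when carrying conclusions from synthetic tests over to real
recordings.

## 1. The physical model

A face mask with a rubber seal forms a chamber in front of the airway
that vents through an orifice (or through many filter pores, which is
equivalent: the total area cancels out of the final relation). Treating
the vent as a frictionless tunnel of area $S$ and applying the momentum
balance to the air accelerating through it gives the ideal relation

$$F \;=\; \operatorname{sign}(\Delta P)\, S\,\sqrt{2\,|\Delta P| / \rho},
\qquad \Delta P = P - P_\text{atmos},$$

implemented by `ideal_flow_from_pressure()` with defaults
$P_\text{atmos} = 101{,}325$ Pa, $\rho = 1.225$ kg·m$^{-3}$ (sea level,
15 °C) and $S = 2.826\times10^{-3}$ m$^2$. Its algebraic inverse
(`ideal_pressure_from_flow()`) is what the simulator uses to turn a
ground-truth flow into a chamber pressure; the round trip is exact to
machine precision.

`standard_flow_lps()` is the same relation collapsed to standard
conditions in L/s, $F = \pm 2.9\sqrt{|\Delta P|}$. The coefficient 2.9
is kept **exactly as conventionally printed** for this standard form and
is exposed as a parameter. Note an internal inconsistency worth knowing
about: re-deriving the coefficient from the stated $S$ and $\rho$ gives
$1000\,S\sqrt{2/\rho}\approx 3.61$, not 2.9 (and $S = 2.826\times10^{-3}$
m$^2$ corresponds to a 6 cm disk, while the reference spirometer's mesh
is usually quoted as 7 cm). We keep both values verbatim and do not
resolve the discrepancy; the closed form serves to understand the
square-root shape of the relationship, not to measure flow. Friction and
non-uniform chamber pressure are deliberately *not* modelled here — in
real use they are absorbed by the fitted calibration, which is the point
of the calibration stage.

The relation is odd and monotone: zero flow at equal pressures, outflow
(expiration, positive sign) for overpressure. Where a branch boundary
matters downstream, $x = 0$ is assigned to the positive branch.

## 2. The synthetic-breathing generator

No public recordings of paired (mask-barometer, spirometer) sessions
exist, so the generator produces them with exactly the statistical
structure the calibration chain assumes. A session per subject consists
of tidal breathing interleaved with 10 forced (FVC) maneuvers, each
separated by at least 5 tidal cycles, ending in a zero-flow tail
(defaults: 1 s; the protocol's "mask off" period) used downstream for
offset estimation.

**Waveforms.** Tidal cycles are paired half-sines scaled so inhaled and
exhaled volume both equal the tidal volume (zero net volume per cycle;
peak flow $\pi \cdot TV / T$ for cycle period $T$). A forced maneuver is
a maximal-inspiration half-sine of volume `fvc_total` followed by a
forced expiration. Two expiration templates exist:

* `rise = "instant"`: $F(t) = \mathit{PEF}\,e^{-t/\tau}$ with an
  instantaneous rise. Its vitals have closed forms
  ($FVC = \mathit{PEF}\,\tau(1-e^{-T/\tau})$,
  $FEV_1 = \mathit{PEF}\,\tau(1-e^{-1/\tau})$,
  $FEF_{25} = \mathit{PEF} - 0.25\,FVC/\tau$), which is what the test
  oracles use.
* `rise = "smooth"` (the session default): a half-sine onset
  (`rise_time`, default 0.12 s) into a brief near-peak plateau
  (`plateau_time`, default 0.15 s) before the exponential decline. Real
  forced expirations reach peak flow in roughly 0.1 s and hold within
  ~10 % of it for a few tenths of a second; an instantaneous step is not
  representative of the signals the conditioning chain (a ~0.2 s
  effective smoother, Section 3) was designed for. Vitals for this
  template are computed numerically from a 1 kHz sampling and attached
  as ground truth.

Maneuver effort is jittered per repetition (PEF and inspired volume
scaled by a uniform draw on $[1-2j, 1]$ with $j = 0.1$; $\tau$
symmetric). Real repeated maneuvers vary by about this much, and the
agreement metric (Section 5) divides by the spread of the vitals — a
cohort whose repetitions were identical would make that metric
degenerate, which is a property of degenerate data, not of the method.
The downward-only scaling keeps every maneuver within the profile's
stated peak flow.

**Ground-truth pressure–flow law.** Each subject carries a root-family
law $y = c^{+}\sqrt{x}$ / $y = c^{-}\sqrt{-x}$ with per-subject
coefficients (defaults around $0.17$ / $-0.14$ L·s$^{-1}$·Pa$^{-1/2}$) —
*not* the ideal physical model. Fitted real-world coefficients are an
order of magnitude below the ideal 2.9–3.6 because of friction and flow
unevenness, and the calibration stage must be tested against the
function family it assumes plus noise, not against an idealisation. The
coefficients vary only ±10 % across subjects in `random_profiles()`: the
law is chiefly a property of the shared mask/orifice geometry, and the
spread represents fit-and-seal differences between wearers. This spread
is what separates the inclusive and exclusive calibration schemes from
the individual one.

**Sensor model.** `flow_to_sensor_traces()` inverts the subject's law to
the true inside-mask overpressure, then applies, in order: a constant
per-sensor offset drawn uniformly from ±50 Pa (inter-sensor
manufacturing offsets are real but their magnitude is not documented;
±50 Pa is an assumption of this package), Gaussian read noise, and
quantisation to the output resolution (rounding, applied after noise).
Two datasheet-grade presets exist, both at 100 Hz: grade A (noise SD
0.2 Pa, resolution 0.18 Pa) and grade B (0.03 Pa, 0.016 Pa). The
reference spirometer channel is the truth flow at 50 Hz plus Gaussian
noise (SD 0.02 L/s) and a constant offset (0.01 L/s) — both assumed, not
documented, and both configurable down to zero.

**What the generator does not emulate:** airway mechanics
(compliance/resistance dynamics), cough or speech transients, turbulence
and flow unevenness inside the chamber beyond the static law, clock
drift between instruments, and temperature-driven sensor drift. Passing
tests therefore demonstrate that the *processing chain* is correct and
robust at datasheet noise levels — not that any particular hardware
reaches a particular clinical accuracy.

## 3. Signal conditioning

`make_conditioned_pair()` fixes the order of operations as: differential
pressure (inside minus outside, outside linearly interpolated onto the
inside timestamps) → subtract the tail offset → zero-phase smoothing →
two-sample-average downsampling to the reference rate → linear
interpolation of both channels onto a common 10 ms grid. The reference
flow receives only its own tail-offset subtraction — flow smoothing is
deliberately not applied, matching the stated processing of the pressure
channel only.

Choices worth recording:

* **Offset estimation** (`estimate_tail_offset()`) is the arithmetic
  mean of the final `tail_s` seconds (default 0.5 s) of the recording,
  when the mask is off and true flow is zero. Because the smoothing step
  is linear with unit DC gain, estimating the offset before or after
  smoothing is equivalent up to edge effects; the package subtracts
  before smoothing.
* **Zero-phase smoothing** (`zero_phase_smooth()`): a boxcar of
  `kernel = 10` samples applied forward then backward. A single-pass
  even-length boxcar cannot be zero-phase on the same grid; the
  forward–backward cascade has an exactly symmetric (triangular,
  unit-mass) impulse response, so peaks are attenuated but never
  shifted. Edges are reflect-padded by one kernel length, which keeps
  the DC gain at one in the offset-estimation tail. At 100 Hz the
  cascade's effective support is ≈0.2 s; this is the resolution floor
  for sharp expiratory peaks, and is why the generator's default
  maneuver template has a finite rise and plateau (Section 2).
* **Downsampling** (`downsample_two_average()`): consecutive-pair
  averaging with midpoint timestamps, 100 → 50 Hz, mirroring the
  hardware path; exact for affine signals. A trailing odd sample is
  dropped with a warning.
* **The 10 ms pairing grid** is kept verbatim from the source processing
  convention (half the 50 Hz device period). We follow it without
  endorsing the sampling-theorem justification sometimes attached to it;
  linear interpolation is used throughout, including onto this grid.

## 4. Calibration models

All three families map conditioned differential pressure $x$ (Pa) to
flow $y$ (L/s). Pressure is always in Pa: published coefficient tables
for such fits typically do not state the pressure unit, so any printed
coefficient sets should be read as layout examples rather than
transferable constants.

* **Root family** (`fit_root`): basis $\{x, 1, x^{1/2}, x^{1/3},
  x^{1/4}\}$ restricted per variant (`root2only` keeps only the square
  root; `root2` adds linear and constant; `root3`, `root4` add the cube
  and fourth roots), fitted independently on the two sign branches with
  the basis evaluated in $|x|$. The branches each carry an intercept and
  need not agree at zero; the discontinuity is accepted as part of the
  formulation, and $x=0$ joins the positive branch.
* **Polynomials** (`fit_poly`): one curve over the full signed range,
  degree 2–5, coefficients stored constant-first ($p_1$ is the
  intercept, $p_{d+1}$ multiplies $x^d$). Monotonicity is *not*
  enforced — polynomial fits genuinely lose it at the data-range edges —
  but `is_monotone()` is provided as a diagnostic.
* **Robust option**: "least absolute residual" is implemented as
  iteratively reweighted least squares with weights
  $1/\max(|r_i|, 10^{-6})$, iterated to a coefficient change below
  $10^{-8}$ or 50 iterations. This reproduces the standard robust
  curve-fitting option without depending on any particular toolbox.
* **Network** (`fit_mlp`): one sigmoid hidden layer of $N$ units with a
  linear output, on standardised inputs and targets. Training is
  full-batch Levenberg–Marquardt (damping $\lambda_0 = 10^{-3}$, ×10 on
  a rejected step, ÷10 on acceptance, abort above $10^{10}$ with a
  best-so-far warning), with a seeded 70/15/15
  train/validation/test split, uniform(−0.5, 0.5) initialisation,
  validation-MSE early stopping (patience 6, max 1000 iterations) and
  best-validation weights returned. These training details are
  conventional defaults — initialisation, damping schedule and patience
  are not prescribed by the method's description — and all are exposed
  as arguments. Everything is deterministic given the seed.

Goodness of fit (`gof_rmse`) is the RMSE between reference flow and
prediction over the fitting samples. Because the root variants are
nested, their training-set RMSE is non-increasing from `root2only`
through `root4` — asserted as a property in the test suite.

## 5. Vitals and the agreement metric

`compute_fvc_vitals()` derives, per maneuver: FVC (total expired
volume), PEF (maximum expiratory flow), FEV1 (volume expired in the
first second after time zero), FEF25 and FIF25 (expiratory/inspiratory
flow at the instant 25 % of FVC has been exhaled/inhaled, linearly
interpolated at the crossing). Time zero uses the standard
back-extrapolation convention — the tangent at the steepest point of the
volume curve (i.e. at peak flow) extended to the zero-volume axis. For
the instant-rise template this coincides with the expiratory onset,
which is what makes the closed-form oracles valid; whether a simpler
onset rule would behave differently is flagged, and back-extrapolation
is the deliberate choice. Maneuvers with under one second of expiration
return `NA` FEV1 with a warning.

Volume is computed two ways, both exposed: per-breath cumulative
trapezoidal integration (`cumulative_volume`, reset at each breath
boundary) and a trailing sliding-window integral
(`sliding_window_volume`, 0.5 s window, 10 ms step) that cannot
accumulate drift over long recordings. The continuous "volume"
agreement figure uses the sliding-window form; "trailing" rather than
centred is a documented choice where the wording is ambiguous.

Agreement is $\delta = \operatorname{rmse}(v_\text{ref} -
v_\text{pred}) / \max(\operatorname{range}(v_\text{ref}),
\operatorname{range}(v_\text{pred}))$, over all maneuvers of the
evaluation set (`delta_vitals`), or sample-wise over continuous signals
(`delta_signal`). Scheme evaluation (`run_scheme`):

* **individual** — one model per subject, tested on that subject;
* **inclusive** — one pooled model, tested on everyone;
* **exclusive** — a seeded random partition of *subjects* (never
  samples) into `n_folds` folds of near-equal size; fit on the rest,
  test on the held-out fold.

When a scheme yields several models, each component δ is computed
within its unit and the components are aggregated by root mean square.
The denominator range is taken over the whole evaluation cohort ("from
all participants") for the individual and inclusive schemes; for the
exclusive scheme the held-out fold's own range is the default
(`range_scope = "fold"`), with the cohort-wide range available as an
option — the convention is genuinely underdetermined, and fold-local
ranges are the more conservative reading of per-fold evaluation.

## 6. Numerical choices and degenerate inputs

* Linear least squares go through a QR decomposition; rank-deficient
  designs (e.g. all pressures identical) are rejected with a diagnostic
  rather than silently pseudo-inverted.
* Trapezoidal integration is used for all volumes (exact for affine
  flow on a uniform grid); interpolation is linear everywhere.
* Breath segmentation detects negative-to-positive zero crossings with
  a ±0.05 L/s hysteresis band, classifies a segment as forced when its
  peak exceeds 3× the session's median segment peak, and extends forced
  segments back to the preceding positive-to-negative crossing so the
  maximal inspiration belongs to the maneuver. All-zero flow yields an
  empty segmentation; near-zero-flow "loops" are rejected as degenerate.
* Quantisation in the sensor model rounds to the nearest resolution
  step after noise is added.
* All randomness flows from named integer seeds; per-subject and
  per-fold seeds are derived from the master seed by a fixed affine map
  below $2^{31}$. Identical inputs and seeds give byte-identical
  outputs, including the trained network.

## 7. Problem sizes in the test suite

The suite exercises the chain at sizes chosen to keep a full run around
twenty seconds while still covering every property: oracle-equivalence
over 100 seeded instances of up to 200 points; single sessions of 2–4
maneuvers for chain tests; a six-subject cohort with full 10-maneuver
sessions and grade-A noise for the end-to-end calibration check; and 20
seeded five-subject cohorts (4 maneuvers each) for the seed-averaged
scheme-ordering property. The closed-form vitals checks run at 1 kHz
(tolerance 0.1 %) and on the 10 ms grid (1 %), with the template's
expiratory onset aligned to the grid so the checks measure estimator
discretisation rather than sampling phase.

## 8. Known limitations

* The package's accuracy statements are properties of the synthetic
  study conditions; real masks add turbulence, leakage and drift that
  the generator does not model (Section 2), so hardware accuracy must be
  established with a real co-measurement, not inferred from this suite.
* The two root-model branches may disagree at zero differential
  pressure by the difference of their intercepts; predictions very close
  to zero flow inherit that seam.
* Polynomial calibrations extrapolate badly and non-monotonically
  outside the fitted pressure range; use `is_monotone()` before trusting
  them at range edges.
* The zero-phase smoother's ~0.2 s support bounds how sharp a true
  expiratory peak can be resolved; peak-sensitive vitals (PEF, FEF25)
  carry a small systematic attenuation that per-subject calibration
  largely, but not entirely, absorbs.
* FEV1 back-extrapolation assumes the volume curve's steepest slope is
  at the sampled peak flow; heavy noise on very short maneuvers can
  shift it.
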