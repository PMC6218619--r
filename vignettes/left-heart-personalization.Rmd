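---
title: "Personalized left-heart hemodynamics: model, estimation and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized left-heart hemodynamics: model, estimation and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioelast)
```

## The model

`cardioelast` implements a zero-dimensional (lumped-parameter) model of the
left heart and systemic circulation with three compartments:

* a **pulmonary venous compartment**: a constant pressure source feeding the
  left atrium through a vessel segment (resistance `R`, inertance `L`) with a
  viscoelastic reservoir (compliance `C` in series with a wall resistance
  `Rv`, Voigt type) and an unstressed reservoir volume;
* the **left heart**: atrium and ventricle as time-varying elastance
  chambers, connected by the mitral valve, with the aortic valve at the
  outlet;
* the **systemic arterial compartment**: a viscoelastic ascending-aortic
  segment (R/Rv/C/L) followed by a three-element viscoelastic Windkessel
  (peripheral resistance `R_p`, storage branch `Rv_wk` in series with
  `C_wk`) draining to a fixed distal pressure of 0 mmHg.

Chamber pressure follows the elastance relation `P(t) = E(t) (V(t) - V_o)`,
optionally with a small viscous wall term `K dV/dt` and an external
(pericardial) pressure, both zero-to-negligible by default. The elastance
curve is a Double-Hill function: the product of an activating Hill term with
exponent `R_C` (contraction rate) and time scale `alpha_S * T`, and a
deactivating term with exponent `R_R` (relaxation rate) and time scale
`alpha_D * T`, scaled by a factor `alpha` computed numerically so that the
curve attains exactly `E_max`; its maximizer defines end-systole `t_max` and
hence the diastolic fraction `100 (T - t_max)/T`. The atrium uses the same
form with an activation offset of `0.85 T`, placing atrial contraction in
late diastole; the timing is otherwise unreported for this model class, and
0.85 T produces a late-diastolic A wave of realistic timing and magnitude.

The aortic valve uses the net (post-recovery) pressure gradient: with the
energy-loss coefficient `ELCo = EOA * A / (A - EOA)`,

```
dP_net = (2 pi rho / sqrt(2 ELCo)) dQ/dt + rho Q^2 / (2 ELCo^2)
```

evaluated in CGS units and converted via 1 mmHg = 1333.22 dyne/cm^2. The
mitral valve carries the same convective form with `EOA` in place of `ELCo`
(no pressure-recovery correction, negligible at the mitral position in
healthy subjects) and a small inertial coefficient exposed as a model
parameter. Valves are diodes: flow is clamped non-negative, and the
open/closed transition is smoothed over a configurable pressure width
(default 0.1 mmHg) and flow width (1 mL/s) so the right-hand side stays
continuous for the stiff solver; while forward flow persists the valve is
held open, which lets late-systolic flow decelerate naturally through an
adverse gradient.

The model comprises exactly 40 scalar parameters (see `param_table()`):
2 global (`T`, `rho`), 10 per chamber, 5 for the valves, 6 pulmonary venous
and 7 systemic vascular. 23 are subject-specific — 3 assigned directly from
measurements (`T`, aortic `EOA` by continuity, aortic cross-sectional area)
and 20 estimated by optimization — while 17 keep literature-tier physiologic
defaults. The defaults were chosen once to reproduce resting hemodynamics of
a healthy adult (stroke volume ≈ 79 mL, aortic pressure ≈ 110/61 mmHg,
E/A ≈ 1.9 at 66 beats/min) and are not tuned per analysis.

## Simulation

The 9-state system (two chamber volumes, four flows, three stored volumes)
is integrated with `deSolve` (lsoda by default; the right-hand side is
compiled C, with an R reference implementation `system_rhs()` that the test
suite holds equal to the compiled one at random states). Cycles are
integrated one at a time; the periodic steady state is declared when stroke
volume and cycle-mean aortic pressure change by less than `tol` (default
1e-3, relative) between consecutive cycles, or when a cycle's start and end
states agree to within `tol` componentwise. Initial conditions are
physiologic guesses (V_lv = 120 mL, V_la = 50 mL, arterial storage at
~75 mmHg) whose influence the steady-state iteration erases; rest-like
defaults converge in about 6 cycles. Volume bookkeeping is exact by
construction: `d(V_la + V_lv)/dt = Q_pv - Q_av`, and total stored volume
changes only through the source inflow and Windkessel outflow (the test
suite audits this to < 0.01 mL per cycle).

Measurement-like sampling (`sample_waveforms()`) interpolates the mitral,
aortic-valve and ascending-aorta flows onto 40 uniform frames per cycle with
periodic cubic splines, emulating the frame resolution of time-resolved
volumetric flow measurements.

## Personalization

`personalize_subject()` chains three steps.

1. **Direct assignment** (`assign_direct_parameters()`): `T`, aortic
   `EOA = SV/VTI` (continuity), aortic area.
2. **Measurement-informed initialization** (`initialize_parameters()`):
   ventricular `E_max` from the single-beat estimate
   `0.9 SBP / (LVESV - V_o)` with `V_o` = 10 mL; Windkessel `R_p` from
   SVR = MAP/CO minus the proximal resistances; the proximal aortic
   compliance from the waveforms themselves — the volume buffered between
   the AV and AA planes, `max - min` of the running integral of
   `Q_AV - Q_AA`, divided by pulse pressure; `C_wk` from total arterial
   compliance `SV/PP` minus the aortic part; and the diastolic shape
   parameter from the ejection end (the last frame with appreciable AV
   flow sits at ~0.92 `alpha_D T` for physiologic shapes, a ratio stable
   to ~5% across the generator's parameter range).
3. **Magnitude warm-up**: a short fit of only the well-conditioned
   magnitude parameters (chamber elastance scales, filling pressure,
   arterial load) with the timing parameters held at their initial
   values. Without it, an initial magnitude mismatch expresses itself as
   an apparent timing error and the full fit can drive the chamber shape
   parameters to their bounds — an attractor it rarely escapes.
4. **Bounded nonlinear least squares** (`optimize_parameters()`): 20 free
   parameters on a log10 scale within physiologic bounds
   (Levenberg-Marquardt via `minpack.lm`), residuals being the model-minus-
   measured flows at the 40 frame times of all three sites with equal
   weights, plus three weighted anchors (below). Optional Latin-hypercube
   multi-starts perturb the starting point; a mandatory seed makes the fit
   reproducible bit-for-bit. For precision recovery studies,
   `scan_alpha_s = TRUE` additionally profile-scans the systolic shape
   parameter: short conditional refits of the other 19 parameters at five
   fixed `alpha_S` values bracket its flat direction and the best-scoring
   one seeds the final fit (local optimization alone tends to settle on a
   minimum flanking the true value along this coordinate).

### Why the objective carries ESV and cuff-pressure anchors

Flow waveforms determine the ventricular volume trajectory only up to an
additive constant, and they never observe pressure directly. In consequence
a pure flow-matching objective has a nearly flat valley: raising `E_max` by
tens of percent while shifting the volume offset (through the atrial and
pulmonary parameters) and re-timing the activation (`alpha_S`, `R_C`)
reproduces all three waveforms to better than 1 mL/s. Profile optimization
makes this concrete: holding `E_max` 40% above its generating value and
re-optimizing everything else leaves a residual of ~1 mL/s RMSE, while the
model's end-systolic volume drifts ~19 mL away from the measured LVESV.
The measured LVESV and cuff pressures are exactly the observations that
close this gap — and they are already inputs of the personalization
workflow. The objective therefore appends three weighted residuals,
`w (ESV_model - LVESV)`, `w (max P_aa - SBP)`, `w (min P_aa - DBP)`, with
`w` = 5 (mL/s per mL or mmHg) by default; `anchor_weight = 0` restores the
pure flow objective. At the generator truth all anchors vanish, so the
objective is still ~0 there.

### Optimizer internals

Two numerical details matter and are deliberate:

* **Frozen-horizon residuals.** Running the adaptive steady-state iteration
  inside the residual makes the objective discontinuous (the cycle count
  switches), which breaks finite-difference Jacobians. Instead each outer
  *round* freezes an accurately converged periodic state of the current
  candidate and evaluates residuals by integrating exactly 5 cycles from
  that frozen state — a smooth, deterministic function of the parameters.
  A fixed horizon alone would let the optimizer exploit slow transients
  (candidates whose waveforms match for 5 cycles while their steady state
  drifts away — e.g. a Windkessel time constant of ~18 s), so the last
  cycle's start/end state mismatch is appended as weighted
  periodicity-defect residuals, which vanish at any periodic solution.
* **Finite-difference step ladder.** Early rounds use coarse relative
  Jacobian steps (`epsfcn` 1e-4) that traverse the broad, curved valley;
  later rounds use very fine steps (1e-8), which are reliable because the
  frozen-horizon residual is smooth, and which are what finally walks the
  estimate down the shallow `alpha_S`/`R_C` trade-off. Every round's
  candidate is re-scored with the true adaptive steady-state objective and
  the best re-scored candidate wins, so a round that wanders off cannot
  displace a better earlier solution. Rounds stop early when the true cost
  plateaus or falls below 0.25 (mL/s)^2.

Failures inside the objective (invalid parameter combinations, solver
failures, non-converged steady states) return a flat penalty residual with
total cost 1e6 (mL/s)^2 instead of raising.

### Practical identifiability

With the anchors, noise-free recovery experiments (see the test suite)
return the five ventricular elastance parameters `E_max`, `R_C`, `R_R`,
`alpha_S`, `alpha_D` to within a few percent at the resting state. The
`alpha_S`/`R_C` pair remains the slowest direction — both shape the rising
limb of the elastance curve over the limited window where ejection flow
observes it — and for some subjects a flanking local minimum reproduces
the data to a fraction of a mL/s while `alpha_S` sits 10-20% off, a
resolution no realistic measurement could distinguish. Recovery is
assessed at rest: under stress the shorter cycle compresses diastole and
merges waveform features, which degrades practical identifiability
further; in particular the relaxation exponent `R_R` loses its main
observable (the early-filling upstroke) when the E and A waves merge
under frame noise, and stress fits can return `R_R` near its lower bound.
Cohort-level conclusions about `R_R` under stress should therefore lean
on better-identified correlates (`tau_D`, the diastolic fraction) rather
than the raw exponent. The noisy-recovery and directional-statistics
checks quantify these limits.

## Synthetic cohort

`generate_cohort()` draws paired rest/stress subjects. Varying parameters
(heart rate; LV `E_max`, `E_min`, `R_C`, `R_R`, `alpha_S`, `alpha_D`; LA
`E_max`; `R_p`; `C_wk`; aortic compliance; pulmonary source pressure; and
subject-level valve geometry) follow truncated normal distributions whose
rest/stress centers and spreads are the published cohort statistics of a
dobutamine stress study in healthy adults (heart rate 66 ± 9 to 105 ± 19
beats/min; LV contraction-rate exponent 1.5 ± 0.3 to 2 ± 0.5; relaxation
exponent 37.2 ± 6.9 to 46.1 ± 12; diastolic shape parameter 0.40 ± 0.05 to
0.50 ± 0.05; maximal elastance 1.8 ± 0.5 to 4.7 ± 3.6 mmHg/mL; aortic
compliance 0.11 ± 0.06 to 0.16 ± 0.10 mL/mmHg). Quantities the study
reports but the model does not parameterize directly (SBP, DBP, LVESV)
emerge from the simulation and are "measured" from it: cuff pressures from
the aortic pressure extremes plus ±3 mmHg cuff noise, LVESV from the
ventricular volume minimum plus ±3 mL, waveforms with iid Gaussian frame
noise (25 mL/s rest, 45 mL/s stress, echoing the fit-residual magnitudes
reported for real data). The velocity-time integral is defined on the
noise-free sampled flow as `VTI = SV/EOA_true`, so the continuity identity
is exact on noise-free bundles; on real data VTI would come from the
velocity at the valve center, a documented discrepancy.

Pairing uses a subject-level random effect with intraclass correlation 0.5
(configurable; the true inter-state correlations are unpublished). Two
study conditions are enforced per subject, mirroring the universal
chronotropic and output response to dobutamine: stress heart rate strictly
above rest, and stress cardiac output above rest (violating draws are
redrawn, bounded and logged). The generator is a pure function of
(spec, seed).

What the generator does *not* emulate: image segmentation and valve-tracking
error structure (noise is iid Gaussian on frames, real errors are
correlated), beat-to-beat variability (the model is strictly periodic),
breathing effects, and any pathology. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to real measurement error.

## Indices and statistics

`compute_indices()` reproduces the standard derived quantities: SV by
cycle-integrating the AV flow (trapezoid with periodic closure), CO, EF
(with EDV = ESV + SV), MAP by the one-third cuff rule unless a
device-reported MAP is present, SVR = MAP/CO, total arterial compliance
SV/PP, EOA by continuity, and the mitral E/A analysis. E/A peak detection
operates on the cyclic series with a prominence threshold of 5% of the
tallest peak and no smoothing at 40 frames; if a single local maximum
survives, the waveform is flagged merged and E/A is undefined — the merging
of E and A waves at high heart rate is expected behavior, not an error.

`wilcoxon_signed_rank()` implements the paired two-sided signed-rank test
with zero differences dropped and ties mid-ranked. The default asymptotic
method uses the normal approximation without continuity correction (with
tie-corrected variance), matching common statistical-package output at this
cohort scale; the exact method enumerates the full null distribution of the
positive-rank sum (dynamic program over doubled ranks, so mid-ranks are
exact). At n = 9 the two agree to better than 0.01 in the decision-relevant
tails; mid-range the normal approximation deviates by up to ~0.06, which is
inherent to n = 9, not an implementation artifact. `summarize_cohort()`
produces the per-variable rest/stress mean ± SD (range) table with p-values
and a significance flag at p < 0.05, erroring on unpaired subjects.

## Numerical choices and problem sizes

* Solver: lsoda (stiff-capable), rtol = atol = 1e-6, 200 output points per
  cycle for reported results; the optimizer uses 60 points and the bdf
  stepper for speed. Halving tolerances changes cycle-mean flows by < 0.1%.
* Valve smoothing width 0.1 mmHg; closed-valve resistance 20 mmHg s/mL
  (closure time constant ~1e-4 s, comfortably inside the stiff solver's
  range).
* Steady state: tol 1e-3, max 30 cycles; the optimizer freezes states at
  tol 1e-6 (up to 60 cycles) because the frozen-horizon residual must be
  unbiased at its expansion point.
* Test-suite problem sizes: recovery experiments use 5 noise-free rest
  subjects (profile scan plus 18 ladder rounds) and 5 noisy seeds
  (6 rounds); the directional-statistics check runs a 9-subject paired
  cohort through the full pipeline with a reduced optimizer budget
  (15 iterations, 4 rounds). These sizes were chosen so the full suite
  completes on a single CPU while leaving the conclusions' margins
  visible.

## Limitations

The right heart, pulmonary arterial tree, baroreflex and regurgitant valves
are out of scope. The constant passive elastance implies a linear
end-diastolic pressure-volume relationship, known to be an approximation.
`E_max` inherits the single-beat assumptions through its initialization and
through the SBP anchor (end-systolic pressure is approximated, not
measured). The 17 literature-tier parameter values stand in for an
unavailable published table and are documented physiologic defaults rather
than reproductions of it.
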