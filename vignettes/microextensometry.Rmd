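---
title: "Virtual micro-extensometry: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual micro-extensometry: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`microext` is a desk-scale re-implementation of a low-cost
micro-extensometer's software stack: instrument control, load-cell
calibration, optical strain tracking, and tensile-curve analysis. The
hardware — a stepper-screw actuator, a strain-gauge load cell behind a
Wheatstone bridge, and a camera watching ink landmarks on the specimen —
is replaced by a physics-based virtual instrument, so every procedure a
user would run at the bench is executable and testable in code. This
vignette explains the models and the choices behind them.

```{r, eval = FALSE}
library(microext)
demo <- run_demo(seed = 1)
glance(demo$summary)
```

## The virtual specimen

Uniaxial tensile behaviour of soft plant tissue shows four phenomena the
toolkit must reproduce: elastic stretch (Hooke's law, σ = E ε),
time-dependent relaxation between actuator steps, irreversible creep
above a yield threshold, and slippage of the specimen within its
mounting tags. No published constitutive law accompanies the instrument
itself, so the specimen model here is our own stand-in — deliberately
the *minimal* model exhibiting all four behaviours:

* **Standard linear solid (SLS).** An equilibrium spring `E_inf_MPa` in
  parallel with a Maxwell branch (`E_1_MPa`, retardation time `tau_s`).
  An instantaneous stretch loads both springs (modulus `E_inf + E_1`);
  holding the grips lets the branch relax exponentially toward the
  equilibrium modulus `E_inf`. Under a constant step rate the
  steady-state slope of the force curve is exactly `E_inf · A / L0`,
  with the viscous branch contributing only a rate-dependent offset.
* **Lockhart/Bingham plastic element.** Plastic strain accumulates at
  rate Φ · max(0, σ − σ_Y): nothing below the yield stress, linear
  excess-stress kinetics above it. This is the classical growth/creep
  picture for walled cells (extensibility × stress in excess of yield).
* **Threshold grip slip.** Above a holding force `F_hold_uN` the
  specimen slides within the tags at rate
  `slip_rate_um_per_s_per_uN · (F − F_hold)`. Slip inflates the grip
  (actuator) displacement but not the true tissue strain — exactly the
  divergence the optical pathway exists to catch.
* **Brittle rupture.** When σ reaches `sigma_ult_MPa` the transmitted
  force drops to zero permanently, in one step, matching the sudden
  force drop used to read ultimate stress off real curves.
* **Tension only.** Force is clamped at ≥ 0: tag mounting cannot push.

State is carried by `specimen_state()` (grip displacement, cumulative
slip, viscous and plastic strain, rupture flag); slip and plastic
strain are monotone by construction, and the rupture flag is one-way.

### Default parameters

The defaults describe a soft, dark-grown seedling axis sized for a 10 g
load cell: cylindrical, radius 100 µm (A ≈ 31 416 µm²), gauge length
L0 = 5 mm, `E_inf` = 20 MPa, `E_1` = 10 MPa, `tau` = 5 s, `sigma_Y` =
1 MPa, `Φ` = 2·10⁻⁴ (MPa s)⁻¹, `sigma_ult` = 2.5 MPa. Rupture then
occurs near 78 mN — inside the 10 g cell's ≈ 98 mN capacity — at an
equilibrium strain of ~12.5%, and yield onset is visible mid-run under
the default ramp (5 µm steps, 2 s wait). Slip is off by default
(`F_hold = Inf`); slip studies enable it with `F_hold` ≈ 2000–3000 µN.
Creep scenarios use a lower-yield set (`sigma_Y` = 0.05 MPa,
`Φ` = 5·10⁻⁴) so that Lockhart flow is active at a 5000 µN holding
force, giving tissue creep rates of a few tenths of µm/s.

### Numerical integration

`evolve_specimen()` applies the grip target at the start of the
interval and holds it (a stepper step is near-instant relative to the
wait between steps), then integrates the three coupled rate laws with a
fixed-substep explicit midpoint (second-order) update. The substep is
capped at `tau/50` and, when plasticity or slip is active, at 2% of
their rate constants' timescales. A first-order scheme at the
conventional `tau/20` leaves percent-level error; the midpoint update
keeps the whole trajectory within ~0.01% of a fine-step reference
integration (the suite checks ≤ 0.1% against an independent
explicit-Euler oracle at `tau/4000` on randomized parameter sets).
Rupture is latched as soon as the stress crosses `sigma_ult`, including
at the instant of the grip step itself.

## The virtual instrument

* **Actuator.** 1 mm pitch screw, 200 full steps per revolution
  (1.8°/step) → 5 µm per step; microstepping divides this (divisor 16 →
  0.3125 µm). Positions are kept in nanometres and are always an exact
  integer multiple of the step size — there is no drift, and the
  µm/nm round trip is lossless for whole steps. Travel-limit violations
  raise a range error with no motion. Backlash is not modelled by
  default (the screw drive shows no noticeable looseness); an optional
  `backlash_um` field exists for robustness studies.
* **Load cell.** Reading = F/gain + offset + Gaussian noise, with the
  true gain and offset hidden from calibration code. The default noise
  (0.01 units at 1000 µN/unit) makes the RMS force noise ≈ 10 µN, the
  stated resolution of the 10 g cell — the instrument text gives no
  noise spectrum, so this is a documented assumption. Forces beyond
  capacity clip the reading and set a `saturated` flag rather than
  erroring, as real amplifiers clip. Re-orienting the cell shifts its
  zero by a configurable self-weight term; the calibration workflow
  must cancel it.
* **Camera.** 8-bit grayscale frames, dark-on-bright polarity
  (India-ink dots on pale tissue; `invert` for the opposite), default
  10 µm/px. Grip tags are rendered as dark bars whose separation tracks
  the actuator; landmark dots are anti-aliased disks placed by
  `landmark_positions()`, so their separation tracks *tissue* strain
  and excludes slip. Anti-aliasing is what makes sub-pixel centroid
  recovery (~0.03 px in practice) possible; optional Gaussian pixel
  noise degrades this gracefully. Landmarks outside the field of view
  are recorded as frame warnings, never silently dropped.

All randomness flows from one explicit seed per experiment
(`experiment_config(seed = )`), so logs are exactly reproducible.

## Calibration workflow

`calibrate_instrument()` mirrors the bench procedure: orient the cell
vertically, **Set Offset** with no load (mean of `n_samples` readings —
the 100-sample default is our choice; the procedure text names none),
**Calibrate Force** against a reference weight (F = m·g; the gravity
constant is exposed because workflows round it differently, 9.81 vs
9.80665), then return the cell to horizontal and re-zero. Gain is
single-point, `target/(mean − offset)`, as in the documented workflow —
a deliberate fidelity choice over multi-point regression. A reading
that does not exceed the offset aborts with a "missing weight or
damaged cell" error, and `validate_calibration()` warns on large gain
changes between sessions, the documented damage indicator.

## Experiment control loops

**Ramp** (`run_ramp()`): move one step, wait `wait_time_s` for force
stabilization, read the force (averaging 25 bridge samples by default),
capture a snapshot, log a record; on completion the actuator
auto-returns to start. `wait_time_s = -1` is external-trigger mode: the
run blocks per step on a confirmation callback (with an auto-confirming
callback it reproduces the `wait_time = 0` log exactly). A stopped run
keeps its partial log and does **not** auto-return. Stabilization is
time-based, as on the bench; rupture is recorded but does not abort the
run — post-hoc analysis locates it.

**Creep** (`run_creep()`): threshold 0 delegates to the ramp
(elasticity experiments). Otherwise phase 1 approaches at a constant
rate (default one step per second — the text says only "constant
rate"), and phase 2 holds the force for `max_duration_s`: every control
period (1 s, a documented default) the force is read and, when it falls
below `threshold · (1 − deadband)`, single steps are issued until back
in band. The deadband default is 1% of the threshold ("maintain that
force" is all the text specifies). Holding a 5000 µN threshold within
1% requires the per-step force increment to be comparable to the band,
so creep studies run the actuator at microstep divisor 16
(0.3125 µm/step → ≈ 59 µN per step at the default stiffness); the
controller hardware explicitly supports subdividing steps. With this
configuration the simulated controller keeps the measured force in-band
for >95% of hold samples and never exceeds threshold + one step + noise.

Logs are written as `Extensometer.csv` (header exactly
`Step,Position (nm),Force (µN),Time (µs)`, UTF-8, full-precision
numbers so the round trip is bit-for-bit), `MRXlog.csv` (raw stream:
`time_us,raw_reading_units,position_nm` — this schema is ours, declared
rather than claimed compatible), a `Snapshots/` folder of PNGs (one per
step by default; `snapshot_every` thins long creep holds), and a
`config.yaml` snapshot sufficient to reproduce the run. Readers accept
ASCII aliases (`Force (uN)`) and fail loudly, naming the missing column
or malformed row.

## Optical strain measurement

`detect_landmarks()` automates what is otherwise manual image
measurement: Otsu's between-class-variance threshold on the 256-bin
histogram (manual override available), connected components
(`EBImage::bwlabel`), an area filter that drops the grip tags and
specks, and intensity-weighted centroids over a 1-px-dilated support so
anti-aliased rims pull the centroid to the true centre. Pixel
convention: the centre of pixel *j* is *j*.

`track_landmarks()` maintains identities by nearest-neighbour matching
with a maximum-displacement gate (default 0.25× the smallest initial
separation — steps are small relative to landmark spacing). Any
ambiguity — a count change, more than one candidate in the gate, a
non-bijective assignment — fails loudly naming the frame; a silent
identity swap is the one failure mode a strain pipeline must not have.

Strain is Euclidean-distance based (landmark pairs sit along the
stretch axis), ε = (d − d_ref)/d_ref × 100. The grip pathway applies
the same formula to the actuator-based separation, so slippage appears
as `grip_strain − landmark_strain ≥ 0` and `slippage_diagnosis()` calls
a run slip-dominated when, at the end of the span, more of the apparent
strain is slip than tissue. The pixel scale can come from any feature
of known size (`pixel_scale(12700, measured_px)` for the 12.7 mm
printed tag width). Junction-style landmarks are handled as ordinary
dark blobs; automated corner detection is out of scope.

## Mechanics analysis

Stress is F/A with the exact unit identity 1 µN/µm² = 1 MPa, and the
*initial* cross-section throughout (constant-area convention; Poisson
thinning is not modelled). The linear region is the contiguous window
(default 50 steps) maximizing linear-fit R², which steers clear of the
initial toe and pre-rupture softening; ties break earliest; a region
beyond 20% strain triggers a warning since elastic analysis is normally
limited to 10–20%. Young's modulus is the two-point Δσ/Δε over the
region endpoints — matching how the curves are read in practice — with
a least-squares option. Rupture is the first drop ≥ 50% of the running
maximum (the text says only "sudden drop"); ultimate stress is the
pre-drop maximum over A. Yield onset is the first post-region step
falling below the extrapolated linear fit by more than 5% (relative) —
onset is identified visually on real curves, so the tolerance is ours;
at tolerance 0 the first numerical wiggle triggers, a documented
degenerate behaviour. Creep profiles use non-overlapping windows
(default 300 s) anchored at the experiment start, rate =
(end − start)/window per pathway.

## What the simulations do and do not show

The synthetic data reproduce the *mechanisms* — SLS relaxation,
threshold creep, threshold slip, brittle rupture, pixel-quantized
optics, Gaussian sensor noise — under exactly known ground truth, which
is what makes the recovery tests meaningful: the optical pathway
recovers `E_inf` within a fraction of a percent on clean specimens, the
grip pathway underestimates it whenever slip is enabled, and the creep
profile shows decelerating tissue creep with the grip rate pulling
ahead late, the qualitative slip signature. They do **not** emulate
heterogeneous strain fields along the specimen, poroelastic water
transport, tag-adhesive viscoelasticity, vibration or EMI (only
additive Gaussian noise), or real cell-wall microstructure — so passing
tests validate the *software pipeline*, not any biological claim.
Published per-genotype moduli cannot be re-derived here because the
underlying images and force logs are not deposited; the worked strain
arithmetic (10.6%, 109.4%, 163%, 19.05%) is reproduced from the printed
lengths instead.

Problem sizes were chosen to keep the full suite light: recovery
studies use 20 specimens × 45 steps, slip studies 6 seeds × 40 steps,
creep runs a 1000 s hold sampled every 10 s, and the oracle comparison
10 random parameter sets × 20-step staircases.

## Known limitations

* One-dimensional kinematics: a single scalar strain per specimen; no
  stiffness gradients along the axis (the landmark machinery would
  support more dots, but the specimen model is homogeneous).
* After rupture the rendered landmark separation follows the (now
  meaningless) grip coordinate; analysis only uses pre-rupture frames.
* The creep controller can only add tension (steps are never reversed
  to shed force), matching the bench workflow but meaning an overshoot
  decays only through relaxation, creep, or slip.
* Junction tracking by template refinement around user seeds is not
  implemented; junctions are treated as dots.
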