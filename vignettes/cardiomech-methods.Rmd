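---
title: "Methods: multiscale cardiac electromechanics across conduction velocities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale cardiac electromechanics across conduction velocities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`cardiomech` asks how myocardial conduction velocity (MCV) shapes the
pumping performance of a ventricle. The pipeline has four stages, each a
module with its own surface:

1. **Ionic cell** — a human ventricular myocyte model (the 2006
   parameterization of the ten Tusscher-Panfilov family) with endocardial,
   mid-myocardial and epicardial variants. The membrane follows
   `dV/dt = -(I_ion + I_stim)` with currents normalized to membrane
   capacitance (pA/pF), where `I_ion` is the sum of exactly twelve membrane
   currents (fast Na+, inward-rectifier K+, transient-outward K+,
   rapid/slow delayed-rectifier K+, L-type Ca2+, Na+/Ca2+ exchanger,
   Na+/K+ pump, Ca2+ and K+ pumps, background Ca2+ and Na+). SR calcium
   follows the leak/uptake/release balance of the same model.
2. **Tissue conduction** — monodomain reaction-diffusion on regular
   Cartesian fixtures, with per-axis diffusion coefficients
   `D_a = 1/(rho_a S_a Cm)` (rho: cellular resistivity, Ohm cm; S:
   surface-to-volume ratio, 1/cm; Cm: membrane capacitance, uF/cm^2; an
   Ohm times a Farad is a second, giving D in cm^2/ms). Activation maps,
   activation (EAT) duration, conduction-velocity (CV) measurement
   (`v = d/t`), and bisection calibration of rho to a target CV live here.
3. **Myofilament** — a Rice-style cross-bridge/regulatory chain
   (non-permissive and permissive regulatory units, pre- and post-rotation
   attached cross-bridges, low/high-affinity troponin Ca binding, mean
   cross-bridge strains) producing normalized active tension and a
   contractile ATP consumption rate, `g_xbT x SOVF_thick x XB_PostR`
   (detachment rate times thick-filament single-overlap fraction times the
   attached post-rotation fraction — one ATP per completed detachment).
   Coupling is strictly one-way: electrophysiology drives mechanics and
   nothing feeds back.
4. **Hemodynamics** — each ventricle is a lumped thin-wall surrogate
   (`P = B(exp(kappa (V - V_rest)) - 1) + alpha T (V/V_ref)^(-2/3)`)
   driven by the mean tension of a myofilament ensemble; the systemic and
   pulmonic circulations are each two Windkessel compartments in series
   (arterial+capillary, venous) with linear pressure-volume relations and
   ideal-diode valves. Volumes update by inflow minus outflow, so total
   blood volume is conserved to round-off. The failing preset multiplies
   every vascular compliance by 0.9.

The experiment (`run_mcv_sweep`) calibrates resistivity for each target
MCV (30-70 cm/s), runs 3 s of sinus-paced electrical simulation at a
600 ms cycle length, extracts the final-cycle activation map (2.4-3 s),
runs 32 mechanical cycles to a periodic steady state, and reports per
condition: EAT duration, systolic LV pressure, mean arterial pressure,
EDV, ESV, SV = EDV - ESV, EF = 100 SV/EDV, stroke work (PV-loop area),
node-summed cycle-average ATP rate, and the efficiency index SW/ATP.
`monotonicity_report` then checks the nine expected directions with
increasing MCV: EAT, EDV, ESV and ATP fall; systolic pressure, SV, EF,
SW and SW/ATP rise.

## Excitation-to-contraction handoff

The mechanics mesh of a full electromechanical model solves myofilament
dynamics at every finite-element node. At desk scale we replace this with
an *ensemble*: per-region calcium transient templates are extracted from
converged single-cell runs (24 pre-pacing beats; rejected when the
beat-to-beat diastolic level drifts more than 2%), and each ensemble
member replays its region's template shifted by its node's activation
time. Activation dispersion therefore staggers the tension contributions
exactly as the activation map dictates, which is the physiological
mechanism under study.

The ensemble (default 64 members) is subsampled from the activation map
*stratified by region and spatial position, not by activation-time
quantiles*. Quantile stratification re-selects different myocardial nodes
under every conduction condition, so the ensemble's regional composition
— which sets its calcium amplitudes and hence its ATP turnover — would
change with the condition and mask the dispersion effect. A fixed
myocardial sample, identical across conditions with only its activation
times changing, is what the between-condition comparison requires.

Sarcomere length is coupled to cavity volume in the coupled run,
`SL = SL_ref (V/V_ref_sl)^(1/3)` (defaults 2.15 um at 95 mL), clamped to
the myofilament model's admissible range. This geometric feedback is the
channel through which activation dispersion reaches the energetic
readouts: with SL held fixed, every node's cycle-integrated ATP is
invariant under a pure time shift, and the between-condition ATP
comparison would be vacuous by construction (the finite-element original
has this coupling inherently). Standalone myofilament operations take SL
as an explicit argument and default to a fixed 2.0 um.

## Fixtures and protocol

All inputs are generated in code. The reference suite
(`reference_fixture_suite`) freezes:

* `cv_cable` — a 2 cm epicardial cable at dx = 0.025 cm for CV
  validation (rho = 162 Ohm cm conducts at ~70 cm/s, matching the normal
  planar velocity the cell-model literature reports);
* `cv_cable_fine` — the same cable at dx = 0.0125 cm for convergence and
  square-root diffusion-scaling checks;
* `calib_cable` — a cable at the sweep fixture's spacing, on which the
  per-condition resistivity is calibrated (planar CV on a cable is the
  standard measurement convention; measuring on the curved shell would
  confound calibration with wavefront curvature);
* `sweep_shell` — a truncated half-ellipsoidal shell (outer semi-axes
  0.6 x 0.6 x 0.75 cm, inner surface at 0.6 of the outer, dx = 0.05 cm,
  ~3,650 nodes) with transmural layers endo/mid/epi = 0.3/0.4/0.3 by wall
  depth. This stands in for an imaging-derived ventricular mesh: it has a
  cavity, an apex-to-base axis, a wall with three electrically distinct
  layers, and endocardial early-activation sites, but none of the fiber
  architecture, anatomical Purkinje geometry, or absolute size of a real
  ventricle. Activation durations are therefore a few tens of
  milliseconds rather than 120-200 ms, and every test about the sweep
  asserts *directions of change*, never anatomical-model magnitudes.

The sinus protocol samples Purkinje-terminal sites from the endocardial
layer (seeded and reproducible; the anatomically mapped early-activation
sites of the experimental literature are not available on a synthetic
shell). Site onsets are the global onset (20 ms) plus the path distance
from the earliest site divided by the Purkinje path speed (200 cm/s);
path distance is approximated by Euclidean distance, acceptable on these
convex fixtures. Two protocol conventions are exposed
separately: the terminal onset (20 ms, the activation-map floor) and the
5 ms delay before the myocardial stimulus current is injected
(ventricular stimulation at 25 ms). A terminal's recorded activation time
is its commanded onset — the network delivered activation at that instant
— so the map minimum equals 20 ms exactly under every condition; all
other nodes record their first upward 0 mV crossing, linearly
interpolated between steps.

Each terminal stimulates a small tissue ball (radius 0.12 cm) rather than
a single node: a point source cannot depolarize 3D tissue against the
diffusive load. For the same reason the planar (cable) protocol
stimulates a fixed ~0.06 cm depth of the low-x face regardless of grid
spacing.

## Numerical choices

* **Cell/tissue step** dt = 0.02 ms, enforced limit 0.05 ms. Gates use a
  Rush-Larsen exponential integrator, so they stay in [0, 1] by
  construction; concentrations use forward updates with the model's
  analytic buffering; the ryanodine-receptor state, linear in itself, is
  updated exponentially. Halving dt moves APD90 by well under 1 ms
  (tested).
* **Voltage-dependent coefficients** are tabulated once per run on a
  0.05 mV grid over [-150, 150] mV and linearly interpolated. This is a
  standard device in fixed-step cardiac solvers; it changes APD90 by less
  than the dt-refinement effect and keeps runs deterministic.
* **Diffusion** uses the second-order 6-neighbour stencil with no-flux
  boundaries implemented by dropping missing neighbours (the pairwise
  antisymmetric form conserves total voltage exactly). The explicit-step
  CFL bound `dt <= 1/(2 sum_a D_a/dx_a^2)` is checked and violations are
  rejected with the computed limit.
* **Activation threshold** 0 mV, first *upward* crossing after cycle
  onset (robust against notch-and-dome repolarization morphologies);
  crossings are linearly interpolated between samples. EAT duration is
  the map **maximum measured from cycle onset** (not max - min): full
  depolarization at 120 ms means an activation duration of 120 ms.
* **CV measurement** between the nodes at 25% and 75% of the cable,
  avoiding stimulus and boundary artifacts. **Calibration** bisects rho
  in log space (CV scales like rho^(-1/2)); monotonicity over the bracket
  is asserted on the endpoints, the default tolerance is 1%, and targets
  below the conduction-failure limit or above the bracket's achievable
  range are rejected with diagnostics.
* **Myofilament step** dt = 0.1 ms. The four-state regulatory pool
  advances by a forward, exactly pairwise-conservative update (the pool
  sum is preserved to ~1e-14 over 1e5 steps); troponin occupancies and
  mean strains, each linear in its own variable, use exponential updates.
  The strain modulation of the forward rotation rate is capped at a
  factor of 2 as a numeric guard against the exponential blow-up the
  published rate law permits at large negative strain; in paced
  operation the cap is inactive. Rate constants are used at the cited
  model's reference parameterization without temperature rescaling.
* **Circulation step** dt = 0.1 ms, synchronized with the myofilament
  bank; one shared C++ step core serves both the R-level single step and
  the engine, and a test pins their agreement. Valve flows are
  ideal-diode gated (never negative). Stroke work is the trapezoidal
  PV-loop area, within 0.5% of refined quadrature on analytic loops.
* **Determinism**: there is no randomness anywhere in the numerics; the
  only seeded draw is Purkinje-site sampling. Two identical sweep runs
  produce byte-identical metric tables.

## Circulation operating point

The thin-wall surrogate has no emergent pressure scale, so four knobs
(active gain alpha, systemic resistance, arterial compliance, initial
preload-setting pressures) were tuned once — `scripts/tune_circulation.R`
documents the procedure — so that the 70 cm/s failing baseline operates
near EDV ~91 mL, ESV ~57 mL, SV ~34 mL, EF ~38%, mean arterial pressure
~145 mmHg and systolic LV pressure ~160 mmHg. Volumes and flows land on
the reported operating range; the systolic pressure peak overshoots it by
roughly 7% because the surrogate's active term stiffens as volume falls
during ejection. Since absolute hemodynamic magnitudes are calibrated
rather than emergent, only trend directions across conditions are treated
as scientific output.

## Problem sizes

The reference analyses use the ~3,650-node shell with 3 s of electrical
simulation per condition, per-condition cable calibration, and 32
mechanical cycles with a 64-member ensemble per ventricle; the full
five-condition sweep completes in roughly ten minutes on one CPU. The
oracle checks run the same equations through an independent adaptive
stiff integrator (deSolve) at tight tolerance on single cells and single
myofilament instances.

## What passing tests do and do not show

The test suite demonstrates: the cell model reproduces its published
resting/peak potentials, transmural APD ordering and dt-convergence; the
monodomain cable conducts at ~70 cm/s at 162 Ohm cm and follows
square-root diffusion scaling; calibration hits arbitrary targets within
tolerance; the myofilament pool is conserved and its steady state matches
the reference integration within 1%; the circulation conserves volume,
discharges with the closed-form RC constant, and converges to a periodic
cycle; and the five-condition sweep reproduces all nine direction-of-
change findings deterministically.

It does **not** show that the magnitudes of a full anatomical
finite-element torso-scale model are reproduced: activation durations,
ATP sums and stroke work are fixture- and ensemble-scale quantities; the
ventricle surrogate has no wall mechanics, fiber architecture or
regional strain; and the between-condition differences, while strictly
monotone, are smaller than in the anatomical original because the
synthetic shell's activation-time spread is compressed. Conclusions
supported here are directional, not quantitative.

## Known limitations

* One-way coupling only; no mechano-electric feedback.
* No atria, baroreflex, valve inertance or characteristic impedance.
* Euclidean (not geodesic) Purkinje path distances; sampled (not
  anatomically mapped) terminal sites.
* Fixed resistivity multipliers do not map cleanly onto target
  velocities under square-root diffusion scaling, so each condition is
  defined by its target velocity and reached by *calibrating* resistivity
  on a matched cable rather than by trusting preset multipliers (which
  ship as a documented preset only).
* Regional myofilament differences enter only through the calcium
  templates; the cross-bridge constants themselves are region-independent.
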