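---
title: "Models and methods behind guvflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind guvflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(guvflux)
```

# The measurement being modelled

A microlitre bolus of acid is pipetted into the chamber holding
pyranine-loaded GUVs. Protons diffuse toward the resting vesicles, the
external pH falls over a few minutes, and protons leak across the bilayer
at a much slower rate. Two confocal channels are recorded at 0.2–0.3
frames/s: a membrane dye delineating each vesicle's equator and the
lumenal pH dye. Because the internal unstirred-layer diffusion time
(`unstirred_layer_time()`: r²/6D ≈ 2 ms for r = 10 µm) is far below the
frame interval, the lumen is treated as well mixed, and each frame yields
one well-defined internal pH.

# Forward model

`simulate_acidification()` integrates, per vesicle, the state
(pH_i, cumulative permeated protons, Δψ, internal anion pool, internal
total weak-acid pool):

* **Proton flux** through the GHK electrodiffusion equation
  (`ghk_flux()`), inward positive, Δψ = ψ_in − ψ_out. At |u| < 1e-6 the
  second-order series is used so the expression is smooth through u = 0;
  the threshold was chosen so series and direct form agree to ~1e-12.
* **Conjugate-anion flux** with valence −1 through the same GHK form
  (equivalent to a cation in the reversed potential).
* **Neutral weak-acid flux** `J_HA = P_HA([HA]_o − [HA]_i)`, with
  instantaneous Henderson–Hasselbalch speciation of each face's total acid
  pool at that face's pH. Surface protonation kinetics are assumed fast.
* **Buffering**: `dpH_i/dt = −(d[H+]T_in/dt)/β(pH_i)` with the analytic
  buffer capacity (`buffer_capacity()`) of 10 mM HEPES (pKa 7.5 near
  21 °C) plus water autoionisation. The ~10 µM pyranine contributes
  negligibly to β and is ignored. A measured β(pH) table can be loaded
  instead (`tabulated_curve()`).
* **External course**: the extravesicular pH holds at 7.6 until an
  arrival delay (default 60 s) and then relaxes exponentially (τ = 120 s)
  to a plateau (default 6.9, chosen to keep the background within the
  resolvable dye window). The *amount* of acid this represents — and
  hence the external anion and total-acid concentrations — is recovered
  in closed form from the buffer titration function
  (`titration_acid_added()`), whose derivative is β.
* **Membrane potential**: capacitive charging
  `dΔψ/dt = F(J_H+ − J_anion)/C_spec`.

The integrator is fixed-step classical RK4 (via deSolve) with dt = 0.05 s
and a step-halving convergence check in the tests (halving dt moves the
600-s endpoint by < 1e-4 pH units). The forward model is deterministic;
all stochasticity lives in the renderer and cohort radius draw, each of
which requires an explicit seed.

## Closure parameters the data do not pin down directly

Two constants close the potential model; both matter and both are
effective values:

* **`C_spec` (default 5e-4 F/cm²).** With the geometric bilayer value
  (~1e-6 F/cm²) the membrane would charge to the Nernst potential within
  ~1–2 s — faster than a single frame — after which the net flux
  collapses; measured fluxes would be unobservably small at frame
  resolution. The observed behaviour of the assay is instead a gradual
  potential buildup over the course of the recording with partial flux
  saturation. The default charges over ~10 minutes and reproduces that
  phenomenology; it should be read as an effective capacitance absorbing
  unmodelled charge-compensating pathways (counter-ion fluxes of the
  bulk electrolytes), not as a dielectric property.
* **`P_anion` (default 1e-10 cm/s).** The counter-anion pool sits at
  buffer-titration (mM) concentrations, ~four orders above [H+]. Its
  permeability default is the literature order for halides across PC
  bilayers; values above ~1e-8 cm/s would make anion charging dominate
  and drive the interior negative, the opposite of the observed
  polarization.

## Weak-acid effective permeability

Field convention reports weak-acid permeabilities as slopes of flux
against Δ[H+]; the mechanistic `P_HA` multiplies Δ[HA] instead. The two
are related through the buffer and the acid's Ka (for formate at pH ~7.3
the conversion factor is ≈ β/(ln10·Ka) ≈ 15–20).
`calibrate_neutral_permeability()` makes the conversion exact by
construction: it runs the clamped forward model, regresses the
ground-truth neutral flux on the ground-truth proton gradient over the
same small-gradient window the analysis uses, and scales `P_HA` to hit a
requested effective ratio. Only forward-model ground truth enters; the
analysis pipeline is never consulted, so recovery tests remain a genuine
round trip.

# Synthetic imaging

`render_timelapse()` draws, per frame, an annular membrane ring
(thickness 3 px) and a uniform lumen disc at the calibrated pyranine
intensity `ph_to_intensity(pH_i)` over a background at
`ph_to_intensity(pH_o)`, then applies per-pixel Poisson shot noise
(counts scale 1) and Gaussian read noise (sd 5). Pixels are 0.5 µm;
centres sit at integer pixel coordinates (0-based). The calibration is a
single-site sigmoid (apparent pKa 7.3, window 6–7.6); a tabulated
measured curve can replace it.

Deliberately *not* modelled: point-spread function and z-sectioning,
photobleaching, dye leakage, vesicle deformation or osmotic volume
change, multilamellarity, overlapping vesicles. Passing recovery tests
therefore demonstrate correctness of the analysis chain under ideal
optics, not robustness to those artefacts.

# Image analysis

* **Detection** (`detect_vesicles()`): Sobel edges vote along ±gradient
  at every candidate radius (circular Hough transform). Candidate
  centres are scored by votes within ±3 px of their peak radius —
  genuine circles concentrate votes there (both ring edges straddle the
  true radius), whereas accumulation ghosts between vesicles spread
  votes over many radii and are rejected (`peak_fraction` = 0.6,
  `sensitivity` = 0.75 of the ideal 4πr response). Radii are reported as
  integers; sub-pixel refinement is intentionally omitted, so centre
  jitter of 1–3 px is expected and the tracking gate must exceed it.
* **Tracking** (`track_vesicles()`): greedy nearest-neighbour linking in
  ascending distance order, gate 8 px, one-frame gap bridging, IDs never
  reused, ties broken deterministically (distance, then track ID, then
  canonical detection order), so the result is independent of detection
  ordering within a frame.
* **Measurement**: lumen = mean over the disc shrunk to 0.7 r (excludes
  the membrane ring); background = mean outside all discs dilated 1.2×.

# Flux analysis

* Cumulative protons use β evaluated at the interval-midpoint pH (the
  evaluation point is second-order accurate in the frame-to-frame pH
  step).
* The cumulative curve is smoothed with a Savitzky–Golay filter
  (window 15 frames, order 2; polynomials of degree ≤ 2 are reproduced
  exactly) and differentiated by central differences. Half a smoothing
  window is trimmed from each profile end, where both operations are
  least reliable. In image mode the measured pH series are additionally
  pre-smoothed with the same filter before profile building.
* Profiles are restricted to the analysable window: from proton arrival
  (external pH 0.02 below baseline) to the first frame at which either
  pH series leaves (6, 7.6); under noise the longest contiguous
  resolvable run is used, because the lumen hovers at the saturation
  bound early in the assay.
* **Linear-regime fit** (`fit_permeability_linear()`): OLS through the
  origin of J on Δ[H+] (zero flux at zero gradient is physically
  forced), restricted to frames with per-frame |dpH_i| < 0.1 *and* to
  the small-gradient segment (Δ[H+] ≤ 0.25 of the profile maximum). The
  second gate matters at single-GUV fluxes, where per-frame pH steps
  never approach 0.1 and the flux at larger gradients is already
  GHK-saturated.
* **Charging-aware fit** (`fit_permeability_ghk()`, image-mode default):
  when the lumen dye is saturated at assay start the small-gradient
  segment is unobservable. For strong acids every permeated proton
  carries charge, so Δψ(t) = k·(cum₀ + cum(t)) with k = F r/(3C) and
  cum₀ reconstructed from the lumenal pH at window start; (P, k) are
  fitted jointly to the GHK flux over the whole profile. This estimator
  assumes the capacitive closure and a strong acid; use the linear fit
  for weak-acid data.
* **Potential inversion** (`invert_ghk()`, `profile_potential()`):
  Brent root finding (bisection/interpolation hybrid, stats::uniroot)
  on ±300 mV with tolerance 1e-9 V; uniqueness follows from strict
  monotonicity of the GHK flux in Δψ. Whether the per-vesicle or pooled
  P feeds the inversion is a configuration choice
  (`P_inversion`, default per-vesicle).

# Problem sizes and determinism

The shipped tests and recovery harness use cohorts of 1–10 vesicles,
256×256 px frames, 60–121 frames at 5 s intervals, and dt = 0.05 s —
sizes at which every stage's output is inspectable while each full run
completes in seconds to about a minute. All stochastic stages take
explicit integer seeds; rendering twice with one seed is bit-identical,
and `run_simulate()` writes a manifest (seed, parameters, output
checksum) beside its outputs.

# Known limitations

* The capacitive closure with a single effective C_spec reproduces the
  qualitative Δψ trajectory but is not a quantitative electrolyte model;
  inverted potentials are only as meaningful as the GHK single-ion
  assumption.
* The strong-acid pmf in this model is always ≤ 0 during influx
  (Δψ approaches the Nernst potential from below); reported positive pmf
  maxima from experimental inversions are not reproduced by the forward
  model and are treated as closed-form arithmetic on reported averages.
* The charging-aware fit degrades for weak acids and for vesicles whose
  resolvable window is very short; the pipeline then falls back to
  per-vesicle linear fits or drops the vesicle from the fit table.
* Tracking assumes drift below the gate per frame and non-overlapping
  discs; adhering or overlapping vesicles are out of scope.
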