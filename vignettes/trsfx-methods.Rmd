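---
title: "Models and methods behind trsfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trsfx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trsfx)
```

## What the package models

`trsfx` is a desk-scale simulate-then-analyze toolkit for pump--probe
time-resolved serial femtosecond crystallography (TR-SFX) of ligand
photolysis in a heme protein. A femtosecond optical pulse (the pump)
dissociates CO from the heme iron in a slurry of microcrystals; X-ray
pulses (the probe) take one diffraction snapshot per crystal at a set
delay. Merging many partial snapshots per delay gives structure-factor
amplitudes, from which difference electron density, photoproduct
occupancy, and sub-Angstrom structural dynamics (iron out-of-plane motion,
heme doming, helix recoil) are extracted on the 100 fs -- 10 ps timescale.

Because the real deposited data are not required, the package ships a
generator (`build_two_state_system`, `ground_truth_schedule`,
`interpolate_state`, `simulate_frames`) producing a toy two-state crystal
whose ground truth is known exactly. Every analysis stage is then tested
as a parameter-recovery problem.

## The synthetic two-state crystal

The system is a ~108-atom caricature of a carboxy-heme protein in an
orthogonal P1 box (default 34 x 30 x 28 A): a 25-atom porphyrin core
(Fe + 4 pyrrole N + 20 ring C), a bound CO, a proximal His N-epsilon, and
two ten-residue backbone helices (a proximal "F" helix carrying the His,
and a distal "E" helix). The excited (photolysed) state shares the atom
roster and differs only in coordinates:

* the iron moves `delta_fe` (default 0.28 A) out of the heme plane toward
  the proximal His — a conventional deoxy-like displacement; the true
  refined amplitude in any given protein is system-dependent, so this is
  configuration, not a claim;
* the CO translocates to a docking site ~2.6 A away;
* the proximal helix recoils 0.45 A away from the heme.

Real myoglobin topology, side chains, solvent, crystal symmetry and
anomalous scattering are deliberately absent: the analyses under test are
symmetry-agnostic and the generator's job is to provide exactly known
ground truth, not realism. Passing tests therefore demonstrate the
correctness and statistical behaviour of the estimators on data whose
noise structure (frame scale, partiality, Gaussian intensity error,
timing jitter) is idealized — not their accuracy on real detector images,
which involve indexing errors, non-isomorphism and radiation damage the
generator does not emulate.

## The kinetics schedule

`ground_truth_schedule` fixes the time dependence (all defaults chosen to
match the regimes reported for heme-CO photolysis):

| parameter | default | meaning |
|---|---|---|
| `f_plateau` | 0.8 | true photolysed fraction (complete at t = 0) |
| `tau_occ` | 400 fs | apparent-occupancy rise time constant |
| `w_fast`, `tau_slow` | 0.4, 400 fs | instantaneous fraction and slow phase of the Fe out-of-plane motion |
| `dome_amp`, `tau_dome`, `period` | 0.06 A, 400 fs, 300 fs | damped heme-doming oscillation |
| `jitter_sd` | 100 fs | pump-probe timing jitter |

The photolysis event itself is complete within the pump pulse; what rises
with `tau_occ` is the *apparent* CO* occupancy. Physically, the
photodissociated CO is initially delocalized (large positional spread
contributes no discrete peak) and "narrows" into the docking site; the
crystallographic occupancy read from density peaks therefore lags the
true photolysis yield. Two design choices realize this:

1. **Parameterize the observable.** The schedule prescribes
   `f_app(t) = f_plateau (1 - exp(-t/tau_occ))` for the peak-ratio
   estimator and back-computes the docking-site localized fraction that
   produces it (with the bound-CO density fixed at `1 - f_plateau`). The
   reported time constants for this phenomenon are exponential-rise
   constants of the apparent occupancy, so that is the quantity the
   generator controls exactly.
2. **Test the mechanism separately.** Inflating the CO* B factor at fixed
   true mixing fraction must strictly decrease the apparent peak-ratio
   occupancy — the disorder-masquerading-as-occupancy effect — and the
   test suite checks this monotonicity from B = 15 to 80 A^2.

The functional forms (exponential rise; exponentially damped cosine for
the doming; `w_fast` step plus slow exponential for the iron) are the
package's own choices: the phenomena they emulate are reported as time
constants and periods without fit equations.

## Scattering model

Structure factors are computed by direct summation over point atoms with
B-factor smearing, `F(h) = sum occ_i Z_i exp(-B_i |s|^2/4) exp(2 pi i h.x_i)`,
rather than multi-Gaussian form-factor tables. For a simulate-then-analyze
toolkit this is exactly self-consistent; the amplitudes are *not*
exchangeable with tables computed from real form factors, and the package
never claims otherwise. Resolution defaults: d_min = 1.4 A, low-resolution
cutoff 10 A — the common cutoffs for datasets of this kind.

Maps are synthesized by FFT on a grid with spacing at most d_min/3. Two
difference-map conventions are provided: isomorphous
(F_light - F_dark) amplitudes with dark-model phases, and unweighted
Fo - Fc "omit" maps (m = 1, D = 1: the sigma-A weighting of full
refinement pipelines is out of scope; with synthetic noise the weights
would rescale numerator and denominator of the occupancy ratio together).
Light-to-dark scaling fits isotropic k and relative B by least squares on
amplitudes (Wilson-type two-parameter scaling, profiled over k and
optimized over B with a log-linear initialization).

**Peak heights.** A d_min/3 grid under-samples sharp difference peaks:
node-limited searches miss between-node maxima by up to ~7%. Because a
synthesized map is exactly band-limited, `synthesize_map` stores its
coefficients and `peak_height` refines the discrete maximum by exact
Fourier evaluation (`density_at`) plus quadratic interpolation, reaching
sub-percent agreement with brute-force oversampled maps. Plain trilinear
interpolation remains the point-evaluation path (`search_radius = 0`),
used for titration residual readout where the position, not a maximum, is
prescribed.

## Occupancy estimators

* **Peak ratio** (`occupancy_peak_ratio`):
  `f = rho_CO* / (rho_dark + rho_CO*)` from omit-map peak heights at the
  docking-site and bound-CO positions. Negative heights are clamped to
  zero first (negative noise density has no occupancy meaning). The omit
  model is the two-state mixture with every CO copy removed — the
  fixed-coordinate stand-in for "refine the dark model without CO against
  the light data", since coordinate refinement is outside this package's
  scope. The estimate is invariant to common map rescaling.
* **Multicopy titration** (`occupancy_titration`): for trial occupancies
  (default 0.05 ... 0.95, step 0.05) build the complex two-state mixture
  Fc with coordinates held fixed, compute the Fo - Fc residual map, read
  the residual density at the bound-CO carbon (option: average C and O),
  fit a line through residual-vs-f and return its zero crossing. The
  residual-vs-f relation is mildly curved, which biases a global line fit
  by up to ~0.06 near the ends of the occupancy range; the root is
  therefore refined by a local linear fit within +/-0.2 of the crossing
  (same samples; falls back to the global line when fewer than three
  points are local). Noise-free recovery is then within ~0.01.
* **Extrapolation comparator** (`occupancy_extrapolation` /
  `extrapolate_structure_factors`): amplitude-level extrapolation
  `F_ext = F_dark + (1/f)(F_light - F_dark)` amplifies measurement noise
  by 1/f, which is why it benchmarks worse than the titration; the
  complex-mode variant exactly inverts `mix_states` and serves as the
  oracle quantifying the amplitude approximation.

`benchmark_estimators` runs the full factorial simulate-then-estimate
sweep (true f x noise level x method) behind the estimator-ranking
claims; with default noise the titration's RMSE is below the peak
ratio's, and both track truth within 0.05 noise-free.

## Structural metrics

All metrics operate on labeled atoms, are invariant under rigid-body
motion, and use the four pyrrole nitrogens as the heme reference frame
(matching the out-of-plane definition): total-least-squares plane fit
with the normal oriented toward the proximal His; signed Fe out-of-plane
distance; Fe--His(NE2) distance; Calpha--Calpha difference-distance
matrices; per-atom displacement from the heme-nitrogen centroid (option:
full-core centroid); unweighted radius of gyration over non-hydrogens
(option: mass weights).

The doming coefficient projects the out-of-plane displacement field of
the 25 core atoms onto a unit-norm A2u-like mode vector (iron and inner
ring toward the proximal side, periphery opposite). No community-standard
normalization exists for such a coefficient, so the unit-Euclidean-norm
convention is fixed here; any consistent rescaling only rescales the
curve. Note that a displaced iron also projects onto this mode, so the
measured doming of a full trajectory is a damped cosine riding on a slow
rise; `replay` removes the rise by an exponential fit before fitting the
oscillation.

## Serial statistics

* `bin_by_delay` sorts frames by timing-tool delay and cuts sliding index
  windows (the 20,000-frame/10,000-step scheme, at desk scale). The
  overlap smears time dependence; the smearing is surfaced as the per-bin
  delay SD, which lands in the reported 40--70 fs regime at 100 fs jitter.
* `merge_frames` is Monte-Carlo merging: per-reflection unweighted mean
  intensity (plain mean; sigma-weighted merging is a CrystFEL variant not
  adopted here), F = sqrt(max(mean, 0)), sigma = SD/sqrt(n) on the
  intensity scale, reflections seen < 3 times dropped.
* `fit_exponential_rise` / `fit_damped_cosine` are weighted least-squares
  fits (Levenberg-Marquardt) with multi-starts over a tau grid and over
  phase/period (period initialized from the dominant discrete-spectrum
  component of the detrended, uniformly resampled series). Flat input is
  returned flagged (`amplitude_zero*`) rather than fitted; a series
  shorter than one initial period is an error.
* `bootstrap_metric` resamples frames (serial images, not reflections)
  with replacement, B = 100 by default — the sample-and-replace scheme
  used for coordinate-uncertainty estimates; failed replicates are
  dropped and counted, >20% failures is an error.

## The end-to-end replay

`replay(run_config())` chains everything: simulate frames at each nominal
delay of the default series (150--1300 fs plus a 10 ps plateau anchor,
100 fs jitter) -> pool and sort by actual delay -> sliding-window bins ->
merge -> scale -> omit map -> per-bin apparent occupancy with
frame-bootstrap error bars -> titration of the final bin -> metric curves
-> kinetics fits; the summary compares recovered f_plateau, tau_occ,
tau_OOP and the doming period against the schedule.

Two numerical points deserve note:

* **The structure follows the actual delay.** Frames are given actual
  delays (nominal + jitter) first; the pooled, sorted delays are
  discretized into `n_state_groups` (default 32) quantile groups, each
  diffracting from the state at its mean actual delay. Simulating from
  the nominal-delay state instead would mis-assign structures to frames
  by up to the jitter SD and demonstrably biases the recovered tau_occ
  upward by ~20%.
* **Problem sizes.** Defaults are 400 frames per delay (4,400 total,
  each observing ~30% of ~22,000 reflections at 1.4 A), window 500 /
  step 250, 20 bootstrap replicates per bin. These desk-scale sizes give
  occupancy error bars of ~0.01 and kinetics recoveries within a few
  percent in minutes on one core; they are the package's default study
  conditions, and all are configuration.

Determinism: every stochastic stage draws from the single RNG stream
seeded by `config$seed`; two replays with equal configs are identical.

## Photoexcitation arithmetic

`photons_per_chromophore` converts fluence to nominally absorbed photons
per chromophore via the decadic-to-natural cross-section
`sigma = ln(10) eps 1000 / N_A` and photon energy hc/lambda (CODATA
constants). `peak_power_density` uses the flat-top convention
(fluence/FWHM) — the convention that reproduces the published
40--1,700 GW cm^-2 range — rather than the Gaussian-pulse 0.94 factor.
`penetration_depth` is 1/(ln(10) eps c); the chromophore concentration in
the crystal is a required input (a concentration of ~53.5 mM reproduces
the familiar ~7 um depth at eps = 11,600). `depth_profile` applies
Poisson photon statistics (P of >= 1 and >= 2 absorptions) down the
Beer-Lambert decay, and `crystal_averaged_yield` averages P(>=1) over
depth and a crystal-thickness distribution — reproducing the phenomenon
that plate crystals thicker than the penetration depth cap the photolysis
yield strictly below 100% at saturating fluence. Multi-photon
photophysics beyond this Poisson bookkeeping (excited-state absorption,
stimulated emission, ground-state bleaching) is out of scope.

## Known limitations

* Point-atom form factors and P1 symmetry: outputs are internally
  consistent but not comparable to real deposited amplitudes.
* No coordinate/B refinement: the titration holds both states fixed and
  the omit model is constructed, not refined; biases a refinement engine
  would absorb (e.g. the iron shift partially soaked up by the dark
  model) appear here as small systematic occupancy offsets (~0.03).
* The generator's noise model is exchangeable across frames; it does not
  emulate indexing ambiguities, detector artifacts, non-isomorphism or
  damage.
* Bootstrap error bars quantify counting noise within a bin, not the
  delay-smearing bias of overlapping windows (which is reported
  separately as the bin delay SD).
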