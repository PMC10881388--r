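# trsfx

Desk-scale analysis pipeline for pump–probe **time-resolved serial
femtosecond crystallography (TR-SFX)** of ligand photolysis in heme
proteins — aimed at method developers and students who want the full
simulate → merge → map → occupancy → kinetics chain on a laptop, with
exactly known ground truth instead of terabytes of detector images.

In a TR-SFX experiment an optical pump pulse photodissociates CO from the
heme iron in microcrystals and an XFEL pulse probes each crystal at a set
delay. The quantities this package computes are the ones such studies
report:

* **Photoproduct occupancy** from difference electron density, two ways:
  the peak-ratio estimator
  `f = ρ_CO* / (ρ_dark + ρ_CO*)`
  on mFo–DFc omit maps, and multicopy titration — refine-free mixtures of
  dark and photolysed states scanned over trial occupancy, with the
  occupancy taken where the residual density at the bound-CO site crosses
  zero. Structure-factor extrapolation
  `F_ext = F_dark + (1/f)(F_light − F_dark)` is included as the noisier
  comparator.
* **Structural dynamics metrics**: signed iron out-of-plane displacement
  (OOP_Fe) from the pyrrole-nitrogen plane, Fe–His distance, an
  A2u-like heme doming coefficient, Cα–Cα difference-distance matrices
  (Go plots), displacement-from-heme profiles and radius of gyration.
* **Serial statistics**: timing-tool style sliding-window binning of
  frames by actual delay, Monte-Carlo merging of partial intensities,
  exponential-rise and damped-cosine kinetics fits, and frame-level
  bootstrap uncertainties.
* **Photoexcitation arithmetic**: absorbed photons per chromophore
  n₀ = (fluence/E_photon)·ln(10)·ε·10³/N_A, peak power density,
  Beer–Lambert penetration depth, and depth-resolved Poisson
  single-/multi-photon fractions.

A synthetic two-state crystal generator (toy heme protein, ~108 atoms,
P1) with a femtosecond kinetics schedule stands in for deposited data, so
every estimator is validated by parameter recovery.

## Worked example

```r
library(trsfx)

# photoexcitation regime of a 101 mJ/cm^2, 530 nm, 60 fs pump
photons_per_chromophore(excitation_params(101))   # 11.95 photons/heme
peak_power_density(excitation_params(101))        # 1683 GW/cm^2
penetration_depth(11600, 0.0535)                  # 7.0 um

# simulate a photolysed mixture and recover its occupancy
s  <- build_two_state_system()
fd <- structure_factors(s$dark, d_min = 1.4)
fe <- structure_factors(s$excited, d_min = 1.4)
f_obs <- mix_states(fd, fe, f = 0.6)              # "light" amplitudes
occupancy_titration(f_obs, s, scale = FALSE)$f    # 0.602

omit <- omit_map(f_obs, mixture_omit_model(s, 0.6), scale = FALSE)
sites <- co_sites(s)
occupancy_peak_ratio(omit, sites$dark, sites$excited)$f  # 0.600

# full pipeline: frames -> bins -> merge -> maps -> occupancy -> kinetics
report <- replay(run_config(seed = 3))
report
#> <replay_report>
#>   bins: 16   seed: 3
#>   f_plateau: 0.806 (true 0.800); titration (last bin): 0.799
#>   tau_occ: 395 fs (true 400)   tau_OOP: 373 fs (true 400)
#>   doming period: 287 fs (true 300)
```

The replay numbers read: the apparent CO* occupancy rises exponentially
to a plateau of ~0.81 (scheduled truth 0.80) with a ~400 fs time
constant; the titration of the final (10 ps) bin recovers the true
photolysed fraction; the iron out-of-plane rise and the ~300 fs heme
doming oscillation are recovered from the binned metric curves. Your
exact digits depend on the seed.

See `vignettes/trsfx-methods.Rmd` for the models, conventions and
numerical choices.

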