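---
title: "Models and methods behind dropmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dropmix)
```

# The problem

Time-resolved serial crystallography of enzyme reactions needs the substrate
to reach the crystals *faster* than the catalytic step it is meant to watch.
In drop-on-drop delivery, a piezoelectric injector fires a burst of
picoliter substrate drops onto a nanoliter crystal-slurry drop riding a
tape; the merged drop then travels a fixed path to the X-ray interaction
point, so the tape speed sets the reaction delay. The central quantitative
question is how quickly the merged drop homogenises: by pure Fickian
diffusion mixing takes seconds, while the inertial flow driven by the
collision should mix in well under a millisecond. dropmix implements the
simulations, fluorescence analysis and planning arithmetic needed to make
those statements quantitative and reproducible.

# Chemistry: competitive calcium–dye binding

Mixing is probed with two calcium indicators with very different
affinities, carried at 1 mM each in the main drop:

* Fura Red, $K_D = 400\ \mathrm{nM}$ (high affinity),
* Fluo-5N, $K_D = 90\ \mu M$ (low affinity),

each binding Ca$^{2+}$ reversibly, $\mathrm{Ca} + \mathrm{D} \rightleftharpoons
\mathrm{CaD}$ with $k_{off} = K_D\, k_{on}$. Forward rate constants are not
tabulated for these probes, so both default to a diffusion-influenced
$k_{on} = 10^8\ \mathrm{M^{-1}s^{-1}}$; every absolute kinetic output
scales with this choice and the constants are plain arguments of
`build_dye_network()`. The unique equilibrium of the two-dye competition is
the root of a single monotone equation in free calcium,

$$x + \sum_d \frac{D_d\,x}{x + K_{D,d}} = \mathrm{Ca}_{tot},$$

which `equilibrium_state()` brackets with Brent's method to $10^{-12}$
relative tolerance (a damped fixed-point iteration converges too, but
bracketing cannot diverge and needs no damping schedule, so it is the
implementation). This closed form is used two ways: as the oracle that the
stochastic and ODE engines must relax to, and as the asymptote against
which equilibration times are measured.

# The stochastic engine

`simulate_ssa()` is an exact Gillespie (direct-method) sampler of the
chemical master equation on a compartmental lattice. Channels are
mass-action reactions inside compartments plus per-particle transport
events along directed couplings. In a compartment of volume $V$,

* unimolecular propensity: $k\,n$,
* bimolecular propensity: $k\,n_A n_B / (N_{scale} V)$,
* transport propensity: $r\,n$ per directed coupling,

where $N_{scale}$ is the number of simulated particles per mole. Real
drops hold $\sim 10^{12}$ molecules; counts are scaled so the most
abundant species holds `particle_target` particles (default $10^5$).
Concentrations, and hence means, are unbiased under this scaling; relative
fluctuations are inflated by $\sqrt{N_{real}/N_{sim}}$, which matters only
for the noise floor of the recorded trajectories, not for the
threshold-crossing times read from them. Waiting times are exponential in
the total propensity; channel choice is inverse-transform sampling with a
binary sum tree over compartments, so runs are $O(\log n)$ per event and
bit-reproducible given the seed (one seeded generator per run, the seed
echoed in the result). Volume-averaged concentrations — total particles
over total volume — are recorded on a fixed grid.

Two independent cross-checks accompany the engine in the test suite: the
deterministic mass-action integrator `simulate_wellmixed_ode()` (lsoda,
relative tolerance $10^{-8}$), which the SSA must match within Monte Carlo
error at large counts, and the closed-form equilibrium above. Moiety totals
(calcium, each dye scaffold) are conserved exactly, event by event.

# Geometry: three mixing regimes

*Diffusion only.* `discretize_sphere()` voxelises the 4 nL main drop
(diameter $\approx 197\ \mu m$) into cubic cells of spacing $h$ whose
centres fall inside the sphere; face-adjacent cells are coupled at the
finite-volume hop rate $D/h^2$ per neighbour. The default $h = 10\ \mu m$
puts $\approx 20$ voxels across the drop; the suite checks that halving
$h$ moves the equilibration time by less than 20% at the scales it runs.
Substrate drops are voxelised on the same grid as small spheres resting on
the surface (`surface_caps`), their cells appended and face-coupled, all
substrate starting there; contact sites sit on a latitude ring 45° from
the top pole (the experiment says only that drops land distributed over
the surface, so the ring is a parameter). A resting drop overlaps the main
drop by a fixed wetting depth (default 0.3 of its radius): a tangent-point
contact would have zero diffusive cross-section, and tying the overlap to
the lattice spacing would make the contact area a discretisation artefact,
so the depth is a physical parameter and the equilibration time converges
as the lattice is refined (checked at 20 -> 10 -> 5 µm in the suite).

*Cone jets.* Collisions at Weber numbers of a few (We $= \rho v^2 L/\sigma
\approx 6$ for a 200 µm drop at 1.5 m/s) drive internal jets within a
millisecond of impact. `apply_pei_initial_condition(mode = "cone_jets")`
starts the same diffusive simulation from substrate pre-distributed in
cones reaching halfway to the centre (depth $0.5R$, base radius set by
volume conservation; both configurable — the original jet geometry is not
published, so these are explicit defaults, not fitted values).

*Mass flow.* `build_mass_flow_model()` idealises post-collision inertial
mixing as a chain of $n$ equal-volume compartments spanning the merged
drop, with per-particle transfer rate $v_{rel}/L_{mix}$,
$L_{mix} = d_{drop}/n$, and no diffusion; substrate enters at one end.
This is the standard lower bound on mixing time for purely
convective transport. The default $n = 10$ resolves the concentration
front while keeping the transfer-event rate tractable.

# Equilibration times

`equilibration_time()` reports the first time the volume-averaged
concentration crosses `threshold` × asymptote, linearly interpolated
between samples. The threshold defaults to 0.9 — the experiment never
states one, so it is exposed in the configuration and echoed in every
result. `run_regime()` uses the closed-form equilibrium as the asymptote
(exact, noise-free); when no asymptote is supplied the function estimates
it from the mean of the final 10% of samples and warns if that tail still
drifts by more than 1% — the tail estimator is kept because measured
trajectories have no closed form. Runs that fail to reach the threshold
are extended once (4× the configured horizon) and flagged if they still
fall short. Default horizons are 10 s for the diffusive regimes and 10 ms
for mass flow.

Under the default conditions this yields sub-millisecond equilibration for
mass flow (about 0.1–0.2 ms at 1.5 m/s) versus several seconds for pure
diffusion — the three-orders-of-magnitude separation that motivates the
delivery design. The ordering mass flow < cone jet ≤ diffusion, and the
monotone speed-up with transfer rate, are asserted by paired runs in the
test suite.

# Fluorescence analysis

The optical validation measures emission spectra of the merged drops at
tape speeds between 600 and 10 mm/s (interaction times 0.1–6 s over the
60 mm path). The analysis chain is:

1. *Residence correction*: a drop spends time $\propto 1/v$ in the
   detection volume, so `scale_by_tape_speed()` multiplies intensities by
   $v/v_{ref}$ ($v_{ref} = 100$ mm/s, a control speed).
2. *Spectral unmixing* (`fit_components()`): ordinary least squares of the
   510–750 nm window against four max-normalised components — diode
   scatter, Fluo-5N (peak 515 nm), Ca-free Fura Red (670 nm), Ca-bound
   Fura Red (640 nm) — plus a constant offset. Coefficients are
   deliberately unconstrained in sign.
3. *Rise fitting* (`fit_rise()`): the Ca-dependent scale factors versus
   interaction time are fitted with $s(t) = a(1 - e^{-t/\tau})$ by
   Levenberg–Marquardt least squares, starting $\tau$ from the half-maximum
   time plus four extra starts over a decade; optionally the $k$ earliest
   points are averaged first (the treatment used for weak fast-time
   signals). A single exponential is a summary statistic here, not a
   transport model; data with no time dependence are flagged
   unidentifiable rather than fitted.

The true component spectra are proprietary/instrument-specific, so
`make_component_spectra()` supplies Gaussian surrogates (dye bands 60 nm
FWHM at the published peaks; a narrower 40 nm scatter line at the 455 nm
excitation wavelength whose tail enters the window — narrow enough to be
scatter-like, wide enough to keep the design well conditioned). Measured component
spectra can be loaded from CSV to replace them. Because unmixing is linear
and the surrogates are well-conditioned on the fit window, coefficient
recovery is exact on noiseless synthetics and unbiased under additive
noise; what the surrogates cannot test is component mis-specification in a
real instrument.

# The synthetic-data generator

`synthesize_measurement_series()` emulates the validation experiment: for
each tape speed it computes the interaction time, evaluates the
exponential-rise coefficients, assembles the forward spectrum, applies the
$v_{ref}/v$ residence factor, and adds Gaussian noise expressed as a
fraction of the in-window peak (default 2%; the instrument's actual noise
is unpublished). Ground-truth coefficients are returned with the spectra,
and generation is bit-reproducible from the seed. It does not model
detector spectral response, photobleaching, replicate-to-replicate drop
variation, or baseline drift — so round-trip tests demonstrate estimator
correctness, not instrument robustness.

# Planning arithmetic

The planner functions are exact closed forms with explicit units: merged
concentration $n v_d c/(v_m + n v_d)$ (reproducing the documented 16.7 and
43.7 mM GlcNAc, 110.3 mM ertapenem and 1.5–7 mM CaCl$_2$ endpoints), delay
time $=$ path/speed (0.1–6 s for 60 mm at 600–10 mm/s), burst-versus-
continuous consumption (10 drops at 30 Hz versus 6.1 kHz is a 20.3-fold
reduction), ligand totals (0.18 mL of 0.226 M is 40.7 ≈ 41 µmol) and the
free-solution diffusion-time heuristic $L^2/6D$ (5 µm at
$7.9\times10^{-10}\ \mathrm{m^2/s}$ gives ~5 ms), with the 1-D $L^2/2D$
convention available. No obstruction factor is applied inside crystals;
the heuristic is free solution by construction.

# Numerical choices and problem sizes

* Equilibrium root: Brent on $[0, \mathrm{Ca}_{tot}]$, tolerance
  $10^{-12}$ relative; particle apportionment to compartments by largest
  remainder (deterministic, exact totals).
* SSA: compartment totals maintained incrementally and refreshed from
  scratch whenever a compartment fires, so floating-point drift
  self-corrects; zero total propensity terminates the run as "absorbed"
  with the grid filled from the final state.
* The shipped tests and the acceptance script run the simulations at
  reduced particle budgets ($10^4$–$2\times10^4$ particles for the most
  abundant species) and, for the diffusion regime, a 20 µm lattice —
  chosen so the full suite runs on a laptop-class single core in minutes.
  Equilibration times are threshold crossings of unbiased means, so the
  budget affects their Monte Carlo scatter, not their location; the
  defaults in `mixing_config()` remain $10^5$ particles and 10 µm.
* Mass-flow runs use the midpoint 1.5 m/s of the 1–2 m/s collision
  velocity estimate.

# Limitations

Compartmental mass flow is an idealisation that brackets, not resolves,
the collision hydrodynamics; the cone geometry is a configurable surrogate
for unpublished jet shapes; dye on-rates are literature-typical rather than
measured, so absolute (not relative) equilibration times inherit that
uncertainty; and the spectral surrogates stand in for instrument component
spectra. The package asserts the robust, order-of-magnitude conclusions —
regime ordering, the <1 ms mass-flow bound, the ≥1 s diffusion bound — and
keeps every underlying constant user-visible.
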