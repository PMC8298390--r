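# dropmix

Simulation and analysis toolkit for **drop-on-drop mixing** in time-resolved
serial crystallography. A burst of picoliter substrate drops is fired from a
piezoelectric injector onto a nanoliter crystal-slurry drop on a moving tape;
the merged drop reaches the X-ray interaction point after a delay set by the
tape speed. Whether this starts the reaction fast enough hinges on how
quickly the merged drop homogenises. dropmix answers that with:

* an exact **compartmental Gillespie engine** (C++ core) for
  reaction–diffusion and collision-driven mass-flow simulations of the
  merged drop, with competitive calcium–indicator binding
  (Fura Red, K_D = 400 nM; Fluo-5N, K_D = 90 µM) as the reporter chemistry;
* closed-form equilibrium and deterministic-ODE **oracles** the stochastic
  engine is validated against;
* **spectral unmixing** of fluorescence spectra,
  `f(λ) = s_d·sc_diode + s_fluo·fl_fluo + s_fura−·fl_fura− + s_fura+·fl_fura+ + c`,
  and **exponential rise fitting** `s(t) = a(1 − e^(−t/τ))` with
  residence-time (inverse tape speed) correction;
* a **synthetic-data generator** for the calcium-dye validation experiment;
* exact **planning arithmetic**: merged concentrations, delay times,
  burst-versus-continuous substrate consumption, diffusion-time heuristics.

## Worked example

Simulate the two extreme mixing regimes of the merged 4 nL + 3×60 pL drop
and read off the bound-dye equilibration times (here at a reduced particle
budget so the example runs in ~seconds):

```r
library(dropmix)

mf <- run_regime(mixing_config("mass_flow", t_end = 5e-3,
                               particle_target = 2e4, seed = 7))
mf
#> Mixing regime: mass_flow
#>   FuraBound: mass_flow equilibration (90% of asymptote) at 0.0001214 s
#>   FluoBound: mass_flow equilibration (90% of asymptote) at 0.0001393 s
```

Collision-driven mass flow (substrate drops arriving at 1.5 m/s)
equilibrates both dyes in ≈ 0.12–0.14 ms — comfortably below a
millisecond. Pure diffusion from drops resting on the surface, by
contrast (about two minutes of compute at this resolution):

```r
di <- run_regime(mixing_config("diffusion_only", h_um = 20,
                               particle_target = 1e4, t_end = 12, seed = 7))
di
#> Mixing regime: diffusion_only
#>   FuraBound: diffusion_only equilibration (90% of asymptote) at 3.668 s
#>   FluoBound: diffusion_only equilibration (90% of asymptote) at 5.831 s
```

— seconds, i.e. slower than typical enzyme turnover, and four orders of
magnitude slower than mass flow. The planner reproduces the experiment's
bookkeeping exactly:

```r
merged_concentration(2, 120, 0.226, 3)   # 2 drops GlcNAc -> 16.74 mM
merged_concentration(4, 120, 0.8, 3)     # 4 drops ertapenem -> 110.34 mM
delay_time(60, 600)                      # fastest delay -> 0.1 s
ligand_amount(0.18, 0.226)               # 40.68 umol (~41)
consumption_report(
  dispense_mode("continuous", continuous_rate_hz = 6100),
  dispense_mode("burst", drops_per_trigger = 10, trigger_rate_hz = 30),
  3600)$fold_ratio                       # 20.33-fold burst-mode saving
```

And the fluorescence chain round-trips: synthesise a noiseless
tape-speed series, unmix each spectrum, fit the rise —

```r
cs  <- make_component_spectra()
gen <- synthesize_measurement_series(cs, tau_map = c(fluo = 0.15,
                                                     fura_plus = 0.10),
                                     noise_sd = 0, seed = 1)
pts <- do.call(rbind, lapply(gen$spectra, function(sp) {
  f <- fit_components(scale_by_tape_speed(sp, 100), cs)
  data.frame(t = 60 / sp$tape_speed_mm_s, s = coef(f)[["s_fluo"]])
}))
fit_rise(pts)
#> Exponential rise fit: a = 1, tau = 0.15 s
```

See `vignettes/drop-on-drop-mixing.Rmd` for the models, assumptions and
numerical choices.

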