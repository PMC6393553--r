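# sidmr — dynamic heterogeneity at complex fluid-fluid interfaces

Interfaces stabilized by proteins, polymers, or nanoparticles (the interfaces
of soft interface-dominated materials) respond to a step expansion or
compression not with a simple exponential relaxation but with a *stretched*
one — the fingerprint of dynamic heterogeneity, i.e. relaxation through a
broad distribution of local time scales. `sidmr` is an R package for both
sides of that problem:

* **Tensiometry analysis.** Fit the stretched-exponential-plus-aging model

  γ(t) = a·exp(−(t/τ₁)^β) + b·exp(−t/τ₂) + c

  to step-dilatation surface-stress traces (`kwwfit()`, a classed model
  object with `coef`/`summary`/`predict`/`plot`/`simulate` methods), locate
  the post-step extremum, quantify expansion/compression asymmetry
  (`asymmetry_report()`), and generate realistic synthetic drop-tensiometry
  traces with known truth (`generate_trace()`). β < 1 beyond its standard
  error flags dynamic heterogeneity; the b·exp(−t/τ₂) term absorbs the slow
  aging of the film so it does not contaminate τ₁.

* **Coarse-grained simulation.** A desk-scale bead-spring MD/NEMD engine
  (Rcpp): truncated-shifted Lennard-Jones species W/H/T/O, harmonic and FENE
  bonds, angles and dihedrals, Langevin thermostat, Lees-Edwards shear,
  virial pressure tensor. From it the package extracts the Kirkwood-Buff
  surface tension of slab systems (`surface_tension_kirkwood_buff()`), the
  bulk-interface momentum-transfer (friction) coefficient ζ_xx defined by
  σ_xz = ζ_xx (v_x − v_xˢ) (`run_shear()`, `friction_coefficient()`), and
  the interfacial film morphology class — strand, in-plane cluster, 3d
  cluster, 3d film — from gyration-tensor spectra (`classify_morphology()`).

## Worked example

```r
library(sidmr)

## a synthetic 10% step-expansion experiment at the nanosphere parameters
truth <- kww_params(a = 5, tau1 = 19.5, beta = 0.55, b = 1, tau2 = 2000, c = 50)
trace <- generate_trace(trace_spec(truth, noise_sd = 0.05, seed = 7),
                        deformation_protocol())
fit <- kwwfit(trace)
fit
#> KWW + aging fit (expansion)
#>   beta = 0.5515 (se 0.0068), tau1 = 19.64 s (se 0.37)
#>   a = 4.988, b = 1.033, tau2 = 2141, c = 49.96 mN/m
#>   residual RMS 0.0512 mN/m on 1001 samples, window [1002, 2002] s
```

The fitter recovers the stretch exponent (0.55) and relaxation time (19.5 s)
within their standard errors from a trace carrying realistic 0.05 mN/m
instrument noise, and the residual RMS matches the injected noise level.
Pairing it with a compression fit quantifies the asymmetry that distinguishes
these interfaces from 2d viscoelastic fluids — for nanoparticle films the
stretched behavior disappears entirely in compression (β = 1):

```r
comp <- kww_params(a = -5, tau1 = 62.9, beta = 1, b = -1, tau2 = 2000, c = 50)
fit_c <- kwwfit(generate_trace(trace_spec(comp, noise_sd = 0),
                               deformation_protocol(step_fraction = -0.10)))
asymmetry_report(fit, fit_c)[c("delta_beta", "heterogeneous_expansion",
                               "heterogeneous_compression")]
#> $delta_beta
#> [1] 0.4485361
#> $heterogeneous_expansion
#> [1] TRUE
#> $heterogeneous_compression
#> [1] FALSE
```

On the simulation side, a sheared symmetric liquid-liquid interface carrying
an H₅T₅ diblock film yields the friction coefficient:

```r
pr <- desk_interface_system(n = 5, count = 10, L = 10, Lz = 20, seed = 105,
                            steps_slab = 5000, steps_equil = 5000)
sr <- run_shear(pr$system, pr$forcefield, pr$topology,
                shear_rate = 0.06, steps = 21000, seed = 205, n_bins = 20)
estimate_friction(sr)$zeta_xx
#> [1] 2.207418
```

(magnitude, in reduced stress per velocity units, with a desk-scale
uncertainty of about 1.3 — at these system sizes only trends across block
size n are meaningful, not absolute values).

A command-line front end (`inst/cli/sidmr`) exposes the same stages as
subcommands (`fit`, `simulate-trace`, `md-run`, `nemd-run`, `friction`,
`morphology`) with JSON output and provenance logs.

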