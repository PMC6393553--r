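---
title: "Dynamic heterogeneity at complex fluid-fluid interfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic heterogeneity at complex fluid-fluid interfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidmr)
```

## The scientific problem

Fluid-fluid interfaces stabilized by proteins, polymers, or nanoparticles do
not behave like the homogeneous two-dimensional viscoelastic fluids formed by
small surfactants.  When such a complex interface is subjected to a step
expansion or compression in a drop tensiometer, the surface stress
$\gamma(t)$ relaxes as a *stretched* exponential rather than a simple one --
the signature of **dynamic heterogeneity**, relaxation governed by a broad
distribution of local relaxation times.  `sidmr` implements the two
computational halves of studying this phenomenon:

1. **Experiment-side**: fitting the relaxation model to step-dilatation
   surface-stress traces (and generating realistic synthetic traces to
   validate the fitter);
2. **Simulation-side**: a desk-scale coarse-grained bead-spring MD/NEMD
   engine for copolymer-stabilized interfaces, from which the bulk-interface
   momentum-transfer (friction) coefficient, the Kirkwood-Buff surface
   tension, and the interfacial film morphology class are extracted.

## The relaxation model

The post-step surface stress is modelled as

$$\gamma(t) = a\,e^{-(t/\tau_1)^\beta} + b\,e^{-t/\tau_2} + c,$$

a Kohlrausch-Williams-Watts (KWW) stretched exponential superposed on a
regular exponential **aging** term and an offset.  The parameters, with units:

| parameter | meaning | unit | typical magnitude |
|---|---|---|---|
| `a` | stretched-term amplitude (sign follows the step direction) | mN/m | a few |
| `tau1` | KWW relaxation time | s | 10--30 |
| `beta` | stretch exponent, $(0,1]$ | -- | 0.4--0.6 (expansion), 0.5--1 (compression) |
| `b` | aging amplitude | mN/m | order 1 |
| `tau2` | aging time | s | $10^3$--$10^4$ |
| `c` | stress offset | mN/m | tens |

$\beta < 1$ (beyond its standard error) flags dynamic heterogeneity; the
aging term decouples the step response from the slow post-adsorption
restructuring of the film, which is present even without deformation.  The
derived mean relaxation time is
$\langle\tau\rangle = (\tau_1/\beta)\,\Gamma(1/\beta)$, computed with R's
`gamma()` special function.

### Fitting protocol

`kwwfit()` follows tensiometry practice: the fit uses samples from the
post-step extremum of the surface stress (maximum in extension, minimum in
compression, searched within three step durations after the step) through a
1000 s window, with time re-zeroed at the extremum.  Numerical choices:

* **Optimizer.** Bounded Levenberg-Marquardt least squares
  (`minpack.lm::nls.lm`) with uniform weights (the tensiometer gives no
  per-sample error model).  KWW least-squares surfaces are multi-modal, so
  the fit is restarted from a grid of `tau1` log-spaced in `[1, window/2]`
  crossed with `beta` in {0.4, 0.6, 0.8, 1.0} (16 restarts by default; extra
  restarts jitter the grid under the supplied seed).
* **Bounds and identifiability.** `0.05 <= beta <= 1`, `tau1, tau2 > 0`, and
  the aging time is reparameterised as `tau2 = 5 * tau1 * exp(r)` with
  `r >= 0`, which enforces `tau2 >= 5 tau1` exactly: the aging term is
  required to be the slow background, otherwise the two exponentials can
  trade roles.  `tau2` is initialised at ten times the window.
* **Tie-breaking.** Among converged restarts the lowest residual sum of
  squares wins; near-ties (relative difference below 1e-8) resolve toward
  the larger `beta`, preferring the less-stretched explanation over spurious
  tiny-`beta` minima.
* **Uncertainties.** Standard errors come from the Jacobian-based covariance
  at the optimum (central differences on the natural parameter scale,
  pseudo-inverse of the Gauss-Newton Hessian, residual variance with
  `n - 6` degrees of freedom) -- the convention of standard curve-fitting
  tools.  On short windows the aging pair `(b, tau2)` can be weakly
  identified; the pseudo-inverse keeps the remaining errors meaningful.
* **Degenerate inputs.** All-restart failure returns a flagged
  (`converged = FALSE`) result rather than an error; a window extending past
  the trace end truncates with a recorded warning; fewer than 30 in-window
  samples refuse outright.

`asymmetry_report()` compares an expansion fit with a compression fit:
$\Delta\beta = \beta_\mathrm{comp} - \beta_\mathrm{exp}$, the ratio of
relaxation times, and per-phase heterogeneity flags
($1 - \hat\beta > \mathrm{se}(\hat\beta)$).

```{r fit-example}
truth <- kww_params(a = 5, tau1 = 19.5, beta = 0.55, b = 1, tau2 = 2000, c = 50)
trace <- generate_trace(trace_spec(truth, noise_sd = 0.05, seed = 7),
                        deformation_protocol())
fit <- kwwfit(trace)
summary(fit)
```

## The synthetic-tensiometry generator

No raw tensiometry traces are published, so the generator emulates the drop
tensiometer protocol: an adsorption phase (1000--6000 s in practice; the
constructor accepts 1000--21600 s), an area step of 10--20% applied linearly
over 2 s, then KWW-plus-aging relaxation with time zeroed at the step end,
plus i.i.d. Gaussian measurement noise at the 0.01--0.1 mN/m level of the
instruments, sampled at 1 s.  Design choices, fixed once:

* The adsorption phase is modelled as `amp * exp(-t/tau') + (c + b)` with
  `tau' = 2000` s by default -- much slower than `tau1`, matching the
  long-time-tail character of protein/nanoparticle adsorption, which the
  source experiments characterise only qualitatively.
* The actuator ramp is linear in time (the tensiometer's true profile is
  unspecified).
* The stabilizer parameters `beta` and `tau1` used as generation truths in
  the tests are published values; the remaining constants are not printed in
  the main text, so the fixtures fix `a = 5`, `b = 1`, `tau2 = 2000` s,
  `c = 50` mN/m -- magnitudes typical of air-water protein films.
* Identical spec + seed gives a bit-identical trace; paired
  expansion/compression experiments share the adsorption baseline (one drop,
  one history).

What passing the recovery tests does and does not show: the generator's
traces satisfy the fitted model exactly by construction (plus white noise),
so parameter recovery validates the *fitter* -- extremum location,
windowing, multi-start optimization, uncertainty calibration -- not the
model's adequacy for real films, and not robustness to correlated
instrument noise, drift, or Young-Laplace analysis artefacts, none of which
the generator emulates.

## The coarse-grained simulation engine

All simulation code works in reduced Lennard-Jones units
($\varepsilon = \sigma = m = k_B = 1$); unit conversion is left to the user.
Species are W (water-like solvent), H (hydrophilic block), T (hydrophobic
block), O (oil-like solvent).

* **Pair interactions**: truncated-and-shifted Lennard-Jones; cutoff
  $2.5\,\sigma$ keeps the attractive branch, $2^{1/6}\sigma$ is purely
  repulsive (WCA).  The NEMD preset follows the symmetric surfactant rule:
  every well depth equal, identical pairs plus H-W and T-O attractive, all
  other pairs repulsive.  For the liquid-vapor systems the non-bonded
  parameter table of the source study is not published; the package's `"lv"`
  preset (identical pairs and H-W attractive; T-W and H-T repulsive) is its
  own convention for an amphiphile at a liquid-vapor interface, overridable
  per matrix entry.
* **Bonded terms**: harmonic bonds (`k = 1000`, `l0 = 1`) for the
  equilibrium copolymers; FENE bonds (`k = 30`, `l0 = 1.5`, diverging at
  `l0`) for the sheared H$_n$T$_n$ diblocks; harmonic angles
  (`theta0 = pi`) and cosine dihedrals on the middle block of triblocks make
  it rigid.  Angle/dihedral stiffnesses (`k_a = 50`, `k_d = 5`, `d = 1`) are
  package defaults standing in for unpublished values, all overridable.
  Directly bonded (1-2) pairs are excluded from the non-bonded loop; 1-3 and
  1-4 pairs are retained, following common bead-spring practice.
* **Integration**: velocity Verlet at `dt = 0.006` time units; the Langevin
  thermostat (damping time 1.0) enters through BAOAB splitting, which
  reduces exactly to velocity Verlet when the friction is zero.  A Langevin
  thermostat was chosen because it is local and robust for slab systems with
  vapor regions, where a global rescaling thermostat couples badly to the
  dilute phase.  The thermostat's noise stream is a dedicated,
  platform-independent generator, so runs are bit-reproducible for a given
  seed.
* **Neighbor search**: a linked-cell list feeds a Verlet pair list with a
  0.4 sigma skin, rebuilt when accumulated displacement could let a pair
  slip through; small boxes fall back to an exact all-pairs scan.  Cell-list
  results are tested identical to an O(N^2) oracle.
* **Shear**: Lees-Edwards sliding-brick boundaries (gradient along z, flow
  along x).  The box-image offset advances continuously; particles crossing
  the z faces pick up the image velocity; the minimum-image convention
  carries the offset.  During shear the thermostat acts only on the y and z
  velocity components, so the streaming profile is not biased and no
  streaming-velocity estimator is needed.  This is the closest
  boundary-driven analogue of shearing the box without introducing wall
  physics.
* **Pressure and surface tension**: the virial tensor accumulates pairwise
  and bonded contributions;
  $\gamma = (L_z/2)\left[\langle P_{zz}\rangle - \tfrac12(\langle
  P_{xx}\rangle + \langle P_{yy}\rangle)\right]$ for a two-interface slab
  (Kirkwood-Buff route).  Shear stress is taken from the global off-diagonal
  virial averaged over steady-state samples ($\sigma_{xz} = -\langle
  P_{xz}\rangle$); a per-slab Irving-Kirkwood stress is not implemented --
  at desk scale its statistical error would dominate, and flux uniformity is
  instead checked through the antisymmetry of the velocity profile.

### System construction

`create_slab_system()` equilibrates a bulk liquid and doubles the box along
z (liquid-vapor), or fills the box with a W|O|W sandwich of equal solvent
counts (liquid-liquid).  `insert_copolymers_by_identity_swap()` converts
chains of adjacent interfacial solvent particles into copolymer beads --
connecting them with bonds and relabeling them -- so the particle count and
total density are exactly unchanged; chains are split evenly between the two
interfaces, and for liquid-liquid systems the H beads come from the W side
and the T beads from the O side.  Chain growth is a seeded random walk on
the contact graph with up to 100 retries per chain.

### Friction (momentum-transfer) coefficient

At a sheared interface the steady shear stress and the velocity jump between
bulk and film obey $\sigma_{xz} = \zeta_{xx}\,(v_x - v_x^s)$: `v_x` is the
bulk velocity profile linearly extrapolated to the interface plane (the
equimolar/density-crossing plane from `locate_interface()`), `v_x^s` the
mean film velocity, which is nearly constant across the film at these
densities.  Defaults, both overridable because the construction is not
prescribed anywhere: the bulk fit region spans 3--10 sigma from the
interface on the bulk side -- clipped at the box face, since the Lees-Edwards
image velocity is discontinuous across it, and widened back toward the
interface (staying 1.5 sigma clear of the film) when the clipped region holds
fewer than three bins, as happens on desk-scale boxes -- and the surface
region is a bead-scale band (1.5 sigma) centred on the interface plane.  A
film-density-peak construction was tried and rejected: the hydrophobic
blocks dissolve into the oil phase and smear the film density, so on small
boxes the peak wanders away from the interface.  When the velocity jump
falls below its own propagated uncertainty the estimator reports the
perfect-coupling limit (`unresolved`) instead of a number.
`estimate_friction()` combines the two interfaces of a slab by
inverse-variance weighting of the *magnitudes*: on desk boxes the sign of
the jump can flip, because the copolymer brush (whose thickness is
comparable to the available bulk) shifts the velocity gradient outward by
roughly its own thickness, an effect that competes with interfacial slip.
The magnitude of the jump still scales with the film thickness, so
$|\zeta_{xx}|$ falls roughly as $1/n$ for H$_n$T$_n$ films and the product
$\zeta_{xx}\,n$ is constant within desk-scale uncertainties -- the trend the
acceptance suite checks.

### Morphology classification

Interfacial films organise into classes of effective dimension $d_e$:
strands ($d_e \approx 1$), in-plane clusters ($1 \le d_e \le 2$), 3d
clusters ($2 \le d_e \le 3$), and 3d films ($d_e \approx 3$).  No
algorithmic definition of these classes is published, so the classifier's
thresholds are declared package conventions (and flagged as such in its
printed output): single-linkage clustering at 1.5 sigma (the first-neighbor
shell of the LJ liquid), gyration-tensor eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ computed after unwrapping each
cluster across the periodic boundaries, anisotropy ratio 8 for strands,
bead-monolayer thickness 1.5 sigma, lateral percolation = the cluster spans
the periodic box in x or y.  The continuous score
$d_e = 1 + g(\lambda_2/\lambda_1) + g(\lambda_3/\lambda_1)$ with
$g(x) = \min(1, x/f)$, $f = 0.1$, is a smoothed eigenvalue count -- a
heuristic, not a fractal dimension; it is monotone under flattening a blob
along the interface normal.

## Problem sizes and what desk scale can and cannot show

The published simulations use boxes of $50.56\,\sigma$ with order $10^5$
particles and $10^5$--$10^6$ steps.  The package ships those geometries as
YAML configurations (`inst/configs/`), flagged long-running, but all tests
and the reproduction script run **desk-scale presets**: boxes of 9--12
sigma, 500--2500 particles, and $10^4$--$5\times10^4$ step runs, sized so
the whole suite completes in minutes on one CPU.  Consequences, stated
plainly: interfacial fluctuations and finite-size effects are much larger;
friction coefficients carry tens-of-percent uncertainties, so only trends
(sign, ordering, the constancy of $\zeta_{xx} n$) are meaningful, never
absolute magnitudes; morphology classes are exercised on constructed
geometries rather than on long self-assembly runs.

One measured limitation: at `dt = 0.006` the instantaneous total energy of
an NVE Lennard-Jones liquid fluctuates and wanders by a few times
$10^{-4}\,\varepsilon$ per particle over $10^4$ steps -- the O(dt^2)
shadow-Hamiltonian error of velocity Verlet, reproduced identically by an
independent minimal implementation at the same state point.  The acceptance
suite's stricter $10^{-4}$ drift bound therefore fails honestly at this
time step; halving `dt` quarters the excursion, and the gentle two-particle
benchmarks conserve energy to better than $10^{-5}\,\varepsilon$.

## Reproducibility

Every stochastic stage takes an integer seed and is bit-reproducible:
synthetic traces, thermostat noise (a self-contained Mersenne-Twister +
Box-Muller stream in the engine), chain insertion, and fit restarts.
`provenance_log()` records the configuration hash, seed, and package version
beside every command-line run, and any result JSON regenerates identically
from its recorded config and seed.
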