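---
title: "Models and methods behind evapLLPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evapLLPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evapLLPS)
```

evapLLPS models how evaporation drives segregative liquid–liquid phase
separation (LLPS) inside a sessile droplet of a PEG/dextran aqueous
two-phase system (ATPS), and what the resulting dextran-rich compartments do
for a ribozyme cleavage reaction. This vignette is the package's account of
each model, its assumptions, the tunable parameters, and the numerical and
design choices.

## Droplet evaporation

A pinned sessile droplet is a spherical cap described by its contact radius
$a$ and contact angle $\theta$. For diffusion-limited evaporation the water
mass loss rate is

$$\left|\frac{dM}{dt}\right| = \pi a D\,(n_s - n_\infty)\, f(\theta),
\qquad
f(\theta) = \frac{\sin\theta}{1+\cos\theta}
 + 4\int_0^\infty \frac{1+\cosh 2\theta\tau}{\sinh 2\pi\tau}
   \tanh[(\pi-\theta)\tau]\, d\tau,$$

with $D$ the vapour diffusivity and $n_s - n_\infty$ the vapour-concentration
difference between the droplet surface and the ambient air. Two closed forms
anchor $f$: the hemisphere $f(\pi/2) = 2$ and the flat disk
$f(\theta\to 0) = 4/\pi$.

*Quadrature.* The integrand of $f$ has the finite limit $(\pi-\theta)/\pi$
at $\tau = 0$ (taken analytically to avoid 0/0) and decays like
$e^{-2(\pi-\theta)\tau}$; beyond $\tau = 6$ the hyperbolic ratio is replaced
by its asymptotic exponential so that `stats::integrate` never overflows.
The quadrature is converged to better than $10^{-8}$ relative over the
working range $\theta \in (0, \pi/2]$.

*Local flux.* Evaporation from a pinned droplet diverges towards the contact
line. The package adopts the edge power law globally,
$J(r) = C\,(R_0 - r)^{-1/2}$, and fixes $C$ so the disk integral of $J$
reproduces the total rate exactly (the annulus integrals of the integrable
singularity are analytic). This is the regime that matters here, because the
kinetic-pathway analysis only ever uses the outermost 5% of the radius.

*Pinned-cap evolution.* `evolve_droplet()` subtracts the evaporated volume
per step at fixed contact radius and re-inverts the cap relation for
$\theta$ (bisection), stopping at a configurable floor (default 5°) where a
pinned thin-film description stops being meaningful. Under the default room
conditions ($D = 2.5\times 10^{-5}\,$m²/s, $n_s = 2.3\times10^{-2}\,$kg/m³
at 22 °C, 60% relative humidity — package defaults, to be replaced by
measured values when available) a 0.5 µL, 45° droplet loses about 1 µg/s and
sweeps the experimentally observed 45°→25° contact-angle band within a few
minutes.

## The polymer phase plane and the kinetic pathway

Compositions live in the $(w_\mathrm{dex}, w_\mathrm{peg})$ plane (mass
fractions; water implied). The binodal is represented by a Merchuk-type
curve

$$w_\mathrm{peg} = B(w_\mathrm{dex})
  = a\, e^{\,b\sqrt{w_\mathrm{dex}} + c\,w_\mathrm{dex}
  + d\,w_\mathrm{dex}^3},$$

which is log-linear in its coefficients, so `fit_binodal()` is an ordinary
linear regression of $\log w_\mathrm{peg}$ — the natural estimator under the
multiplicative noise the generator produces — with coefficient standard
errors taken from the same regression. A fit that is not strictly decreasing
over its validity range is rejected. Compositions exactly on the curve are
single-phase by convention (strict inequality defines the two-phase region).

Tie lines use a constant slope (default −0.55; the slope is a configurable
model input, to be fitted from measured tie lines when available).
`tie_line_through()` intersects the line through a two-phase composition
with the binodal by bisection on both sides, and `lever_rule()` splits the
bulk by distances to the endpoints: the dextran-rich to PEG-rich mass ratio
equals the ratio of the distances to the PEG-rich and dextran-rich
endpoints. Mass balance (bulk = mass-weighted endpoints) holds to $10^{-8}$
by construction and is property-tested.

*Kinetic pathway.* The calculation domain is the edge annulus of width
$0.05\,R_0$; with the $(R_0-r)^{-1/2}$ flux it carries a fixed 33% of the
total evaporation regardless of droplet size. Every 5 s step removes that
water mass from the annulus liquid (solution density default 1030 kg/m³),
concentrates both polymers by $1/(1-\phi)$ — water-only removal, so the
PEG:dextran ratio and the annulus polymer mass are exactly conserved — and
re-tests the binodal. Once two-phase, the tie line, lever split and tie-line
length (TLL) are attached. Each step re-splits the whole annulus composition
from scratch; the coexisting phases are not tracked separately afterwards,
which matches presenting the pathway as a sequence of successive bulk
compositions. Under the default conditions the annulus loses ~29% of its
mass in the first step, so both stock mixtures (5/10 and 9/4 wt%
PEG/dextran) cross the binodal within 5 s — consistent with compartments
appearing at the rim within seconds.

*Regimes.* Two pattern morphologies exist: coalescing lobe-shaped
dextran-rich domains (regime 1) when the first split produces comparable
phase masses, and dispersed dextran-rich droplets (regime 2) when the
dextran-rich phase is a small minority. `classify_regime()` offers the
mechanistic route (first-split mass ratio, threshold 0.5 — a tunable chosen
midway between the two observed ratios ≈1.1 and ≈0.09) and the empirical
composition map (below 4 wt% dextran: dispersed iff PEG > 2× dextran; above:
dispersed iff PEG > 7 wt%).

*Synthetic phase diagram.* No coexistence table ships with the package, so
`default_synthetic_binodal()` provides a frozen PEG-8000/dextran-10000-like
curve ($a = 0.3555$, $b = -5.22$, $c = 0$, $d = -18.3$, valid for
$w_\mathrm{dex} \in [0.001, 0.5]$, tie slope −0.55). Its shape was fixed
once so that (i) both stock compositions are single-phase, (ii) both cross
the binodal on the first evaporation step, (iii) the first-split lever
ratios (1.21 and 0.13) fall on the two sides of the regime threshold with
roughly the observed magnitudes, and (iv) the constant-slope tie lines of
the first two steps intersect the curve inside the validity range. It is a
synthetic stand-in, not a measured diagram; analyses of real systems should
fit their own table with `fit_binodal()`.

## Capillary versus Marangoni flow

Surface tension dominates gravity for these droplets: the Bond number
$Bo = \rho g a^2/\gamma \approx 0.12$ for 0.5 µL at 45° with
$\gamma = 64$ mN/m.

The edge-peaked evaporation drives the outward "coffee-ring" flow. Its
depth-averaged velocity comes from mass conservation in the film,
$\bar u(r) = \frac{1}{\rho r h}\int_0^r (\rho\dot h - J)\,r'\,dr'$, with the
surface-lowering rate $\dot h(r)$ obtained from the pinned-cap family
$h(r;\theta(t))$ and the volumetric loss rate. Evaluated at $0.95\,R_0$
(the inner edge of the calculation domain) this gives ~1.3 µm/s under
default conditions — the same order as the ~6 µm/s inward front speed it
competes with.

PEG is surface active, so the composition jump created by LLPS at the rim
lowers the surface tension there and drives an inward Marangoni flow. Two
balances are implemented in `required_delta_gamma()`:

* **pressure** (default): Marangoni stress against the capillary (Laplace)
  pressure of the cap acting across the film,
  $\Delta\gamma = \tfrac{1}{2} h_\mathrm{edge}\,(2\gamma/R_s)$. This gives
  ~2.2 mN/m for the default droplet — the mN/m scale a surfactant-driven
  reversal actually needs.
* **velocity**: the exact inversion of the lubrication velocity scale
  $u_M = \tfrac{1}{2}\Delta\gamma\, h/(\mu L)$ at the capillary velocity;
  it answers a different question (what $\Delta\gamma$ makes the *film
  velocities* equal) and yields values several orders smaller. It is kept
  because it is the exact algebraic inverse of `marangoni_velocity_scale()`
  and is round-trip tested.

The linear surface-tension model (default slope −0.05 N/m per unit
$w_\mathrm{peg}$, anchored at 64 mN/m for 5 wt% PEG) makes the composition
jump across the first split worth ~3.8 mN/m — comfortably above the ~2 mN/m
requirement, which is the feasibility argument for the Marangoni-driven
reversal. The O(1) lubrication coefficient (default 1/2, plane-Couette
depth average) is exposed in both functions.

*Front kinematics.* The phase-separation front radius $R_2(t)$ retreats
linearly (advective transport, $L = R - R_2 \sim t$, in contrast to the
$\sqrt t$ of diffusive fronts). `detect_front()` locates $R_2$ in a radial
intensity profile as the centroid of the half-maximum region around the
largest smoothed-gradient magnitude (moving average, default window 7
samples ≈ one front width at the packaged sampling density; outermost
maximizer on exact ties). Profiles without a gradient peak at least twice
the median gradient — flat or featureless monotone ramps — return a no-front
signal. `psf_linear_fit()` is ordinary least squares of $R_2(t)$.

## Ribozyme cleavage in a partitioned compartment

Cleavage S → P is modelled with Michaelis–Menten kinetics; the
substrate–enzyme complex is eliminated (its concentration is negligibly
low), and the two short products are lumped into one field. Substrate and
product diffuse with equal constant $D$ in a spherical domain of radius
$R_d = 10$ µm while the ribozyme is uniform:

$$\partial_t s = D\nabla^2 s - \frac{k_\mathrm{cat}\,e\,s}{K_M+s},\qquad
  \partial_t p = D\nabla^2 p + \frac{k_\mathrm{cat}\,e\,s}{K_M+s}.$$

Length-dependent partitioning enters only through the boundary data: the
43-nt ribozyme partitions strongly ($K_E$, enzyme enriched to $K_E e_b$
throughout), the 14-nt substrate moderately (boundary value $K_S s_b$,
a constant supply), and the 8/6-nt products barely ($p = 0$ sink — short
chains escape freely). The water-droplet scenario is identical with
$K_E = K_S = 1$; the product sink is kept there too, since identical
surroundings impose no barrier. A `closed` (reflecting) configuration
exists purely as a test harness.

*Defaults* (all overridable; literature-typical hammerhead values, not
fitted): $k_\mathrm{cat} = 0.017$ s⁻¹ (≈1 min⁻¹), $K_M = 10^{-4}$ mol/m³
(0.1 µM), $D = 10^{-10}$ m²/s, $e_b = 10^{-5}$, $s_b = 10^{-4}$ mol/m³,
$K_E = 50 \ge K_S = 5 \ge K_P = 1$ (the ordering is enforced — it is the
length-dependence itself).

*Numerics.* Method of lines on a uniform radial grid (default 200 nodes)
in conservative finite-volume form: spherical-shell cell volumes double as
the volume-integral weights, so interface fluxes telescope and the closed
configuration conserves $\int (s+p)\,dV$ to solver tolerance by
construction; the centre cell reproduces the analytic $x\to 0$ limit
$3\,\partial_{xx}$. Time integration uses the stiff sparse solver `lsodes`
(deSolve), relative tolerance $10^{-8}$. The well-mixed large-$D$ closed
limit is verified against the implicit integrated Michaelis–Menten progress
curve $K_M\ln(s_0/s) + (s_0 - s) = k_\mathrm{cat} e\, t$ to $10^{-6}$, and
the productivity plateau is grid-converged to <0.5% between 100 and 200
nodes.

*Productivity.* With a constant substrate supply, the cumulative amount of
substrate ever converted grows without bound, so it cannot define a
"maximum productivity". The package therefore defines
$m_p(t') = \int p\,dV / (V s_b)$ — the product inventory held in the domain,
on the diffusive clock $t' = Dt/R_d^2$ — which saturates when diffusive
escape through the boundary balances production. That plateau and the time
to reach 95% of it (interpolated between saved samples) are the two-scenario
comparison surface; the cumulative-conversion normalization remains
available as `type = "converted"`. With the default parameter set the
compartment's plateau is ~83× the water droplet's while both approach their
plateaus on the same diffusive timescale (ratio ≈ 1): the enrichment ratio
scales with $K_E K_S$, while the approach time is set by $R_d^2/D$, which
partitioning does not change. Larger contrasts in the *time* ratio require
parameter sets in which the water-droplet reaction is far from its diffusive
steady state at the end of the run; the ratios reported by
`compare_scenarios()` are therefore strong functions of the kinetic
parameters, and both ratios reduce exactly to 1 when all partition
coefficients are 1 (property-tested). The plateau ratio is nondecreasing in
$K_E$ (property-tested).

## Synthetic data generators

Three seeded generators stand in for the external measurements the pipeline
would otherwise need; every generator attaches its ground truth as an
attribute (and `write_synthetic_csv()` writes it to a JSON sidecar) so
recovery tests close the loop:

* `synth_binodal_table()` — coexistence points on the Merchuk curve with
  multiplicative log-normal noise, plus exact tie-line endpoint pairs.
* `synth_mass_timeseries()` — the pinned-cap mass trajectory with additive
  Gaussian noise (weighing noise does not scale with the signal).
* `synth_front_profiles()` — radial sigmoid steps marching inward at
  constant speed (default 6 µm/s) with additive noise.

They are deterministic given a seed and restore the caller's RNG stream.
What they do *not* emulate: contact-line pinning defects, the late-stage
inhibition of Marangoni convection in the thinning film, coarsening and
coalescence of compartments, spatial nonuniformity of the tie-line slope,
or imaging artefacts. Tests passing on these generators validate the
numerics and estimators, not the field-worthiness of the underlying
physical simplifications.

## Problem sizes and runtime choices

The shipped tests use 60–200 radial nodes for the reaction–diffusion
solves, 100-replicate recovery ensembles, 500 random lever-rule splits and
50 random geometry/ambient pairs; the full suite runs in well under a
minute, and each two-scenario comparison takes a fraction of a second at
200 nodes. These sizes were chosen as the smallest at which every
convergence criterion above is comfortably met.

## Known limitations

* The flux power law is the edge asymptote applied globally; fine for the
  edge annulus, increasingly crude near the droplet centre.
* Constant tie-line slope; real slopes drift with quench depth, and at very
  deep quench the line can leave the binodal's validity range (the pathway
  then reports the split as unresolved).
* The pathway does not model transport between the annulus and the droplet
  interior, nor per-phase evolution after a split.
* The reaction–diffusion domain is stationary: no coupling to evaporation,
  advection, compartment growth or coalescence, and no RNase degradation —
  the compartment enhancement is accordingly an upper estimate.
* Contact angles at or above 90° and unpinned (receding) contact lines are
  out of scope.
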