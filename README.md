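# evapLLPS

Modelling toolkit for **evaporation-triggered segregative liquid–liquid
phase separation (LLPS) in a sessile droplet** of a PEG/dextran aqueous
two-phase system (ATPS), and for the reaction advantage the resulting
dextran-rich compartments give a ribozyme cleavage reaction. It is aimed at
people studying membraneless compartmentalization — droplet microfluidics,
ATPS physics, origins-of-life model systems — who want the quantitative
backbone of that experiment as reusable, tested code.

The package covers four connected models:

1. **Evaporation.** A pinned spherical-cap droplet evaporates
   diffusion-limited at rate
   `|dM/dt| = pi a D (n_s - n_inf) f(theta)`, where the contact-angle
   factor is

   ```
   f(theta) = sin(theta)/(1 + cos(theta))
            + 4 * Int_0^Inf (1 + cosh(2 theta tau)) / sinh(2 pi tau)
                  * tanh((pi - theta) tau) d tau
   ```

   with the closed-form anchors `f(pi/2) = 2` and `f(0+) = 4/pi`. The local
   flux diverges towards the pinned contact line as
   `J(r) ~ (R0 - r)^(-1/2)`, normalized so its disk integral equals the
   total rate.

2. **Phase plane and kinetic pathway.** The binodal is a Merchuk-type curve
   `w_peg = a exp(b sqrt(w_dex) + c w_dex + d w_dex^3)`; tie lines have a
   constant slope and the lever rule splits any two-phase composition into
   its PEG-rich and dextran-rich endpoint masses. The kinetic pathway
   concentrates the droplet-edge annulus (width `0.05 R0`, time step 5 s)
   by the water the edge flux removes, and tracks when and how the mixture
   crosses the binodal — the first-split mass ratio separates lobe-forming
   (regime 1) from dispersed-droplet (regime 2) morphologies.

3. **Hydrodynamic scalings.** Bond number, the outward coffee-ring
   (capillary) velocity from film mass conservation, the surface-tension
   difference an inward Marangoni flow needs to beat it, and linear
   kinematics of the phase-separation front `R2(t)` with a gradient-based
   front detector.

4. **Compartmentalized ribozyme kinetics.** Michaelis–Menten
   reaction–diffusion of substrate and product in a 10 µm spherical domain,
   with length-dependent RNA partitioning encoded in the boundary
   conditions; `compare_scenarios()` quantifies how a dextran-rich
   compartment outperforms a plain water droplet in dimensionless
   productivity `m_p(t')`.

Seeded synthetic-data generators emulate every external input (coexistence
table, droplet-mass weighing series, radial front profiles), each carrying
its ground truth for closed-loop recovery tests.

## Worked example

A 0.5 µL droplet (45° contact angle) of 9 wt% PEG / 4 wt% dextran under 60%
relative humidity:

```r
library(evapLLPS)

geom    <- droplet_from_volume(0.5e-9, 45 * pi / 180)
ambient <- ambient_conditions(relative_humidity = 0.6)
geom
#> <droplet_geometry> a = 0.8991 mm, theta = 45.00 deg, V = 0.5 uL
total_evaporation_rate(geom, ambient)   # ~9.74e-10 kg/s, i.e. ~1 ug/s

bin <- default_synthetic_binodal()
pw  <- kinetic_pathway(composition(w_peg = 0.09, w_dex = 0.04),
                       geom, ambient, bin$curve,
                       tie_slope = bin$tie_slope, n_steps = 2)
as.data.frame(pw)
#>   step time_s w_peg  w_dex annulus_mass_kg two_phase ratio_dex_to_peg
#> 1    0      0 0.090 0.0400        5.50e-09     FALSE               NA
#> 2    1      5 0.127 0.0565        3.90e-09      TRUE            0.128
#> 3    2     10 0.216 0.0959        2.29e-09      TRUE            0.238
#>   mass_frac_dex_rich   tll
#> 1                 NA    NA
#> 2              0.113 0.252
#> 3              0.192 0.552
```

The edge annulus crosses the binodal within the first 5 s; the first phase
split makes the dextran-rich phase a ~8× mass minority
(`ratio_dex_to_peg = 0.128`), so this droplet forms dispersed dextran-rich
droplets rather than coalescing lobes, and the tie-line length (quench
depth) grows with further evaporation:

```r
classify_regime(composition(0.09, 0.04), "lever_ratio",
                binodal = bin$curve, geom = geom, ambient = ambient)
#> [1] "regime2"

fluid <- fluid_properties()
bond_number(fluid, geom)                                   # 0.128
1e6 * capillary_velocity_scale(geom, ambient, fluid)       # 1.30 um/s outward
1e3 * required_delta_gamma(geom, ambient, fluid)           # 2.15 mN/m
```

Surface tension dominates gravity (Bo ≈ 0.13), the coffee-ring outflow is a
few µm/s, and a ~2 mN/m surface-tension difference — less than the ~3.8 mN/m
the LLPS composition jump provides — suffices to reverse it with an inward
Marangoni flow.

```r
cmp <- compare_scenarios(rd_parameters(), rd_grid(n_nodes = 120))
cmp$plateau_ratio            # 83.3: compartment productivity plateau vs water
cmp$time_to_plateau_ratio    # 1.00: both plateau on the diffusive timescale
```

With the default kinetic parameters the enzyme-enriched, substrate-fed
compartment holds an ~83× higher steady product inventory than the same
domain in plain water.

The full pipeline (evaporation → pathway → regime → Marangoni → ribozyme)
runs from one config: `run_pipeline(out_dir = "results/run1")`, writing CSVs,
JSON summaries and a manifest. A template config ships in
`inst/extdata/default_config.json`.

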