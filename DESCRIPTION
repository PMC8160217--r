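Package: evapLLPS
Title: Evaporation-Triggered Liquid-Liquid Phase Separation in Sessile
    Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the physics of segregative liquid-liquid phase
    separation (LLPS) triggered by evaporation in a sessile droplet of a
    PEG/dextran aqueous two-phase system. Implements diffusion-limited
    spherical-cap evaporation with the Popov contact-angle factor and its
    edge-divergent flux, the binodal/tie-line/lever-rule machinery of the
    polymer phase plane with the evaporation-driven kinetic pathway of
    phase separation in the droplet-edge annulus, scaling analyses of the
    competing capillary and Marangoni flows, and a Michaelis-Menten
    reaction-diffusion model of ribozyme cleavage inside a partitioned
    spherical compartment. Seeded synthetic-data generators emulate the
    coexistence table, droplet-mass time series and phase-separation-front
    profiles needed to exercise every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
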