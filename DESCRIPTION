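Package: nanokin
Title: Diffusion-Controlled Kinetics of Nanoparticle-Induced Membrane Damage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic modelling of silver-nanoparticle-induced damage to
    macrophage plasma membranes. Implements Stokes-Einstein transport and the
    empirical water-viscosity law, the Smoluchowski diffusion-limited rate
    constant with its transient correction and a radial finite-difference
    oracle, an Arrhenius-based effective rate constant modulated by the cell's
    antioxidant-defense death probability P2(T), the closed-form dead-cell
    time course, least-squares inference of P2 with coefficient of
    determination, activation-energy profiles across temperature, and a
    seeded generator of synthetic membrane-integrity assay data with binomial
    field-of-view counting noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
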