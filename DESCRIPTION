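Package: cuticleflux
Title: Mechanistic Modelling of Ionic Agrochemical Penetration Through
    Plant Cuticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates foliar uptake of hydrophilic ionic active
    ingredients (such as calcium chloride) through isolated plant
    cuticles from an evaporating sessile droplet.  The model couples
    quasi-one-dimensional Fickian diffusion of solute and water through
    swelling aqueous nanopores (Langmuir water adsorption, fractal
    tortuosity scaling of the effective diffusivity) with a
    diffusion-limited sessile-droplet evaporation model extended for the
    hygroscopic, deliquescent behaviour of ionic solutions, surfactant
    effects on contact angle and point of deliquescence, and irreversible
    ion binding at the cuticle surface.  Includes validation suites
    across applied concentrations, one-factor-at-a-time sensitivity
    analysis, Nelder-Mead parameter estimation against penetration
    curves, and a synthetic penetration-curve generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
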