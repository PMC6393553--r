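Package: sidmr
Title: Dynamic Heterogeneity at Complex Fluid-Fluid Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the relaxation dynamics of complex
    (protein-, polymer-, or nanoparticle-stabilized) fluid-fluid interfaces.
    Fits a Kohlrausch-Williams-Watts stretched-exponential-plus-aging model
    to step-dilatation surface-stress traces from drop tensiometry, generates
    synthetic tensiometry traces for validation, and ships a desk-scale
    coarse-grained bead-spring molecular dynamics engine (Lennard-Jones
    liquids, FENE/harmonic copolymers, Langevin thermostat, Lees-Edwards
    shear) from which the bulk-interface momentum-transfer (friction)
    coefficient, Kirkwood-Buff surface tension, and interfacial film
    morphology class are extracted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
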