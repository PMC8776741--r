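Package: imkfit
Title: Two-Population Integrated Microdosimetric-Kinetic Cell-Survival Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form surviving fractions under the integrated
    microdosimetric-kinetic (IMK) model for acute, split-dose, protracted
    and multi-fractionated irradiation of cell populations composed of
    progeny cells and radioresistant cancer stem-like cells. Includes the
    split-dose estimator of the sub-lethal damage repair (SLDR) rate,
    Bayesian Metropolis MCMC joint fitting of parental and radioresistant
    clonogenic-survival data, and a seeded synthetic clonogenic-assay data
    generator for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
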