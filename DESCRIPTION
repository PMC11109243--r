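Package: mesochrom
Title: Phase-Field Simulation of Mesoscale Nuclear Chromatin Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the mesoscale organization of chromatin in the
    interphase nucleus with a two-field phase-field model: a conserved
    nucleoplasm volume fraction and a heterochromatin-euchromatin order
    parameter evolve under Cahn-Hilliard diffusion, active epigenetic
    (acetylation/methylation) reactions, and transcription-driven
    supercoiling-mediated loop extrusion localized to domain interfaces.
    Includes sharp-interface theory for mean phase fractions, droplet
    growth, steady domain radius and lamina-associated-domain (LAD)
    thickness; a quantification toolkit for segmenting and measuring
    heterochromatin domains in 2D density fields; scenario orchestration
    (control, transcription inhibition, WAPL depletion) with calibration
    of the extrusion rate; and synthetic planted-shape fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    rlang,
    Matrix,
    EBImage,
    tibble,
    dplyr,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
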