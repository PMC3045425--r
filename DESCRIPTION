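Package: petidif
Title: Image-Derived Input Functions for Dynamic Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and comparison framework for image-derived arterial
    input functions (IDIF) in dynamic brain PET. Generates synthetic arterial
    input functions, two-tissue-compartment tissue kinetics, and a digital
    head phantom with carotid arteries imaged through a two-Gaussian point
    spread function with frame-dependent noise. Implements seven published
    carotid IDIF extraction methods (Chen, Mourik, Naganawa, Su, Parker,
    Backes, Croteau), metabolite correction, Logan graphical analysis and
    unconstrained two-tissue compartment modelling, and the figures of merit
    (AUC ratios, distribution-volume ratios and a scoring rule) used to
    compare them.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
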