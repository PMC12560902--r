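Package: tagburden
Title: Hydrodynamic Drag and Energetic Burden of Animal-Borne Tags on Pelagic Sharks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the hydrodynamic and energetic burden that externally
    attached biologging tags impose on pelagic sharks. Converts drag
    coefficients from computational fluid dynamics sweeps (packaged
    coefficient tables for a lamnid body plan, or user-supplied CSV) into
    drag forces, daily energy expenditure under glide/cruise/burst activity
    budgets, equal-power burst-speed compensation, and tag-to-body weight
    ratio rule checks. Includes Reynolds-number and inlet-turbulence
    utilities for setting up external CFD cases, a friction-line surrogate
    generator for synthetic coefficient sweeps with parameter-recovery
    fitting, and reference-table reporting for tag-impact assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
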