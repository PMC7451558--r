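Package: hopperburn
Title: Digital-Image Phenotyping of Planthopper Damage in Rice Seedling
    Seed-Box Tests
Version: 0.1.0
Authors@R:
    person("Seedbox", "Imaging Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring planthopper damage to rice seedlings from
    colour photographs taken during seedling seed-box resistance screens.
    Segments seedling patches from their background by colour range,
    summarizes foreground pixels into mean red-green-blue reflectance,
    converts channel means to normalized RGB and hue-saturation-brightness,
    computes two- and three-colour vegetation indices (GMR, GDR, NGRDI,
    VARI, GLI, TGI, DGCI), standardizes test time, scores condition change
    of each variety against a susceptible check, and provides permutation
    inference (PERMANOVA-style pseudo-F, pairwise and many-to-one
    permutation tests, principal coordinates ordination). A synthetic
    screening-experiment generator reproduces the colour-trajectory
    structure of planthopper damage so the whole pipeline can be exercised
    without access to greenhouse data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
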