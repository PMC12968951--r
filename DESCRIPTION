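Package: trapsurv
Title: Multi-Scale Analysis of Trap-Based Forest Insect Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing multi-trap surveillance
    networks for bark- and wood-boring beetles around points of entry.
    Computes a trap-scale urbanization index from local tree cover and
    barrier-free angle, incidence-based diversity statistics (Chao2
    richness, sample completeness, sample coverage with rarefaction and
    extrapolation), the replacement component of beta diversity among
    traps, and sampling-effort-reduction simulations (random and
    urbanization-ordered trap removal with percent-species-loss curves).
    Includes mixed-model fits of trap catches against urbanization, a
    calibrated synthetic-study generator for method validation, and an
    end-to-end pipeline with reproducible seeded outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmmTMB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
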