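Package: crispropt
Title: Optimal Number of Spacers in CRISPR Arrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative model of CRISPR-Cas adaptive immunity that predicts the
    number of spacers a CRISPR array should carry. Implements steady-state effector
    occupancy under geometric crRNA allocation, interference kinetics, Poisson
    infection survival, exact and Monte-Carlo averaging over spacer-to-species
    assignments in multi-virus pools, grid-search optimization of array size and
    crRNA decay coefficient, calibration of the interference efficiency from a
    measured single-spacer interference probability, and the burst-minimization
    variant with rescaled interference efficiency. Includes a command-line
    front-end and a seeded fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
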