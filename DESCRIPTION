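Package: loopmc
Title: Monte Carlo Simulation of Protein-Mediated DNA Looping
Version: 0.1.0
Authors@R:
    person("loopmc", "maintainers", email = "loopmc@example.org", role = c("aut", "cre"))
Description: Base-pair-step Monte Carlo machinery for protein-mediated DNA
    looping. DNA is modelled as a chain of rigid base-pair steps (tilt, roll,
    twist, shift, slide, rise) fluctuating about the ideal B-form rest state
    under a quadratic elastic potential; architectural HU dimers decorate the
    chain with sharp, untwisted 14-step bends, and Lac-repressor end
    conditions close the chain in one of four loop orientations with a
    variable opening angle. Looping and cyclization J factors are estimated by
    direct enumeration or by half-chain pairwise combination with spatial
    hashing, and a thermodynamic partition-function bridge converts looping J
    factors to and from reporter-gene repression measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
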