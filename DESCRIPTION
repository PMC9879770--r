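Package: multishift
Title: Shape-Shifting Multifarious Self-Assembly with Non-Reciprocal
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grand-canonical kinetic Monte Carlo simulation of multifarious
    self-assembly on a square lattice, extended with programmable
    non-reciprocal interactions that drive autonomous, sequenced transitions
    between stored target structures.  Several target structures, each a
    random permutation of distinct tile species, are encoded in a shared
    table of orientation-specific reciprocal bonds; directed non-reciprocal
    "approach" weights bias the arrival of tiles of the next structure in a
    programmed sequence, turning an equilibrium associative-memory assembler
    into an autonomous shape-shifter.  The package provides the interaction
    compilers, the compiled Monte Carlo engine, observables (cluster overlap,
    assembly error, energy, density, entropy production, shift detection and
    timescales, regime classification, structure colouring), replica and
    parameter-scan drivers for phase diagrams and shift statistics, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
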