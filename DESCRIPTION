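Package: epferm
Title: Uniform-Design Medium Optimization and Structured Growth Kinetics for
    Ergosterol Peroxide Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing a submerged-fermentation medium and for
    modelling batch growth of the producing fungus. Implements U-type uniform
    designs built by the good-lattice-point method with centered L2
    discrepancy column selection, a mixed quadratic/linear response-surface
    model with stationary-point optimization of the medium recipe, one-way
    ANOVA with Monte-Carlo Dunnett many-to-one comparisons reconstructed from
    summary statistics, four structured growth models (Monod, Contois,
    Andrews, Aibe) with yield-coupled batch and fed-batch simulation, fitting
    of their integrated linearized forms with kinetic-parameter recovery, and
    seeded synthetic-data generators so the whole pipeline is testable
    without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
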