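Package: ssims
Title: Simulation of Genetic Biocontrol with Sex-Sorting Incompatible Male Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates genetic biocontrol of pest Drosophila with engineered
    strains that combine engineered genetic incompatibility (EGI, an
    underdominance-like post-zygotic mating barrier) with X-linked
    tetracycline-repressible female lethality (the SSIMS architecture), and
    compares them with RIDL and female-lethal-only strategies. Provides exact
    Mendelian gamete and cross enumeration for the engineered loci, a
    tetracycline dose-response model with maternal carryover, a synthetic
    daily-temperature climatology, a degree-day driven agent-based model of a
    Spotted Wing Drosophila field season under scheduled releases, a
    discrete-event laboratory cage-trial protocol, release-grid sweep drivers,
    and Hill dose-response fitting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
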