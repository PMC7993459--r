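Package: pcgpipe
Title: Phylogenetic Core Groups: Community Assembly Simulation and Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates microbial community assembly on phylogenies (trait
    evolution with divergence, convergence and horizontal gene transfer;
    neutral and selective dispersal-limited sampling) and implements a
    detection pipeline for phylogenetic core groups (PCGs): community-class
    discovery from beta-diversity, per-class neutral community model fitting
    with per-taxon departure calls, nearest-taxon-index dispersion tests,
    PCG determination by hierarchical sequence clustering at descending
    identity thresholds, and a final niche-type classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    cluster,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
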