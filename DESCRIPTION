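Package: scMaxCut
Title: Single-Cell A/B Compartment Calling from 3D Chromosome Structures
    by Semidefinite Max-Cut
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates A/B chromatin compartments in individual cells from
    3D chromosome structures (chromatin-tracing imaging or structure models).
    Each single-cell chromosome trace is embedded as a weighted graph whose
    edge weights combine spatial distance, genomic separation and nuclear
    speckle proximity; the two compartments are recovered as the maximum cut
    of that graph via the Goemans-Williamson semidefinite relaxation with
    randomized hyperplane rounding. Includes ensemble compartment statistics
    (compartment frequency, normalized frequency, variability), structural
    features (radial position, radius of gyration, nuclear-body distances,
    interchromosomal contacts), contact- and distance-based
    compartmentalization scores, baseline compartment callers (distance-matrix
    PCA, CG-content phasing, Hi-C PCA) and a synthetic trace generator with
    planted compartments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
biocViews: Epigenetics, SingleCell, Spatial, GraphAndNetwork, HiC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
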