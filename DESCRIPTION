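Package: mirTherapy
Title: miRNA-Seq Differential Expression, Biomarker Pairs and In Silico
    miRNA Therapy Simulation on Mass-Action Signaling Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for small-RNA sequencing analysis of matched
    normal/tumor/metastasis cohorts and for in-silico miRNA treatment
    studies. Implements on-target read counting over miRNA annotation
    intervals, median-centered log2-ratio differential expression with
    per-patient t-tests, detection Venn partitions, delta-delta-Ct
    validation math, Mann-Whitney biomarker ranking with exhaustive
    two-marker linear-separability screening, a mass-action reaction
    network model with SBML import/export, Monte Carlo kinetic-parameter
    ensemble steady-state simulation, synthesis-rate dose perturbation of
    miRNA target genes, and classification of per-component expression
    shifts into ten therapeutic-effect subgroups across a dose grid.
    Includes seeded synthetic-data generators for every input so the full
    pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    xml2,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
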