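Package: metafst
Title: Population Differentiation of Marine Protists from Metagenomic Allele Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates genomic differentiation (pairwise and global FST) of a
    marine microbial species from per-station metagenomic allele-count tables,
    builds geographic (least-cost over-sea), environmental (PCA-based) and
    oceanographic (Lagrangian connectivity) distance matrices between sampling
    stations, and attributes drivers of differentiation
    (isolation-by-distance versus isolation-by-environment) with an exhaustive
    BIC-selected linear model on normalized genomic distances. Includes a
    synthetic-data generator (Balding-Nichols island model, logit-Gaussian
    process isolation-by-distance, environmental-effect scenarios) with known
    ground truth so the full pipeline can be exercised and validated without
    any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    geosphere,
    vcfR,
    MASS,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
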