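Package: rdascape
Title: Landscape Genomics by Redundancy Analysis, Spatial Eigenvectors and
    Genome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions SNP variation of geographically structured plant
    populations into environmental, spatial-autocorrelation and
    population-structure components using simple and partial redundancy
    analysis (RDA) with distance-based Moran's eigenvector maps (dbMEM).
    Provides the supporting population-genetic statistics: Hudson-style
    ratio-of-averages FST, Nei (1972) distance, neighbor-joining trees,
    likelihood-free ancestry-coefficient factorization, allele-sharing
    distances, unPC gene-flow anomaly scores with a Box-Cox/Student-t
    outlier test, Hill-Weir linkage-disequilibrium decay fitting, and an
    RDA-based Mahalanobis genome scan with genomic-inflation correction
    and FDR control. A synthetic-data module simulates selfing populations
    over a landscape with isolation by distance, a dispersal barrier,
    collinear environmental gradients and a minority of environmentally
    selected loci, with a full ground-truth record, so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    geosphere,
    igraph,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
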