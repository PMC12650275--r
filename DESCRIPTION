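Package: gutlink
Title: Gut Microbiome-Phenotype Integration Analysis for Feeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis toolkit for small-replicate feeding-trial microbiome
    studies: ASV-table diversity profiling (rarefaction, Bray-Curtis, PCoA,
    group partition arithmetic), normality-gated group statistics with
    compact-letter displays and 2^-ddCt qPCR quantification, per-ASV
    differential abundance screening, correlation-module mining with module
    eigenvectors and Mantel-test phenotype linking, molecular ecological
    network analysis with random-network nulls and Fisher-test module
    preservation, Sloan neutral community model fitting, and a Tax4Fun-style
    functional projection. Ships a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    vegan,
    igraph,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
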