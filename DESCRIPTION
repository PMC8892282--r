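Package: surfaceomics
Title: Cell-Surfaceome Classification and Endocytome Target Prioritization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a curated cell-surfaceome classifier from annotation-source
    exports (merge, curation, transmembrane/GPI topology categorization),
    preprocesses label-free proteomics abundance tables (low-abundance
    resampling imputation of missing values, total-intensity normalization),
    filters identities to classifier members, computes differential protein
    expression with an inclusive log2 fold-change up-regulation partition
    across surface and endocytosed fractions, runs preranked gene-set
    enrichment (weighted Kolmogorov-Smirnov running sum with label
    permutation) and hypergeometric pathway overrepresentation, ranks shared
    surface/endocytome proteins into abundance quadrants to prioritize
    antibody-drug-conjugate candidate targets, maps mouse symbols to human
    orthologs, and generates synthetic annotation and abundance fixtures with
    planted effects and intensity-dependent missingness for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
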