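Package: exitpaths
Title: Multi-Trajectory Analysis of Drug-Induced Exit from the Proliferative Cell State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing how non-cytotoxic drug perturbations move
    cancer cells out of the proliferative state, using transcriptome time
    courses under many drugs at once. Implements Z-score hit calling for
    high-content differentiation screens, an error model from untreated
    replicate arrays, divergent-convergent trajectory classification of genes
    into dynamic categories (C1-C5), modified Pearson dispersion statistics
    over the time course, chemical/target/efficacy similarity measures with a
    permutation null for shared drug targets, and the CAP-Net algorithm that
    intersects per-drug shortest-path networks between drug targets and
    differentially expressed genes on a protein-interaction network. A
    synthetic-data module generates all pipeline inputs with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
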