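Package: tetraqtl
Title: Multi-Allelic QTL Mapping in Autotetraploid Bi-Parental Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identity-by-descent (IBD) based QTL interval mapping for
    autotetraploid F1 populations such as tetraploid potato. Provides a
    tetrasomic meiosis simulator (bivalent and quadrivalent pairing with
    double reduction), homologue-dosage grids derived from parental
    gamete-class probabilities, naive single-locus genome scans by
    constrained regression on homologue dosages with permutation-based
    genome-wide LOD thresholds, homologue-effect estimation, exhaustive
    bi-allelic QTL model search ranked by the Schwarz information
    criterion, cofactor (composite) QTL analysis on residuals, and
    phenotype statistics (ANOVA variance components, broad-sense
    heritability, REML best linear unbiased estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
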