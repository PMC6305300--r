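Package: apoenet
Title: APOE Genotype Effects on Brain Proteomic Networks and Cell Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-level pipeline for label-free quantitative (LFQ)
    proteomics of post-mortem brain across APOE genotypes in Alzheimer's
    disease: missing-value filtering and Gaussian-downshift imputation,
    connectivity-based sample outlier removal, bootstrap covariate
    regression with a PCA verification check, signed weighted protein
    co-expression networks (biweight midcorrelation, topological overlap,
    dynamic hybrid tree cut, module eigenproteins and kME, module-trait
    correlations), per-protein ANOVA with Tukey pairwise tests, exclusive
    cell-type marker construction with Fisher enrichment, linear-model
    cell-type deconvolution (digital sorting), direction-split
    "homeostatic" versus "disease-associated" marker eigenprotein analysis,
    and domain-level tau (MTBR) and amyloid-beta peptide quantification.
    Includes a synthetic-cohort generator that emulates the statistical
    structure of such cohorts so every stage is testable without access to
    the original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
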