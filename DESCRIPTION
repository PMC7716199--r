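Package: rdmassoc
Title: Case-Control SNP and Haplotype Association with Randomized
    Matched Sub-Sampling in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A candidate-gene case-control association pipeline for
    admixed populations: PLINK text PED/MAP input, SNP and sample
    quality control with Hardy-Weinberg exact testing, allelic and
    covariate-adjusted logistic SNP association with
    Benjamini-Hochberg FDR, a randomized confounder-matched
    sub-sampling (RDM) inference procedure, EM-based haplotype
    frequency estimation and haplotype association, genotype PCA for
    population structure, and analytic power for two-proportion
    tests. Includes a Balding-Nichols admixture simulator with
    ancestry-correlated confounders so the whole analysis runs on
    synthetic data.
License: MIT
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
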