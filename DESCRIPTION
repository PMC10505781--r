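Package: rrgwas
Title: Longitudinal Single-Step GWAS with Random Regression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-step genomic BLUP for repeatedly measured traits modelled
    with Legendre-polynomial random regressions, and the associated
    longitudinal genome-wide association workflow: pedigree and genomic
    relationship matrices (A-inverse, A22, VanRaden G with blending and
    tuning, H-inverse), assembly and iterative solution of the mixed model
    equations, Gibbs-sampling estimation of random-regression covariance
    components, back-solving of age-specific SNP effects from genomic
    breeding values with prediction-error-variance based P-values, and
    multiple-testing correction through the effective number of independent
    SNP. A gene-dropping simulator generates pedigrees, genotypes and
    longitudinal phenotypes with the exact covariance structure the model
    assumes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
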