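Package: gxepower
Title: Gene-by-Physical-Activity Interaction Analysis and Power Simulation for BMI
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying interactions between a genetic risk score (GRS)
    and physical activity on body mass index. Implements construction of an
    unweighted 12-SNP obesity risk score with quality control and
    missing-genotype imputation, derivation of the Cambridge Physical Activity
    Index from occupational and leisure-time questionnaire categories, linear
    and logistic interaction regression with covariate adjustment,
    sample-size-weighted and inverse-variance meta-analysis with heterogeneity
    statistics, and a Monte-Carlo power and sample-size framework for
    interaction terms with a closed-form analytic oracle. A synthetic cohort
    generator reproduces the statistical structure the analysis assumes
    (Hardy-Weinberg genotypes, normal GRS, correlated binary activity via a
    Gaussian copula, linear BMI model), so every stage is testable without
    individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), metafor, emmeans, vcfR
Config/testthat/edition: 3
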