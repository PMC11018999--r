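Package: mrpipe
Title: Two-Sample Mendelian Randomization Pipelines from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: harmonization of exposure and outcome effects to a
    shared effect allele, instrument selection (genome-wide significance,
    greedy LD clumping, outcome-association exclusion, Steiger
    directionality filtering, per-SNP F screening), univariable estimation
    with multiplicative random-effects inverse-variance weighting, MR-Egger,
    the weighted median and MR-PRESSO outlier detection, multivariable MR,
    two-step mediation with delta-method inference, inverse-variance
    meta-analysis across consortia, binary-outcome power calculation and
    sample-overlap bias diagnostics, plus a seeded synthetic summary-statistic
    generator with known causal truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), metafor, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
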