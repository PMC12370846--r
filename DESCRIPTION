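Package: mrmediate
Title: Two-Sample Mendelian Randomization with SMR/HEIDI Validation and
    Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Summary-data Mendelian randomization (MR) toolkit built around a
    three-stage causal screen: instrument selection from GWAS summary
    statistics (genome-wide significance, MAF filter, greedy LD clumping,
    F-statistic strength filter), allele harmonization with
    frequency-based resolution of palindromic SNPs, five causal
    estimators (IVW fixed and multiplicative random effects, MR-Egger,
    weighted median, weighted and simple mode), a sensitivity cascade
    (Cochran's Q, Egger intercept, leave-one-out, MR-PRESSO), SMR and
    HEIDI tests separating a shared causal variant from linkage, and
    two-step mediation MR with product-of-coefficients decomposition and
    directional-consistency filtering. A synthetic summary-statistics
    generator with known truth (LD blocks, instrument effects,
    exposure-mediator-outcome chains, pleiotropy, shared-causal vs
    linkage regions) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
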