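Package: ccfreq
Title: Case and Control Allele Frequencies from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs case-specific and control-specific allele
    frequencies from genome-wide association study (GWAS) summary
    statistics. Two closed-form routes are provided: one solves a quadratic
    in the control allele frequency given the odds ratio, total-sample
    allele frequency, and case/control sample sizes; the other recovers the
    full 2x2 allele-count table from the odds ratio and the standard error
    of the log odds ratio, returning folded minor allele frequencies. A
    proxy-panel bias correction (binned second-order polynomial
    regressions) removes the covariate-induced underestimation of the
    standard-error route at common variants. A liability-threshold GWAS
    simulator with vectorized per-variant logistic regression and Lin's
    concordance correlation coefficient utilities support accuracy
    evaluation, and delimited-text readers/writers plus a command-line
    interface handle heterogeneous summary-statistics formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
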