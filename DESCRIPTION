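Package: mrbench
Title: Simulation Benchmarking of Two-Sample Mendelian Randomization
    Estimators in One-Sample Designs
Version: 0.1.0
Authors@R:
    person("mrbench", "maintainers", email = "mrbench@example.org",
           role = c("aut", "cre"))
Description: Simulates individual-level cohorts with confounded exposure and
    outcome errors and genetic instruments of exponential-family strength,
    reduces them to per-SNP summary statistics, and benchmarks six causal
    effect estimators (IVW fixed- and multiplicative random-effects, weighted
    median, weighted mode, MR-Egger regression and two-stage least squares)
    for bias, precision, coverage and root mean square error in one-sample
    and two-sample Mendelian randomization. Includes instrument diagnostics
    (per-SNP F statistics, variance explained, the I-squared statistic of the
    gene-exposure estimates, Cochran's Q, and a residual-correlation
    decomposition of the correlation between gene-exposure and gene-outcome
    estimation errors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
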