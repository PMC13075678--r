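Package: heattol
Title: Screening Wheat Genotypes for Terminal Heat Tolerance from
    Two-Sowing-Date Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for yield-based screening of wheat genotypes for terminal
    heat tolerance in multi-environment trials where late (spring) sowing
    imposes heat stress during flowering and grain filling. Computes the ten
    standard stress tolerance and sensitivity indices (HSI, YSI, STI, TOL,
    MP, GMP, YI, HM, MRP, PYR), classifies genotypes by heat susceptibility
    index, and performs composite mean-rank selection. Provides balanced
    combined analysis of variance over sowing dates and years under a
    randomized complete block framework, variance-component extraction by
    expected mean squares, broad-sense heritability, Fisher's LSD, Pearson
    trait correlations with significance flags, and principal component
    analysis of standardized genotype means. Includes a synthetic trial
    generator with genotype, sowing-date, year and interaction variance
    components so the whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
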