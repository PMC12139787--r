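Package: fieldsel
Title: Analysis of Multi-Site Sow-and-Sequence Selection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for field selection experiments in which equal numbers of
    seeds from a panel of inbred accessions are sown at several sites and
    fitness is read out as genotype frequency among sampled descendants.
    Provides a synthetic-study generator (structured genotype panels,
    Wright-Fisher reproduction, degraded low-coverage genotype calls, native
    volunteers), assignment of field-sampled genotypes to panel accessions
    with mismatch-rate classification, geographic filtering of cryptic native
    contamination via isolation-by-distance, frequency-based fitness
    estimation with exact group-pattern statistics, a drift-null allele
    frequency selection scan with effective-population-size estimation, and a
    liability-threshold model linking survival probabilities between
    environments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
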