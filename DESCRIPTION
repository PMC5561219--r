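Package: duosweep
Title: Detect Convergent and Divergent Artificial Selection Between Two
    Domestication Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A genome-scan toolkit for contrasting two wild/domestic
    population pairs (e.g. Chinese and European wild boars and domestic
    pigs). Implements sliding-window Weir-Cockerham Fst with genome-wide
    Z-transformation, permutation-based empirical p-values, the H12
    haplotype-homozygosity statistic with sample-size-matched
    subsampling, allele-frequency identity scores against an ancient
    genome to separate introgression-then-selection from
    pre-introgression selection, a normalized identity-by-descent
    (nIBD) summary, and a seeded founder-haplotype simulator that
    generates phased cohorts with known per-region selection scenarios
    for end-to-end validation. All user-facing functions take and
    return tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
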