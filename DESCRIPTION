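Package: missweave
Title: Replay Empirical Missing-Genotype Structure onto Simulated Replicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Degrades simulated diploid genotype data so that it resembles
    empirical data, with a focus on ancient-DNA workflows. Fits a per-sample,
    per-block missingness profile from an empirical genomic segment and
    replays it onto smaller simulated replicates via block partitioning and
    resampling; provides a beta-distribution missingness baseline,
    genotype-degradation operators (unphasing, depolarization, deamination,
    pseudohaploidization, sequencing error), conversion between VCF, ms-style
    and EIGENSTRAT/ANCESTRYMAP text formats, PLINK-style missingness
    summaries, and dynamic-time-warping comparison of per-site missingness
    signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
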