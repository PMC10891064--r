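Package: rhizoqmp
Title: Quantitative Microbiome Profiling and Co-Occurrence Ecology for
    Root-Associated Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative microbiome profiling (QMP) of
    root-associated bacterial communities sampled over plant development:
    spike-in calibration of amplicon read counts to absolute abundance
    (16S copies per gram), relative profiling with rarefaction, alpha and
    beta diversity with ordination and PERMANOVA, temporal turnover and
    divergence regressions on Bray-Curtis dissimilarity, differential
    load testing (stage-averaged paired Wilcoxon with a fold-change
    gate), thresholded Spearman co-occurrence networks with module
    detection, within/among-module connectivity (Zi/Pi) keystone roles
    and random-removal robustness, and rule-based design of synthetic
    communities (SynComs) from cultured isolates matched to network
    modules. Includes a synthetic-data generator that plants known
    absolute abundances, module structure, treatment effects and isolate
    sequences so that every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cli,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
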