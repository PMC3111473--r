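Package: poda
Title: Pathways of Distinction Analysis for Multi-SNP GWAS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pathway-based multi-SNP analysis of case/control genotype data.
    For every sample and every pathway-defined SNP set, computes a
    leave-one-out relative distance statistic comparing the sample to the
    case and control genotype centroids, summarises the case/control
    difference with a Wilcoxon rank-sum statistic, normalises it against a
    permuted-label null ensemble to obtain a distinction score, and assesses
    significance by resampling length-matched random SNP sets. Includes
    per-gene representative-SNP selection by Fisher's exact test, logistic
    effect-size modelling with false-discovery-rate adjustment, redundancy
    culling of overlapping pathways, a pairwise-distance variant sensitive
    to centroid-invisible (XOR-type) epistasis, and simulators for epistatic,
    null and XOR case/control genotype data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
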