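Package: refstab
Title: Reference-Gene Stability Analysis for Stratified Circadian qPCR Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Efficiency-corrected relative quantification of RT-qPCR data and
    reference-gene stability analysis for circadian experiments stratified by
    mouse strain and tissue. Implements the geNorm pairwise-variation algorithm
    (M values, iterative exclusion ranking, geometric-mean normalization
    factors, V(n/n+1) pairwise variation) and the NormFinder model-based
    intra-/intergroup variance decomposition with subgrouping by circadian
    time, together with standard-curve efficiency estimation, normalization
    strategy comparison for rhythmic target genes, and a synthetic-data
    generator that emulates a three-strain, two-tissue, seven-time-point
    study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
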