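Package: sweepkit
Title: Selective-Sweep Scanning and Breed-Discriminant Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting signatures of artificial selection and
    breed-discriminant variants from multi-sample genotype data. Implements
    creeping-window pooled-heterozygosity (ZHp) genome scans with
    suggestive/strong selection classification and sweep-region merging,
    random-forest ranking of group-discriminant SNPs with a permutation-tested
    Davies-Bouldin cluster-separation statistic, candidate-marker and
    nearest-gene selection rules, structural-variant deletion filtering for
    trait carriers, depth-window log2 copy-number analysis, and two-locus
    genotype-phenotype concordance tables. Ships a synthetic diploid genotype
    simulator (Balding-Nichols group divergence, planted sweeps, discriminant
    markers, deletions and duplications) so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    randomForest,
    vcfR,
    ape,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
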