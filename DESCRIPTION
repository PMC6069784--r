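Package: magicpop
Title: Simulation and Genetic Analysis of Multi-Parent (MAGIC) Crop Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate multi-parent advanced generation intercross
    (MAGIC) populations under an eight-founder funnel crossing design with
    single-seed descent, and to analyse them: SNP quality control and
    identity-by-state dosage coding, allele-frequency-group specific
    segregation-distortion tests and distortion-region calling, genetic
    similarity, principal components and linkage-disequilibrium decay,
    cross-validated stepwise multiple-regression association scans with
    detection-rate thresholding and QTL grouping, and a di-genic epistasis
    scan with additive-by-additive effect estimation. The simulator follows
    an eight-founder winter-wheat funnel design (founders crossed in fixed
    pairs, two four-way crosses, reciprocal eight-way crosses, selfing to F4)
    and produces founder haplotype mosaics, genotype matrices and multi-year
    phenotypes with additive, epistatic and year-interaction components.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
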