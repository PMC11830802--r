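Package: vntrproxy
Title: Tandem-Repeat Genotyping, Tag-Haplotype Proxying and Association
    Models for an Intronic VNTR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven toolkit for linking a polymorphic intronic
    variable number tandem repeat (VNTR) to flanking SNPs. Implements repeat
    copy-number counting and de novo unit inference on long-read-like
    sequences, Short/Long allele binarization with Mendelian trio checks,
    read-depth window features with a regularized logistic carrier
    classifier, tag-SNP haplotype proxy selection (chi-square screen,
    kappa-maximizing pair search, LD r2), biallelic pseudo-marker imputation
    scored by concordance and the chance-corrected imputation quality score
    (IQS), splice-junction read classification into canonical and
    intron-retention events, G-quadruplex run-score scanning, and
    haplotype-coded linear and logistic association models with conditional,
    interaction and permutation analyses. A seeded synthetic-data layer
    generates phased SNP+VNTR haplotype panels with controlled linkage
    disequilibrium, repeat-array sequences, coverage profiles, junction read
    sets and phenotype cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
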