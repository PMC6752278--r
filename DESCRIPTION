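Package: starcallr
Title: Star-Allele Calling and Pharmacogenetic Phenotyping from Phased
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Translates phased, imputed genotype data into pharmacogenetic
    star-allele diplotypes and metabolizer phenotypes. Parses and curates
    PharmGKB-style allele definition tables, reads phased multi-sample VCFs
    with an imputation-probability filter and genotyped-over-imputed source
    merging, matches star alleles to haplotypes through a nonfunctional-first
    priority ladder, integrates CYP2D6-style whole-gene deletions and
    duplications, maps diplotypes to metabolizer phenotypes, and aggregates
    cohort-level allele, diplotype and phenotype frequencies together with
    clinical-impact statistics (one-proportion z-tests with log-space tail
    probabilities, carrier percentages, and drug-consumption-weighted impact
    in defined daily doses). A seed-deterministic synthetic-cohort generator
    emulates every input with ground truth so the full pipeline is testable
    without restricted data.
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
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
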