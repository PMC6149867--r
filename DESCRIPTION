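Package: dioseq
Title: Sex-Biased Expression and Sex-Associated SNP Discovery in Dioecious Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for comparative transcriptomics of dioecious
    (separate-sex) species without a reference genome. From a replicated
    gene-by-sample read-count matrix it calls sex-biased genes with a
    negative-binomial test and Benjamini-Hochberg false discovery rate
    control, flags sex-specific genes (zero counts in one sex, expressed
    in the other), and checks that samples cluster by sex. From
    multi-sample variant calls it applies a three-criterion segregation
    filter to find SNP sites fixed within each sex but different between
    sexes, the signature of sex-linked loci. It also summarises SNP
    spectra (transitions/transversions, per-kilobase density, codon
    position, synonymy), assembly and read-quality statistics, and tests
    category enrichment of the sex-biased genes with a length-bias-aware
    Wallenius noncentral hypergeometric model. A seeded synthetic-data
    generator emulates the full study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    ape,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
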