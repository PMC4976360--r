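Package: sexscan
Title: Sex-Locus Discovery, Genetic Sexing and Association Scans from
    Population Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers sex-linked loci from diploid population genotype
    data under an explicit heterogamety model (XX-XY or ZZ-ZW), calls
    genetic sex per individual from a method-of-moments inbreeding
    coefficient over a panel of sex-linked loci, and localizes
    sex-associated genomic regions with an exact genotypic (2x3) Fisher
    test computed in log-space followed by standard-deviation-threshold
    region calling. Includes composable site filters (biallelic SNPs,
    mean depth, minor allele frequency, per-population missingness,
    caller annotations, indel proximity), a diploid cohort simulator
    with a planted sex haplotype and known truth, and a utility that
    cuts long reads into artificial fixed-length end pairs.
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
    methods,
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
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
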