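test_that("VCF genotype strings are encoded by zygosity, half-calls missing", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("LG1", "100", ".", "A", "T", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", "./1", sep = "\t"),
    paste("LG1", "200", ".", "A", "T", ".", ".", ".", "GT",
          "0|1", "1|0", "1/0", "./.", sep = "\t")
  ), vcf)
  meta <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                         sex = c("female", "female", "male", "male"),
                         population = "p")
  g <- read_vcf(vcf, meta)
  expect_equal(unname(g$calls[1, ]), c(0L, 1L, 2L, NA))
  # phased, swapped-order and unphased hets all collapse to HET
  expect_equal(unname(g$calls[2, ]), c(1L, 1L, 1L, NA))
})

test_that("multi-allelic records are read and flagged, not dropped", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("LG1", "100", ".", "A", "T,G", ".", ".", ".", "GT",
          "1/2", "2/2", sep = "\t")
  ), vcf)
  g <- read_vcf(vcf, tibble::tibble(sample_id = c("s1", "s2"),
                                    sex = c("female", "male"),
                                    population = "p"))
  expect_equal(nrow(g$loci), 1L)
  expect_false(g$loci$is_biallelic)
  expect_false(g$loci$is_snp)
  expect_equal(unname(g$calls[1, ]), c(1L, 2L))  # zygosity coding
})

test_that("VCF sample ids missing from metadata are a configuration error", {
  vcf <- tempfile(fileext = ".vcf")
  g0 <- toy_matrix(matrix(c(0L, 1L), nrow = 1))
  write_vcf(g0, vcf)
  expect_error(
    read_vcf(vcf, tibble::tibble(sample_id = "other", sex = "male",
                                 population = "p")),
    "absent from metadata"
  )
})

test_that("write/read VCF round-trips calls, positions and alleles", {
  set.seed(42)
  for (rep in 1:3) {
    g <- random_matrix(50, 20)
    path <- tempfile(fileext = ".vcf")
    write_vcf(g, path)
    g2 <- read_vcf(path, g$samples)
    expect_equal(unname(g2$calls), unname(g$calls))
    expect_equal(g2$loci$pos, g$loci$pos)
    expect_equal(g2$loci$ref, g$loci$ref)
    expect_equal(g2$loci$alt, g$loci$alt)
    expect_equal(g2$samples$sample_id, g$samples$sample_id)
  }
})

test_that("INFO annotations and DP are parsed into the loci table", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("LG1", "100", ".", "A", "T", ".", ".", "FS=61.5;QD=1.5;MQ=39",
          "GT:DP", "0/0:10", "0/1:20", sep = "\t"),
    paste("LG1", "200", ".", "A", "T", ".", ".", ".",
          "GT:DP", "0/0:4", "1/1:.", sep = "\t")
  ), vcf)
  g <- read_vcf(vcf, tibble::tibble(sample_id = c("s1", "s2"),
                                    sex = c("female", "male"),
                                    population = "p"))
  expect_equal(g$loci$fs, c(61.5, NA))
  expect_equal(g$loci$qd, c(1.5, NA))
  expect_equal(g$loci$mq, c(39, NA))
  expect_equal(g$loci$mean_depth, c(15, 4))
})

test_that("per-sex genotype counts partition each sex at every locus", {
  g <- cod_discovery_matrix()
  cc <- count_genotypes(g)
  expect_equal(cc$f_hom_ref + cc$f_het + cc$f_hom_alt + cc$f_missing,
               rep(27L, 13))
  expect_equal(cc$m_hom_ref + cc$m_het + cc$m_hom_alt + cc$m_missing,
               rep(21L, 13))
  # the fixture expansion reproduces its own counts exactly
  expect_equal(cc[names(cod_discovery_counts())[-13]],
               cod_discovery_counts()[-13],
               ignore_attr = TRUE)
  # spot checks against the published rows
  r <- cc[cc$pos == 11888434, ]
  expect_equal(c(r$f_hom_ref, r$f_het, r$f_hom_alt, r$f_missing), c(27, 0, 0, 0))
  expect_equal(c(r$m_hom_ref, r$m_het, r$m_hom_alt), c(0, 21, 0))
  r <- cc[cc$pos == 11893118, ]
  expect_equal(c(r$m_hom_ref, r$m_het, r$m_hom_alt), c(1, 18, 1))
})

test_that("unknown-sex samples are rejected unless explicitly excluded", {
  g <- toy_matrix(matrix(c(0L, 1L, 2L), nrow = 1),
                  sexes = c("female", "male", "unknown"))
  expect_error(count_genotypes(g), "unknown sex")
  cc <- count_genotypes(g, exclude_unknown = TRUE)
  expect_equal(cc$f_hom_ref + cc$f_het + cc$f_hom_alt + cc$f_missing, 1L)
})

test_that("an all-missing locus counts as fully missing in both sexes", {
  g <- toy_matrix(matrix(NA_integer_, nrow = 1, ncol = 4))
  cc <- count_genotypes(g)
  expect_equal(c(cc$f_missing, cc$m_missing), c(2L, 2L))
  expect_equal(cc$f_hom_ref + cc$f_het + cc$f_hom_alt, 0L)
})

test_that("alt allele frequency follows allele counting and folds to MAF", {
  expect_equal(alt_allele_freq(2, 0, 0), 0)
  expect_equal(alt_allele_freq(0, 0, 2), 1)
  expect_equal(alt_allele_freq(1, 2, 1), 0.5)
  expect_error(alt_allele_freq(0, 0, 0), "undefined")
  # relabelling ref<->alt maps f -> 1 - f; MAF is invariant
  set.seed(1)
  for (i in 1:20) {
    n <- sample(1:30, 3, replace = TRUE)
    f <- alt_allele_freq(n[1], n[2], n[3])
    f_swap <- alt_allele_freq(n[3], n[2], n[1])
    expect_equal(f_swap, 1 - f)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_equal(maf(n[1], n[2], n[3]), maf(n[3], n[2], n[1]))
  }
})

test_that("geno_matrix validates its invariants", {
  expect_error(toy_matrix(matrix(3L, 1, 2)), "0, 1, 2 or NA")
  expect_error(toy_matrix(matrix(0L, 1, 2), pos = 0L), "1-based")
  expect_error(toy_matrix(matrix(0L, 1, 2), ref = "X"), "alleles")
  expect_error(
    geno_matrix(matrix(0L, 1, 2),
                tibble::tibble(chrom = "c", pos = 1L, ref = "A", alt = "T"),
                tibble::tibble(sample_id = c("a", "a"),
                               sex = c("male", "male"), population = "p")),
    "unique"
  )
})
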