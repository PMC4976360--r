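#' Published sex-linked genotype counts for the Atlantic cod discovery cohort
#'
#' Genotype counts at the thirteen sex-linked polymorphisms identified in
#' 48 wild-caught Atlantic cod (27 females, 21 males) from Lofoten,
#' Norway. All thirteen sites fall within a ~15 kb window on linkage
#' group 11 and show the homozygous-female / heterozygous-male pattern
#' expected under XX-XY sex determination. Rows whose per-sex counts sum
#' below the cohort size reflect missing genotypes in the original
#' calls.
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, the
#'   per-sex genotype counts (`f_hom_ref`, `f_het`, `f_hom_alt`,
#'   `f_missing`, `m_hom_ref`, `m_het`, `m_hom_alt`, `m_missing`) and
#'   `in_filtered` (whether the locus also survived quality filtering).
#' @seealso [cod_discovery_matrix()] to expand the counts into a
#'   48-sample [geno_matrix()]; [cod_sex_regions()] for the genome-scan
#'   region summary at full cohort size.
#' @export
cod_discovery_counts <- function() {
  tb <- tibble::tribble(
    ~pos,      ~ref,    ~alt,  ~f_hom_ref, ~f_het, ~f_hom_alt, ~m_hom_ref, ~m_het, ~m_hom_alt, ~in_filtered,
    11885753L, "G",     "T",   0L, 2L, 24L,  1L, 20L, 0L, TRUE,
    11886873L, "T",     "A",   0L, 0L, 27L,  1L, 20L, 0L, TRUE,
    11888434L, "T",     "C",  27L, 0L,  0L,  0L, 21L, 0L, FALSE,
    11893118L, "T",     "A",  27L, 0L,  0L,  1L, 18L, 1L, TRUE,
    11897471L, "G",     "GTGT", 0L, 0L, 27L, 0L, 21L, 0L, FALSE,
    11897513L, "C",     "T",   0L, 0L, 27L,  0L, 20L, 1L, FALSE,
    11897519L, "A",     "T",   0L, 0L, 27L,  0L, 21L, 0L, FALSE,
    11897566L, "AATCC", "A",   0L, 1L, 25L,  1L, 19L, 0L, FALSE,
    11899188L, "A",     "G",   0L, 0L, 27L,  0L, 20L, 1L, FALSE,
    11899196L, "G",     "T",   0L, 0L, 27L,  0L, 21L, 0L, FALSE,
    11899391L, "C",     "CT",  0L, 0L, 27L,  0L, 21L, 0L, FALSE,
    11899539L, "G",     "T",   0L, 2L, 25L,  0L, 20L, 0L, FALSE,
    11899548L, "TA",    "T",   0L, 2L, 25L,  0L, 20L, 0L, FALSE
  )
  dplyr::mutate(
    tb,
    chrom = "LG11",
    f_missing = 27L - .data$f_hom_ref - .data$f_het - .data$f_hom_alt,
    m_missing = 21L - .data$m_hom_ref - .data$m_het - .data$m_hom_alt,
    .before = 1
  ) %>%
    dplyr::relocate("chrom", "pos", "ref", "alt",
                    "f_hom_ref", "f_het", "f_hom_alt", "f_missing",
                    "m_hom_ref", "m_het", "m_hom_alt", "m_missing")
}

#' Expand per-sex genotype counts into an explicit genotype matrix
#'
#' Builds a [geno_matrix()] realising a table of per-sex genotype counts
#' as individual diploid samples: within each sex, samples are assigned
#' hom-ref, then het, then hom-alt, then missing genotypes in sample
#' order. Defaults to the thirteen-locus discovery table of
#' [cod_discovery_counts()], yielding the 48-fish cohort (27 females
#' `F01..F27`, then 21 males `M01..M21`).
#'
#' @param counts A tibble of per-sex genotype counts in the shape
#'   returned by [cod_discovery_counts()].
#' @param n_females,n_males Cohort composition; per-row counts must sum
#'   to these (missing counts are inferred when the explicit
#'   `f_missing`/`m_missing` columns are absent).
#' @param population Population label for all samples.
#' @return A [geno_matrix()] whose [count_genotypes()] reproduces
#'   `counts` exactly.
#' @export
cod_discovery_matrix <- function(counts = cod_discovery_counts(),
                                 n_females = 27L, n_males = 21L,
                                 population = "Lofoten") {
  counts <- tibble::as_tibble(counts)
  if (is.null(counts$f_missing)) {
    counts$f_missing <- n_females - counts$f_hom_ref - counts$f_het - counts$f_hom_alt
  }
  if (is.null(counts$m_missing)) {
    counts$m_missing <- n_males - counts$m_hom_ref - counts$m_het - counts$m_hom_alt
  }
  stopifnot(
    all(counts$f_hom_ref + counts$f_het + counts$f_hom_alt + counts$f_missing == n_females),
    all(counts$m_hom_ref + counts$m_het + counts$m_hom_alt + counts$m_missing == n_males),
    all(counts$f_missing >= 0), all(counts$m_missing >= 0)
  )
  expand_row <- function(hr, het, ha, mis) {
    c(rep(0L, hr), rep(1L, het), rep(2L, ha), rep(NA_integer_, mis))
  }
  calls <- t(mapply(
    function(fhr, fhe, fha, fmi, mhr, mhe, mha, mmi) {
      c(expand_row(fhr, fhe, fha, fmi), expand_row(mhr, mhe, mha, mmi))
    },
    counts$f_hom_ref, counts$f_het, counts$f_hom_alt, counts$f_missing,
    counts$m_hom_ref, counts$m_het, counts$m_hom_alt, counts$m_missing
  ))
  samples <- tibble::tibble(
    sample_id = c(sprintf("F%02d", seq_len(n_females)),
                  sprintf("M%02d", seq_len(n_males))),
    sex = rep(c("female", "male"), c(n_females, n_males)),
    population = population
  )
  geno_matrix(calls, counts[, c("chrom", "pos", "ref", "alt")], samples)
}

#' Published sex-associated region summary for Atlantic cod
#'
#' The six genomic regions containing sex-linked loci found by the exact
#' genotypic association scan of 226 Atlantic cod (116 females, 110
#' males) across >55 million variable sites. `start`/`stop` are the
#' first and last locus whose transformed p-value exceeded six standard
#' deviations above the genome-wide mean; `n_sex_linked` counts those
#' loci, `n_total` all loci with MAF >= 0.05 in the interval, and
#' `max_neglog10_p` the region's largest -log10 p (rounded as printed).
#'
#' @return A tibble with one row per region.
#' @export
cod_sex_regions <- function() {
  tibble::tribble(
    ~lg,   ~start,    ~stop,     ~n_sex_linked, ~n_total, ~max_neglog10_p,
    "08a", 1784400L,  1784813L,  11L, 23L, 47,
    "08b", 24118524L, 24118864L,  8L, 14L, 19,
    "11",  11864114L, 11918378L, 127L, 472L, 67,
    "14",  27062221L, 27062388L,  3L,  8L, 22,
    "15",  3678047L,  3679605L,  14L, 64L, 41,
    "17",  18769676L, 18769822L,  3L,  6L, 26
  )
}
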