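#' Sex-linked segregation criterion
#'
#' Parametrises the discovery rule for sex-linked loci under a chosen
#' heterogamety model. Under XX-XY (`heterogametic = "male"`) a
#' sex-linked locus should be homozygous in females and heterozygous in
#' males; under ZZ-ZW (`heterogametic = "female"`) the roles swap. The
#' defaults tolerate two discordant genotypes per sex — heterozygotes
#' are prone to being lost from low-coverage data, so a small allowance
#' avoids discarding genuinely linked loci — and 10% missing genotypes.
#'
#' @param heterogametic Which sex carries the two different sex
#'   chromosomes: `"male"` (XX-XY) or `"female"` (ZZ-ZW).
#' @param max_het_homogametic Maximum heterozygous genotypes tolerated
#'   in the homogametic sex.
#' @param max_hom_heterogametic Maximum homozygous genotypes (hom-ref
#'   plus hom-alt) tolerated in the heterogametic sex.
#' @param max_missing Maximum missing-genotype fraction, computed over
#'   all samples jointly (set `per_sex = TRUE` to require it within each
#'   sex instead).
#' @param per_sex Apply the missingness cap within each sex separately.
#' @return An object of class `seg_criterion`.
#' @export
segregation_criterion <- function(heterogametic = c("male", "female"),
                                  max_het_homogametic = 2L,
                                  max_hom_heterogametic = 2L,
                                  max_missing = 0.10,
                                  per_sex = FALSE) {
  heterogametic <- match.arg(heterogametic)
  stopifnot(max_het_homogametic >= 0, max_hom_heterogametic >= 0,
            max_missing >= 0, max_missing <= 1)
  structure(
    list(heterogametic = heterogametic,
         max_het_homogametic = as.integer(max_het_homogametic),
         max_hom_heterogametic = as.integer(max_hom_heterogametic),
         max_missing = max_missing,
         per_sex = per_sex),
    class = "seg_criterion"
  )
}

#' @export
print.seg_criterion <- function(x, ...) {
  sys <- if (x$heterogametic == "male") "XX-XY" else "ZZ-ZW"
  cat("<seg_criterion> ", sys, " (heterogametic ", x$heterogametic, ")\n",
      "  max het in homogametic sex:  ", x$max_het_homogametic, "\n",
      "  max hom in heterogametic sex: ", x$max_hom_heterogametic, "\n",
      "  max missing fraction: ", x$max_missing,
      if (x$per_sex) " (per sex)" else " (all samples)", "\n", sep = "")
  invisible(x)
}

#' Find loci whose genotypes segregate with sex
#'
#' Applies a [segregation_criterion()] to every locus: a locus passes if
#' the homogametic sex shows at most `max_het_homogametic` heterozygous
#' genotypes, the heterogametic sex shows at most
#' `max_hom_heterogametic` homozygous genotypes, and the missing
#' fraction is within `max_missing`. Both SNPs and indel polymorphisms
#' are eligible, so this runs on the unfiltered matrix by design.
#'
#' @param g A [geno_matrix()] containing at least one sample of each
#'   sex.
#' @param criterion A [segregation_criterion()].
#' @return A tibble of passing loci with their per-sex genotype counts,
#'   sorted by `(chrom, pos)`.
#' @examples
#' find_sex_linked(cod_discovery_matrix())          # all 13 loci pass
#' nrow(find_sex_linked(cod_discovery_matrix(),
#'   segregation_criterion("female")))              # reverse rule: 0
#' @export
find_sex_linked <- function(g, criterion = segregation_criterion()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(criterion, "seg_criterion"))
  cc <- count_genotypes(g, exclude_unknown = TRUE)
  sexes <- g$samples$sex
  n_f <- sum(sexes == "female")
  n_m <- sum(sexes == "male")
  if (n_f == 0 || n_m == 0) {
    stop("both sexes must be represented in the cohort", call. = FALSE)
  }

  if (criterion$heterogametic == "male") {
    het_homog <- cc$f_het
    hom_heterog <- cc$m_hom_ref + cc$m_hom_alt
  } else {
    het_homog <- cc$m_het
    hom_heterog <- cc$f_hom_ref + cc$f_hom_alt
  }
  if (criterion$per_sex) {
    miss_ok <- cc$f_missing / n_f <= criterion$max_missing &
      cc$m_missing / n_m <= criterion$max_missing
  } else {
    miss_ok <- (cc$f_missing + cc$m_missing) / (n_f + n_m) <= criterion$max_missing
  }
  pass <- het_homog <= criterion$max_het_homogametic &
    hom_heterog <= criterion$max_hom_heterogametic &
    miss_ok
  dplyr::arrange(cc[pass, , drop = FALSE], .data$chrom, .data$pos)
}

#' Compare both heterogamety orientations on one cohort
#'
#' Runs [find_sex_linked()] under the XX-XY and the ZZ-ZW orientation
#' with identical thresholds. A genuine sex-determination system shows
#' passing loci under its own orientation and none under the reverse.
#'
#' @inheritParams find_sex_linked
#' @return A list with `summary` (tibble: orientation, n_pass) and
#'   `loci` (named list of the two passing-locus tibbles, `"XY"` and
#'   `"ZW"`).
#' @export
orientation_sweep <- function(g, criterion = segregation_criterion()) {
  crit_xy <- criterion
  crit_xy$heterogametic <- "male"
  crit_zw <- criterion
  crit_zw$heterogametic <- "female"
  loci <- list(XY = find_sex_linked(g, crit_xy),
               ZW = find_sex_linked(g, crit_zw))
  list(
    summary = tibble::tibble(
      orientation = c("XY", "ZW"),
      heterogametic = c("male", "female"),
      n_pass = c(nrow(loci$XY), nrow(loci$ZW))
    ),
    loci = loci
  )
}
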