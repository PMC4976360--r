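#' Per-individual inbreeding coefficient over a locus panel
#'
#' Computes the method-of-moments inbreeding coefficient F for each
#' sample over a panel of loci, and calls genetic sex by its sign. At
#' each panel site the expected probability of homozygosity is
#' `1 - 2 p (1 - p) * 2n / (2n - 1)`, where `p` is the alternative-allele
#' frequency over all called individuals at the site and `n` the number
#' of called diploid individuals there (the `2n/(2n-1)` factor is the
#' small-sample correction on expected heterozygosity; disable it with
#' `small_sample_correction = FALSE` for sensitivity checks). For a
#' sample called at `L` panel sites with `O` observed homozygous
#' genotypes and `E` the summed expectation over those sites,
#' `F = (O - E) / (L - E)`.
#'
#' At sex-linked loci the heterogametic sex is systematically
#' heterozygous, driving F strongly negative, while the homogametic sex
#' is homozygous, driving F positive: under XX-XY, positive F is called
#' female and negative F male. `F = 0` exactly, no called sites, or a
#' vanishing denominator yield the call `"unknown"`.
#'
#' Monomorphic panel sites (frequency 0 or 1 in the cohort) carry no
#' information and would contribute a zero expected-heterozygosity term;
#' they are excluded from the panel with a warning.
#'
#' @param g A [geno_matrix()].
#' @param panel Data frame identifying the panel loci by `chrom` and
#'   `pos` (e.g. the output of [find_sex_linked()]).
#' @param small_sample_correction Apply the `2n/(2n-1)` factor (default
#'   `TRUE`).
#' @return A tibble, one row per sample: `sample_id`, `o_hom`, `e_hom`,
#'   `l_sites`, `f`, `call`.
#' @export
inbreeding_f <- function(g, panel, small_sample_correction = TRUE) {
  stopifnot(inherits(g, "geno_matrix"))
  panel <- tibble::as_tibble(panel)
  stopifnot(all(c("chrom", "pos") %in% names(panel)))
  key <- paste(g$loci$chrom, g$loci$pos)
  idx <- match(paste(panel$chrom, panel$pos), key)
  if (anyNA(idx)) {
    stop("panel loci absent from the genotype matrix: ",
         paste(head(paste(panel$chrom, panel$pos)[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }

  m <- g$calls[idx, , drop = FALSE]
  called <- !is.na(m)
  n_called <- rowSums(called)
  if (any(n_called < 2)) {
    stop("allele frequency not estimable: fewer than 2 called individuals ",
         "at some panel loci", call. = FALSE)
  }
  p_hat <- rowSums(m, na.rm = TRUE) / (2 * n_called)

  poly <- p_hat > 0 & p_hat < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic panel locus/loci excluded from F",
            call. = FALSE)
    m <- m[poly, , drop = FALSE]
    called <- called[poly, , drop = FALSE]
    n_called <- n_called[poly]
    p_hat <- p_hat[poly]
  }

  corr <- if (small_sample_correction) 2 * n_called / (2 * n_called - 1) else 1
  e_site <- 1 - 2 * p_hat * (1 - p_hat) * corr

  o_hom <- unname(colSums(m == 0L | m == 2L, na.rm = TRUE))
  e_hom <- unname(colSums(called * e_site))
  l_sites <- unname(colSums(called))
  denom <- l_sites - e_hom
  f <- ifelse(l_sites == 0 | denom == 0, NA_real_, (o_hom - e_hom) / denom)

  tibble::tibble(
    sample_id = g$samples$sample_id,
    o_hom = o_hom,
    e_hom = e_hom,
    l_sites = l_sites,
    f = f,
    call = dplyr::case_when(
      is.na(f) ~ "unknown",
      f > 0 ~ "female",
      f < 0 ~ "male",
      .default = "unknown"
    )
  )
}

#' Classify the genetic sex of a whole cohort
#'
#' Runs [inbreeding_f()] on every sample and compares the genetic calls
#' with the recorded phenotypic sex. Returns a `sex_classification`
#' object with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @inheritParams inbreeding_f
#' @return A `sex_classification` object: `calls` (per-sample tibble
#'   with phenotype and concordance), `confusion` (genetic x phenotypic
#'   contingency tibble over phenotyped samples), `mismatches` (the
#'   discordant samples).
#' @export
classify_cohort <- function(g, panel, small_sample_correction = TRUE) {
  calls <- inbreeding_f(g, panel, small_sample_correction)
  calls$phenotypic_sex <- g$samples$sex
  calls$concordant <- ifelse(
    calls$phenotypic_sex == "unknown" | calls$call == "unknown",
    NA, calls$call == calls$phenotypic_sex
  )
  known <- calls[calls$phenotypic_sex != "unknown", ]
  confusion <- known %>%
    dplyr::count(.data$call, .data$phenotypic_sex, name = "n") %>%
    tidyr::complete(
      call = c("female", "male", "unknown"),
      phenotypic_sex = c("female", "male"),
      fill = list(n = 0L)
    )
  structure(
    list(calls = calls,
         confusion = confusion,
         mismatches = calls[!is.na(calls$concordant) & !calls$concordant, ]),
    class = "sex_classification"
  )
}

#' @export
print.sex_classification <- function(x, ...) {
  n <- nrow(x$calls)
  n_known <- sum(!is.na(x$calls$concordant))
  n_ok <- sum(x$calls$concordant, na.rm = TRUE)
  cat("<sex_classification> ", n, " samples; ", n_ok, "/", n_known,
      " concordant with phenotypic sex\n", sep = "")
  if (nrow(x$mismatches) > 0) {
    cat("  discordant: ", paste(x$mismatches$sample_id, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname classify_cohort
#' @param x A `sex_classification` object.
#' @param ... Unused.
#' @method tidy sex_classification
#' @export
tidy.sex_classification <- function(x, ...) x$calls

#' @rdname classify_cohort
#' @method glance sex_classification
#' @export
glance.sex_classification <- function(x, ...) {
  conc <- x$calls$concordant
  tibble::tibble(
    n_samples = nrow(x$calls),
    n_classified = sum(x$calls$call != "unknown"),
    n_compared = sum(!is.na(conc)),
    n_concordant = sum(conc, na.rm = TRUE),
    n_discordant = sum(!conc, na.rm = TRUE),
    concordance = ifelse(sum(!is.na(conc)) == 0, NA_real_,
                         mean(conc, na.rm = TRUE))
  )
}

#' @rdname classify_cohort
#' @param object A `sex_classification` object.
#' @method autoplot sex_classification
#' @export
autoplot.sex_classification <- function(object, ...) {
  d <- object$calls
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phenotypic_sex, y = .data$f)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$call), width = 0.15,
                         height = 0, alpha = 0.8) +
    ggplot2::labs(x = "phenotypic sex", y = "inbreeding coefficient F",
                  colour = "genetic call") +
    ggplot2::theme_minimal()
}
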