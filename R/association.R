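# log point probability grid and tail sum for one 2x3 table; lg is a
# precomputed lgamma table with lg[k+1] = log(k!), length >= N+1.
log_p_2x3_one <- function(f0, f1, f2, m0, m1, m2, lg, tie_tol = 1e-7) {
  c0 <- f0 + m0; c1 <- f1 + m1; c2 <- f2 + m2
  nf <- f0 + f1 + f2
  N <- c0 + c1 + c2
  lch <- function(n, k) lg[n + 1L] - lg[k + 1L] - lg[n - k + 1L]

  amax <- min(c0, nf)
  a <- rep.int(0:amax, rep.int(c1 + 1L, amax + 1L))
  b <- rep.int(0:c1, amax + 1L)
  cc <- nf - a - b
  keep <- cc >= 0L & cc <= c2
  a <- a[keep]; b <- b[keep]; cc <- cc[keep]

  base <- lch(N, nf)
  lp <- lch(c0, a) + lch(c1, b) + lch(c2, cc) - base
  lobs <- lch(c0, f0) + lch(c1, f1) + lch(c2, f2) - base
  sel <- lp <= lobs + log1p(tie_tol)
  x <- lp[sel]
  mx <- max(x)
  min(mx + log(sum(exp(x - mx))), 0)
}

#' Exact genotypic (2x3) test of sex association
#'
#' Fisher-type exact test on the genotype-by-sex contingency table
#' (hom-ref / het / hom-alt by female / male), conditional on both
#' margins. The p-value sums the multivariate-hypergeometric point
#' probabilities of every table with the observed margins whose point
#' probability does not exceed the observed one (within a relative tie
#' tolerance of `tie_tol`, mirroring common exact-test
#' implementations). All accumulation is in log-space via a stable
#' log-sum-exp, so p-values far below the double-precision underflow
#' limit (e.g. 1e-300) remain exact in log form.
#'
#' @param f_hom_ref,f_het,f_hom_alt,m_hom_ref,m_het,m_hom_alt Per-sex
#'   genotype counts; vectorised over loci. Missing individuals are
#'   simply absent from the counts.
#' @param tie_tol Relative tolerance of the "as or more extreme" rule.
#' @return A tibble with `log_p` (natural-log p-value, <= 0) and
#'   `neglog10_p` (`-log_p / ln 10`, >= 0), one row per input table.
#'   Both sexes must have at least one called individual in every
#'   table.
#' @examples
#' fisher_exact_2x3(27, 0, 0, 0, 21, 0)  # perfect segregation, 27F/21M
#' @export
fisher_exact_2x3 <- function(f_hom_ref, f_het, f_hom_alt,
                             m_hom_ref, m_het, m_hom_alt,
                             tie_tol = 1e-7) {
  nf <- f_hom_ref + f_het + f_hom_alt
  nm <- m_hom_ref + m_het + m_hom_alt
  if (any(nf < 1) || any(nm < 1)) {
    stop("both sexes need >= 1 called individual at every locus", call. = FALSE)
  }
  N <- nf + nm
  lg <- lgamma(seq_len(max(N) + 1L))
  log_p <- vapply(
    seq_along(nf),
    function(i) log_p_2x3_one(f_hom_ref[i], f_het[i], f_hom_alt[i],
                              m_hom_ref[i], m_het[i], m_hom_alt[i],
                              lg, tie_tol),
    numeric(1)
  )
  tibble::tibble(log_p = log_p, neglog10_p = -log_p / log(10))
}

#' Genome-wide exact association scan
#'
#' Tests every locus of a cohort for genotypic association with sex
#' using [fisher_exact_2x3()], preserving genome order. Loci at which
#' one sex has no called individuals are untestable; they are kept in
#' the output with `tested = FALSE` and `NA` p-values.
#'
#' @param g A [geno_matrix()]; samples of unknown sex are excluded.
#' @param tie_tol Passed to [fisher_exact_2x3()].
#' @return A `sex_scan` tibble: the locus columns, per-sex genotype
#'   counts, `maf` (minor allele frequency over called samples, `NA`
#'   when no sample is called), `tested`, `log_p` and `neglog10_p`.
#' @export
scan_sex_association <- function(g, tie_tol = 1e-7) {
  cc <- count_genotypes(g, exclude_unknown = TRUE)
  nf_called <- cc$f_hom_ref + cc$f_het + cc$f_hom_alt
  nm_called <- cc$m_hom_ref + cc$m_het + cc$m_hom_alt
  tested <- nf_called >= 1 & nm_called >= 1

  cc$maf <- NA_real_
  any_called <- nf_called + nm_called > 0
  cc$maf[any_called] <- maf(
    cc$f_hom_ref[any_called] + cc$m_hom_ref[any_called],
    cc$f_het[any_called] + cc$m_het[any_called],
    cc$f_hom_alt[any_called] + cc$m_hom_alt[any_called]
  )
  cc$tested <- tested
  cc$log_p <- NA_real_
  if (any(tested)) {
    res <- fisher_exact_2x3(
      cc$f_hom_ref[tested], cc$f_het[tested], cc$f_hom_alt[tested],
      cc$m_hom_ref[tested], cc$m_het[tested], cc$m_hom_alt[tested],
      tie_tol = tie_tol
    )
    cc$log_p[tested] <- res$log_p
  }
  cc$neglog10_p <- -cc$log_p / log(10)
  class(cc) <- c("sex_scan", class(cc))
  cc
}

#' Call sex-associated regions from a scan
#'
#' Thresholds the transformed statistic at
#' `mean(neglog10_p) + sd_multiplier * sd(neglog10_p)` (sample SD,
#' n - 1, over all tested loci genome-wide) and clusters the strictly
#' above-threshold loci: loci on the same chromosome join one region
#' unless consecutive above-threshold loci lie more than `merge_gap_bp`
#' apart. Each region is delimited by its first and last qualifying
#' locus.
#'
#' @param scan A `sex_scan` tibble from [scan_sex_association()] (needs
#'   at least two tested loci for the SD to be defined).
#' @param sd_multiplier Threshold distance from the mean, in SDs.
#' @param merge_gap_bp Maximum within-region gap between consecutive
#'   above-threshold loci (bp).
#' @param maf_min MAF cutoff applied only to each region's `n_total`
#'   locus count.
#' @return A tibble of regions: `lg`, `start`, `stop`, `size`
#'   (`stop - start`, bp), `n_sex_linked` (above-threshold loci),
#'   `n_total` (tested loci with `maf >= maf_min` inside
#'   `[start, stop]`), `max_neglog10_p`. Zero above-threshold loci give
#'   an empty tibble. The threshold used is attached as attribute
#'   `"threshold"`.
#' @export
call_regions <- function(scan, sd_multiplier = 6, merge_gap_bp = 1e6,
                         maf_min = 0.05) {
  tested <- scan[scan$tested & !is.na(scan$neglog10_p), , drop = FALSE]
  if (nrow(tested) < 2) {
    stop("need >= 2 tested loci for a SD-based threshold", call. = FALSE)
  }
  thr <- mean(tested$neglog10_p) + sd_multiplier * sd(tested$neglog10_p)

  hits <- tested[tested$neglog10_p > thr, , drop = FALSE]
  empty <- tibble::tibble(
    lg = character(), start = integer(), stop = integer(), size = integer(),
    n_sex_linked = integer(), n_total = integer(), max_neglog10_p = numeric()
  )
  if (nrow(hits) == 0) {
    attr(empty, "threshold") <- thr
    return(empty)
  }

  hits <- dplyr::arrange(hits, .data$chrom, .data$pos)
  new_region <- c(TRUE, hits$chrom[-1] != hits$chrom[-nrow(hits)] |
                    diff(hits$pos) > merge_gap_bp)
  hits$region <- cumsum(new_region)

  regions <- hits %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(
      lg = dplyr::first(.data$chrom),
      start = min(.data$pos),
      stop = max(.data$pos),
      n_sex_linked = dplyr::n(),
      max_neglog10_p = max(.data$neglog10_p),
      .groups = "drop"
    ) %>%
    dplyr::mutate(size = .data$stop - .data$start)

  regions$n_total <- purrr::pmap_int(
    regions[, c("lg", "start", "stop")],
    function(lg, start, stop) {
      sum(tested$chrom == lg & tested$pos >= start & tested$pos <= stop &
            !is.na(tested$maf) & tested$maf >= maf_min)
    }
  )
  out <- regions[, c("lg", "start", "stop", "size", "n_sex_linked",
                     "n_total", "max_neglog10_p")]
  attr(out, "threshold") <- thr
  out
}

#' Summarise called regions
#'
#' Formats a region table for reporting — `size` recomputed as
#' `stop - start`, the maximum statistic rounded to integer as
#' conventionally printed — and totals the sex-linked loci across
#' regions.
#'
#' @param regions A region tibble with at least `lg`, `start`, `stop`,
#'   `n_sex_linked`, `n_total`, `max_neglog10_p` (e.g. from
#'   [call_regions()] or [cod_sex_regions()]).
#' @return A list: `regions` (tibble with columns `lg`, `start`, `stop`,
#'   `size`, `n_sex_linked`, `n_total`, `max_p` rounded) and
#'   `total_sex_linked`.
#' @export
summarize_regions <- function(regions) {
  regions <- tibble::as_tibble(regions)
  out <- tibble::tibble(
    lg = regions$lg,
    start = regions$start,
    stop = regions$stop,
    size = regions$stop - regions$start,
    n_sex_linked = regions$n_sex_linked,
    n_total = regions$n_total,
    max_p = as.integer(round(regions$max_neglog10_p))
  )
  list(regions = out, total_sex_linked = sum(out$n_sex_linked))
}

#' Discovery rate of sex-linked loci
#'
#' Expresses a hit count against the number of variable sites screened
#' as a "1 in N loci" rate, rounded down.
#'
#' @param n_variants Total variable sites screened.
#' @param n_hits Sex-linked loci found.
#' @return `floor(n_variants / n_hits)`.
#' @examples
#' discovery_rate(55160622, 166)
#' @export
discovery_rate <- function(n_variants, n_hits) {
  stopifnot(n_hits >= 1)
  floor(n_variants / n_hits)
}

#' Manhattan-style plot of an association scan
#'
#' @param object A `sex_scan` tibble from [scan_sex_association()].
#' @param sd_multiplier Draw the region-calling threshold at this many
#'   SDs above the mean (set `NULL` to omit).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sex_scan
#' @export
autoplot.sex_scan <- function(object, sd_multiplier = 6, ...) {
  d <- object[object$tested, , drop = FALSE]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6,
                                       y = .data$neglog10_p)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10] * italic(p))) +
    ggplot2::theme_minimal()
  if (!is.null(sd_multiplier)) {
    thr <- mean(d$neglog10_p) + sd_multiplier * sd(d$neglog10_p)
    p <- p + ggplot2::geom_hline(yintercept = thr, colour = "firebrick",
                                 linetype = "dashed")
  }
  p
}
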