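#' Composable locus-level site filters
#'
#' Each `filter_*()` function takes a [geno_matrix()], removes the loci
#' that violate its rule, and appends a row to the matrix's filter
#' report (retrieved with [filter_report()]). All boundary readings are
#' strict where the rule says "more than"/"higher than"/"below": a locus
#' sitting exactly on a threshold is kept.
#'
#' * `filter_biallelic_snps()`: keep only biallelic SNPs (drops indels
#'   and multi-allelic records).
#' * `filter_mean_depth()`: drop loci whose mean read depth exceeds
#'   `max_mean` (default 30); loci without depth information are kept
#'   with a warning.
#' * `filter_maf()`: drop loci with minor allele frequency below
#'   `min_maf` (default 0.05), computed over all called samples;
#'   monomorphic loci have MAF 0 and are dropped.
#' * `filter_missing_per_population()`: drop a locus if in any single
#'   population its missing fraction exceeds `max_missing` (default
#'   0.10).
#' * `filter_annotations()`: drop loci whose variant-caller annotations
#'   violate the standard hard thresholds (FS > 60, MQRankSum < -12.5,
#'   ReadPosRankSum < -8, QD < 2, MQ < 40). A locus lacking an
#'   annotation is never removed for that annotation.
#' * `filter_near_indel()`: drop SNPs within `window` bp (default 10) of
#'   an indel's reference footprint `[pos, pos + nchar(ref) - 1]` on the
#'   same chromosome; the indels themselves are untouched.
#' * `filter_sites()`: the full battery in the order above, i.e. the
#'   standard "filtered dataset" preset.
#'
#' @param g A [geno_matrix()].
#' @param max_mean Maximum mean read depth (reads).
#' @param min_maf Minimum minor allele frequency.
#' @param max_missing Maximum tolerated missing fraction per population.
#' @param thresholds Named list of annotation thresholds; see
#'   [annotation_thresholds()].
#' @param window Exclusion distance around indels (bp).
#' @return The filtered `geno_matrix`, with the cumulative report in
#'   `filter_report(g)`.
#' @name site_filters
NULL

#' Hard-filter thresholds for variant-caller annotations
#'
#' @param fs_max,mq_rank_sum_min,read_pos_rank_sum_min,qd_min,mq_min
#'   Unitless INFO-annotation thresholds (FisherStrand, mapping-quality
#'   rank sum, read-position rank sum, quality-by-depth, RMS mapping
#'   quality).
#' @return A named list of the five thresholds.
#' @export
annotation_thresholds <- function(fs_max = 60.0, mq_rank_sum_min = -12.5,
                                  read_pos_rank_sum_min = -8.0,
                                  qd_min = 2.0, mq_min = 40.0) {
  th <- list(fs_max = fs_max, mq_rank_sum_min = mq_rank_sum_min,
             read_pos_rank_sum_min = read_pos_rank_sum_min,
             qd_min = qd_min, mq_min = mq_min)
  stopifnot(all(vapply(th, is.finite, logical(1))))
  th
}

#' Retrieve the cumulative filter report of a genotype matrix
#'
#' @param g A [geno_matrix()] that has passed through one or more
#'   filters.
#' @return A tibble with columns `filter`, `n_in`, `n_removed`, `n_out`,
#'   one row per applied filter, in application order.
#' @export
filter_report <- function(g) {
  rep <- attr(g, "filter_report")
  if (is.null(rep)) {
    tibble::tibble(filter = character(), n_in = integer(),
                   n_removed = integer(), n_out = integer())
  } else {
    rep
  }
}

apply_locus_filter <- function(g, keep, name) {
  rep <- filter_report(g)
  out <- g[keep, ]
  attr(out, "filter_report") <- dplyr::bind_rows(rep, tibble::tibble(
    filter = name,
    n_in = nrow(g$loci),
    n_removed = sum(!keep),
    n_out = sum(keep)
  ))
  out
}

#' @rdname site_filters
#' @export
filter_biallelic_snps <- function(g) {
  apply_locus_filter(g, g$loci$is_snp & g$loci$is_biallelic, "biallelic_snps")
}

#' @rdname site_filters
#' @export
filter_mean_depth <- function(g, max_mean = 30) {
  depth <- g$loci$mean_depth
  if (all(is.na(depth))) {
    warning("no mean depth information; depth filter is a no-op", call. = FALSE)
  }
  keep <- is.na(depth) | depth <= max_mean
  apply_locus_filter(g, keep, "mean_depth")
}

#' @rdname site_filters
#' @export
filter_maf <- function(g, min_maf = 0.05) {
  cc <- count_genotypes(g, exclude_unknown = TRUE)
  n0 <- cc$f_hom_ref + cc$m_hom_ref
  n1 <- cc$f_het + cc$m_het
  n2 <- cc$f_hom_alt + cc$m_hom_alt
  called <- n0 + n1 + n2
  mafs <- rep(0, nrow(g$loci))
  mafs[called > 0] <- maf(n0[called > 0], n1[called > 0], n2[called > 0])
  apply_locus_filter(g, mafs >= min_maf, "maf")
}

#' @rdname site_filters
#' @export
filter_missing_per_population <- function(g, max_missing = 0.10) {
  pops <- unique(g$samples$population)
  worst <- rep(0, nrow(g$loci))
  for (p in pops) {
    m <- g$calls[, g$samples$population == p, drop = FALSE]
    worst <- pmax(worst, rowMeans(is.na(m)))
  }
  apply_locus_filter(g, worst <= max_missing, "missing_per_population")
}

#' @rdname site_filters
#' @export
filter_annotations <- function(g, thresholds = annotation_thresholds()) {
  l <- g$loci
  ann <- function(col) if (is.null(l[[col]])) rep(NA_real_, nrow(l)) else l[[col]]
  fs <- ann("fs"); mqrs <- ann("mq_rank_sum"); rprs <- ann("read_pos_rank_sum")
  qd <- ann("qd"); mq <- ann("mq")
  if (all(is.na(fs)) && all(is.na(mqrs)) && all(is.na(rprs)) &&
      all(is.na(qd)) && all(is.na(mq))) {
    warning("no caller annotations present; annotation filter is a no-op",
            call. = FALSE)
  }
  viol <- function(x, bad) !is.na(x) & bad(x)
  remove <- viol(fs, function(x) x > thresholds$fs_max) |
    viol(mqrs, function(x) x < thresholds$mq_rank_sum_min) |
    viol(rprs, function(x) x < thresholds$read_pos_rank_sum_min) |
    viol(qd, function(x) x < thresholds$qd_min) |
    viol(mq, function(x) x < thresholds$mq_min)
  apply_locus_filter(g, !remove, "annotations")
}

#' @rdname site_filters
#' @export
filter_near_indel <- function(g, window = 10) {
  l <- g$loci
  is_indel <- !l$is_snp
  keep <- rep(TRUE, nrow(l))
  snp_idx <- which(l$is_snp)
  for (chr in unique(l$chrom[is_indel])) {
    ind <- which(is_indel & l$chrom == chr)
    if (length(ind) == 0) next
    starts <- l$pos[ind]
    ends <- l$pos[ind] + nchar(l$ref[ind]) - 1L
    snps <- snp_idx[l$chrom[snp_idx] == chr]
    if (length(snps) == 0) next
    p <- l$pos[snps]
    # distance from a point to an interval, 0 inside
    for (k in seq_along(ind)) {
      d <- pmax(starts[k] - p, p - ends[k], 0L)
      keep[snps[d <= window]] <- FALSE
    }
  }
  apply_locus_filter(g, keep, "near_indel")
}

#' @rdname site_filters
#' @export
filter_sites <- function(g, thresholds = annotation_thresholds(),
                         window = 10, max_mean = 30, min_maf = 0.05,
                         max_missing = 0.10) {
  g %>%
    filter_annotations(thresholds) %>%
    filter_near_indel(window) %>%
    filter_biallelic_snps() %>%
    filter_mean_depth(max_mean) %>%
    filter_maf(min_maf) %>%
    filter_missing_per_population(max_missing)
}
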