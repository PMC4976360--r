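#' Genotype matrix container
#'
#' Bundles a loci table, a sample table and a loci-by-samples matrix of
#' coded genotype calls. Calls are integers: `0` = homozygous reference,
#' `1` = heterozygous (any phased or unphased het configuration), `2` =
#' homozygous alternative, `NA` = missing (includes half-calls).
#'
#' @param calls Integer matrix, one row per locus, one column per sample,
#'   values in `{0, 1, 2, NA}`.
#' @param loci Data frame with one row per locus. Required columns:
#'   `chrom` (character), `pos` (1-based bp, integer-ish), `ref`, `alt`
#'   (allele strings over A/C/G/T/N/*). Optional columns: `is_snp`,
#'   `is_biallelic` (derived from ref/alt when absent), `mean_depth`
#'   (mean FORMAT/DP over called samples; `NA` when depth is unknown),
#'   and caller annotations (`fs`, `mq_rank_sum`, `read_pos_rank_sum`,
#'   `qd`, `mq`).
#' @param samples Data frame with one row per sample. Required columns:
#'   `sample_id` (unique), `sex` (one of `"male"`, `"female"`,
#'   `"unknown"`), `population` (character label).
#' @return An object of class `geno_matrix`.
#' @examples
#' g <- geno_matrix(
#'   calls   = matrix(c(0L, 1L, 2L, NA), nrow = 2),
#'   loci    = tibble::tibble(chrom = "LG11", pos = c(100L, 200L),
#'                            ref = "A", alt = "T"),
#'   samples = tibble::tibble(sample_id = c("s1", "s2"),
#'                            sex = c("female", "male"), population = "pop1")
#' )
#' g
#' @export
geno_matrix <- function(calls, loci, samples) {
  loci <- tibble::as_tibble(loci)
  samples <- tibble::as_tibble(samples)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"

  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(loci)),
    all(c("sample_id", "sex", "population") %in% names(samples)),
    nrow(calls) == nrow(loci),
    ncol(calls) == nrow(samples)
  )
  if (anyDuplicated(samples$sample_id)) {
    stop("sample ids must be unique within a cohort", call. = FALSE)
  }
  if (any(loci$pos < 1)) stop("locus positions are 1-based (pos >= 1)", call. = FALSE)
  # alt may hold a comma-separated allele list at multi-allelic records
  bad_allele <- !grepl("^[ACGTN*]+$", loci$ref) |
    !grepl("^[ACGTN*]+(,[ACGTN*]+)*$", loci$alt)
  if (any(bad_allele)) {
    stop("ref/alt alleles must be non-empty strings over {A,C,G,T,N,*}; first bad locus at row ",
         which(bad_allele)[1], call. = FALSE)
  }
  bad_sex <- !samples$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) {
    stop("sample sex must be 'male', 'female' or 'unknown'", call. = FALSE)
  }
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)

  if (!"is_snp" %in% names(loci)) {
    loci$is_snp <- nchar(loci$ref) == 1L & nchar(loci$alt) == 1L &
      !grepl(",", loci$alt, fixed = TRUE)
  }
  if (!"is_biallelic" %in% names(loci)) {
    loci$is_biallelic <- !grepl(",", loci$alt, fixed = TRUE)
  }
  if (!"mean_depth" %in% names(loci)) loci$mean_depth <- NA_real_
  loci$pos <- as.integer(loci$pos)

  dimnames(calls) <- list(NULL, samples$sample_id)
  structure(
    list(loci = loci, samples = samples, calls = calls),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$loci), " loci x ", nrow(x$samples), " samples\n", sep = "")
  sx <- table(factor(x$samples$sex, levels = c("female", "male", "unknown")))
  cat("  samples: ", sx[["female"]], " female, ", sx[["male"]], " male, ",
      sx[["unknown"]], " unknown; populations: ",
      paste(unique(x$samples$population), collapse = ", "), "\n", sep = "")
  cat("  missing calls: ",
      format(100 * mean(is.na(x$calls)), digits = 3), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$loci), nrow(x$samples))

#' Subset a genotype matrix by loci and/or samples
#'
#' @param x A [geno_matrix()].
#' @param i Locus index (logical or integer).
#' @param j Sample index (logical or integer).
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the selected loci and samples.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$loci))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  geno_matrix(x$calls[i, j, drop = FALSE], x$loci[i, , drop = FALSE],
              x$samples[j, , drop = FALSE])
}

#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  dplyr::bind_cols(
    x$loci,
    tibble::as_tibble(x$calls, .name_repair = "minimal")
  )
}

#' Per-locus, per-sex genotype counts
#'
#' Tabulates, for every locus, the number of hom-ref / het / hom-alt /
#' missing individuals within each phenotypic sex. Counts partition the
#' samples of each sex at every locus.
#'
#' @param g A [geno_matrix()].
#' @param exclude_unknown Drop samples with `sex == "unknown"` before
#'   counting. With the default `FALSE`, their presence is an error:
#'   sexed counts would silently lose individuals otherwise.
#' @return A tibble with one row per locus: the locus columns plus
#'   `f_hom_ref`, `f_het`, `f_hom_alt`, `f_missing`, `m_hom_ref`,
#'   `m_het`, `m_hom_alt`, `m_missing`.
#' @export
count_genotypes <- function(g, exclude_unknown = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  unk <- g$samples$sex == "unknown"
  if (any(unk)) {
    if (!exclude_unknown) {
      stop("cohort contains samples of unknown sex; drop them or set ",
           "exclude_unknown = TRUE", call. = FALSE)
    }
    g <- g[, !unk]
  }
  fem <- g$samples$sex == "female"
  count_sex <- function(m) {
    cbind(
      hom_ref = rowSums(m == 0L, na.rm = TRUE),
      het     = rowSums(m == 1L, na.rm = TRUE),
      hom_alt = rowSums(m == 2L, na.rm = TRUE),
      missing = rowSums(is.na(m))
    )
  }
  fc <- count_sex(g$calls[, fem, drop = FALSE])
  mc <- count_sex(g$calls[, !fem, drop = FALSE])
  dplyr::bind_cols(
    g$loci,
    tibble::tibble(
      f_hom_ref = unname(fc[, 1]), f_het = unname(fc[, 2]),
      f_hom_alt = unname(fc[, 3]), f_missing = unname(fc[, 4]),
      m_hom_ref = unname(mc[, 1]), m_het = unname(mc[, 2]),
      m_hom_alt = unname(mc[, 3]), m_missing = unname(mc[, 4])
    )
  )
}

#' Alternative-allele frequency from genotype counts
#'
#' `alt_allele_freq()` returns the alternative-allele frequency
#' `(n_het + 2 n_hom_alt) / (2 n_called)`; `maf()` folds it to the minor
#' allele, `min(f, 1 - f)`. Both are vectorised.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (individuals).
#' @return Frequency in `[0, 1]`. An element with zero called
#'   individuals is an error: the frequency is undefined there.
#' @examples
#' alt_allele_freq(1, 2, 1) # 0.5
#' @export
alt_allele_freq <- function(n_hom_ref, n_het, n_hom_alt) {
  n_called <- n_hom_ref + n_het + n_hom_alt
  if (any(n_called == 0)) {
    stop("allele frequency undefined: no called individuals", call. = FALSE)
  }
  (n_het + 2 * n_hom_alt) / (2 * n_called)
}

#' @rdname alt_allele_freq
#' @export
maf <- function(n_hom_ref, n_het, n_hom_alt) {
  f <- alt_allele_freq(n_hom_ref, n_het, n_hom_alt)
  pmin(f, 1 - f)
}
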