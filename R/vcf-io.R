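#' Read a VCF into a genotype matrix
#'
#' Reads GT (mandatory) and per-sample DP (optional) from a VCF v4.2 file
#' and pairs the calls with a sample metadata table. Phased and unphased
#' genotypes are treated identically; any half-call (`./1`) or full
#' missing (`./.`) becomes `NA`. Multi-allelic records are retained with
#' `is_biallelic = FALSE` (dropping them is a filter's job); any genotype
#' containing an allele index > 1 at such a record is coded by zygosity
#' of the listed alleles (two identical non-ref alleles = hom-alt,
#' differing alleles = het).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param samples_meta Sample table as returned by [read_sample_meta()],
#'   or a data frame with columns `sample_id`, `sex`, `population`.
#'   Must cover every sample named in the VCF.
#' @return A [geno_matrix()]. `mean_depth` is the mean FORMAT/DP over
#'   called samples when DP is present, otherwise `NA` (depth filters
#'   then no-op with a warning). INFO annotations FS, MQRankSum,
#'   ReadPosRankSum, QD and MQ are carried into the loci table when
#'   present.
#' @export
read_vcf <- function(path, samples_meta) {
  samples_meta <- tibble::as_tibble(samples_meta)
  stopifnot(all(c("sample_id", "sex", "population") %in% names(samples_meta)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v, getINFO = TRUE))

  vcf_samples <- colnames(v@gt)[-1]
  missing_meta <- setdiff(vcf_samples, samples_meta$sample_id)
  if (length(missing_meta) > 0) {
    stop("VCF samples absent from metadata: ",
         paste(head(missing_meta, 5), collapse = ", "), call. = FALSE)
  }
  samples <- samples_meta[match(vcf_samples, samples_meta$sample_id), ]

  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- encode_gt(gt)

  loci <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  loci$is_biallelic <- !grepl(",", loci$alt, fixed = TRUE)
  first_alt <- sub(",.*$", "", loci$alt)
  loci$is_snp <- nchar(loci$ref) == 1L & nchar(first_alt) == 1L & loci$is_biallelic

  dp <- tryCatch(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
    error = function(e) NULL
  )
  if (!is.null(dp) && !all(is.na(dp))) {
    loci$mean_depth <- unname(rowMeans(dp, na.rm = TRUE))
    loci$mean_depth[is.nan(loci$mean_depth)] <- NA_real_
  } else {
    loci$mean_depth <- NA_real_
  }

  info <- fix$INFO
  if (!all(is.na(info) | info == ".")) {
    grab <- function(key) {
      val <- sub(paste0(".*(?:^|;)", key, "=([^;]+).*"), "\\1", info)
      out <- suppressWarnings(as.numeric(val))
      out[!grepl(paste0("(^|;)", key, "="), info)] <- NA_real_
      out
    }
    loci$fs <- grab("FS")
    loci$mq_rank_sum <- grab("MQRankSum")
    loci$read_pos_rank_sum <- grab("ReadPosRankSum")
    loci$qd <- grab("QD")
    loci$mq <- grab("MQ")
  }

  geno_matrix(calls, loci, samples)
}

# GT strings -> 0/1/2/NA zygosity codes; vectorised over the whole matrix.
encode_gt <- function(gt) {
  u <- unique(as.vector(gt))
  code1 <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(al))
    if (any(is.na(a))) return(NA_integer_)
    if (a[1] == 0L && a[2] == 0L) 0L else if (a[1] != a[2]) 1L else 2L
  }, integer(1))
  m <- matrix(code1[match(as.vector(gt), u)], nrow = nrow(gt))
  colnames(m) <- colnames(gt)
  m
}

#' Write a genotype matrix as a VCF v4.2 file
#'
#' Emits a minimal plain-text VCF with GT only (coded `0/0`, `0/1`,
#' `1/1`, `./.`). `read_vcf(write_vcf(g))` round-trips calls, positions
#' and alleles exactly.
#'
#' @param g A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$calls + 1L], nrow = nrow(g$calls))
  gt_str[is.na(g$calls)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  body <- paste(
    g$loci$chrom, g$loci$pos, ".", g$loci$ref, g$loci$alt, ".", ".", ".", "GT",
    apply(gt_str, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write the sample metadata table
#'
#' Sample metadata is a TSV with header `sample_id  sex  population`;
#' `sex` must be `male`, `female` or `unknown`.
#'
#' @param path TSV file path.
#' @return `read_sample_meta()`: a tibble with the three columns.
#' @export
read_sample_meta <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  stopifnot(all(c("sample_id", "sex", "population") %in% names(m)))
  bad <- !m$sex %in% c("male", "female", "unknown")
  if (any(bad)) {
    stop("unrecognised sex value(s): ", paste(unique(m$sex[bad]), collapse = ", "),
         call. = FALSE)
  }
  m
}

#' @rdname read_sample_meta
#' @param samples Sample tibble (`sample_id`, `sex`, `population`).
#' @export
write_sample_meta <- function(samples, path) {
  readr::write_tsv(samples[, c("sample_id", "sex", "population")], path,
                   progress = FALSE)
  invisible(path)
}
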