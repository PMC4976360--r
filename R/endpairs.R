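#' Cut long reads into artificial fixed-length end pairs
#'
#' Converts each long read into one artificial paired-end read: mate 1
#' is the first `end_len` bases, mate 2 the reverse complement of the
#' last `end_len` bases (standard forward-reverse orientation; set
#' `revcomp = FALSE` to keep mate 2 on the forward strand). Reads
#' shorter than `2 * end_len` are skipped — overlapping mates would
#' misrepresent the insert — and counted. Names gain `/1` and `/2`
#' suffixes; FASTQ qualities are sliced in register with the bases
#' (mate 2 qualities reversed along with the sequence).
#'
#' @param reads A `Biostrings::DNAStringSet` (FASTA case) or
#'   `Biostrings::QualityScaledDNAStringSet` (FASTQ case).
#' @param end_len Mate length in bases (default 300).
#' @param revcomp Reverse-complement mate 2 (default `TRUE`).
#' @return A list: `mate1`, `mate2` (same class as the input) and
#'   `report` (tibble: `n_input`, `n_pairs`, `n_skipped`).
#' @examples
#' reads <- Biostrings::DNAStringSet(c(r1 = "ACGTACGTACGT"))
#' make_end_pairs(reads, end_len = 4)
#' @export
make_end_pairs <- function(reads, end_len = 300L, revcomp = TRUE) {
  stopifnot(end_len >= 1)
  has_qual <- methods::is(reads, "QualityScaledDNAStringSet")
  w <- Biostrings::width(reads)
  keep <- w >= 2L * end_len
  kept <- reads[keep]

  mate1 <- Biostrings::subseq(kept, start = 1L, width = end_len)
  mate2 <- Biostrings::subseq(kept, start = Biostrings::width(kept) - end_len + 1L,
                              width = end_len)
  if (revcomp) {
    if (has_qual) {
      # reverseComplement drops qualities; reverse them in register
      q2 <- Biostrings::reverse(methods::slot(mate2, "quality"))
      rc <- Biostrings::reverseComplement(methods::as(mate2, "DNAStringSet"))
      # constructor warns about dropped mcols; none are carried here
      mate2 <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(rc, q2))
    } else {
      mate2 <- Biostrings::reverseComplement(mate2)
    }
  }
  base <- names(kept)
  if (is.null(base)) base <- sprintf("read%06d", which(keep))
  names(mate1) <- paste0(base, "/1")
  names(mate2) <- paste0(base, "/2")

  list(
    mate1 = mate1,
    mate2 = mate2,
    report = tibble::tibble(
      n_input = length(reads),
      n_pairs = sum(keep),
      n_skipped = sum(!keep)
    )
  )
}

#' File-to-file end-pair extraction
#'
#' Reads FASTA or FASTQ (by `format`), applies [make_end_pairs()], and
#' writes the two mate files in the input's format (FASTA in gives
#' FASTA out — no fabricated qualities).
#'
#' @param input Input FASTA/FASTQ path.
#' @param out1,out2 Output paths for mate 1 and mate 2.
#' @param end_len,revcomp Passed to [make_end_pairs()].
#' @param format `"fasta"` or `"fastq"`; guessed from the file extension
#'   by default.
#' @return The skip-report tibble, invisibly.
#' @export
end_pairs_file <- function(input, out1, out2, end_len = 300L, revcomp = TRUE,
                           format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", input)) "fastq" else "fasta"
  }
  reads <- if (format == "fastq") {
    # the reader always warns about dropped mcols on plain FASTQ
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(input))
  } else {
    Biostrings::readDNAStringSet(input, format = "fasta")
  }
  pairs <- make_end_pairs(reads, end_len = end_len, revcomp = revcomp)
  if (format == "fastq") {
    Biostrings::writeQualityScaledXStringSet(pairs$mate1, out1)
    Biostrings::writeQualityScaledXStringSet(pairs$mate2, out2)
  } else {
    Biostrings::writeXStringSet(pairs$mate1, out1, format = "fasta")
    Biostrings::writeXStringSet(pairs$mate2, out2, format = "fasta")
  }
  invisible(pairs$report)
}
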