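#' Simulation configuration for a diploid cohort with a planted sex locus
#'
#' Describes a wild-cohort genotype simulation: sex-independent
#' Hardy-Weinberg background loci spread over a chromosome layout, plus
#' a planted sex-determining haplotype inside one interval. Planted loci
#' follow the heterogamety model: the homogametic sex is homozygous and
#' the heterogametic sex heterozygous with probability `lambda` per
#' locus (sex-linkage completeness; `lambda < 1` emulates regions only
#' inconsistently linked to sex). Three noise layers are applied to the
#' true genotypes, in this fixed order: heterozygote dropout (a true het
#' is observed homozygous with probability `het_dropout`, split equally
#' between the two homozygotes — the signature failure of low-coverage
#' genotyping), uniform genotype error (`genotype_error`, reassignment
#' to either other state), and missingness (`missing_rate`).
#'
#' The defaults mirror the Atlantic cod study design this package was
#' built around: 110 males and 116 females, a 10^5-locus background over
#' five linkage groups, and 200 fully linked XY loci in a 50 kb interval
#' on LG11.
#'
#' @param n_males,n_females Cohort composition.
#' @param chrom_layout Tibble with columns `chrom`, `length_bp`,
#'   `n_loci`: background loci are placed uniformly at random (without
#'   replacement) along each chromosome.
#' @param planted Tibble (or named list) with `chrom`, `start`, `stop`,
#'   `n_loci` for the sex haplotype; `n_loci = 0` gives a null cohort.
#' @param system `"XY"` (males heterogametic) or `"ZW"` (females
#'   heterogametic).
#' @param lambda Per-locus probability that a heterogametic individual
#'   is heterozygous at a planted locus.
#' @param freq_range Background alternative-allele frequencies are drawn
#'   uniformly from this range.
#' @param genotype_error,het_dropout,missing_rate Noise rates in [0,1].
#' @param mixed_polarity Fraction of planted loci at which the
#'   homogametic sex is homozygous-alternative instead of
#'   homozygous-reference (observed at a minority of real sex-linked
#'   loci).
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_males = 110L, n_females = 116L,
                       chrom_layout = default_chrom_layout(),
                       planted = list(chrom = "LG11", start = 11870000L,
                                      stop = 11920000L, n_loci = 200L),
                       system = c("XY", "ZW"),
                       lambda = 1.0,
                       freq_range = c(0.05, 0.5),
                       genotype_error = 0.005,
                       het_dropout = 0.05,
                       missing_rate = 0.05,
                       mixed_polarity = 0,
                       seed = 1L) {
  system <- match.arg(system)
  planted <- as.list(planted)
  chrom_layout <- tibble::as_tibble(chrom_layout)
  stopifnot(
    n_males >= 1, n_females >= 1,
    all(c("chrom", "length_bp", "n_loci") %in% names(chrom_layout)),
    lambda >= 0, lambda <= 1,
    genotype_error >= 0, genotype_error <= 1,
    het_dropout >= 0, het_dropout <= 1,
    missing_rate >= 0, missing_rate <= 1,
    mixed_polarity >= 0, mixed_polarity <= 1
  )
  if (planted$n_loci > 0) {
    lay <- chrom_layout[chrom_layout$chrom == planted$chrom, ]
    stopifnot(nrow(lay) == 1, planted$start >= 1,
              planted$stop <= lay$length_bp, planted$start <= planted$stop)
  }
  structure(
    list(n_males = as.integer(n_males), n_females = as.integer(n_females),
         chrom_layout = chrom_layout, planted = planted, system = system,
         lambda = lambda, freq_range = freq_range,
         genotype_error = genotype_error, het_dropout = het_dropout,
         missing_rate = missing_rate, mixed_polarity = mixed_polarity,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_chrom_layout <- function() {
  tibble::tibble(
    chrom = c("LG04", "LG08", "LG11", "LG14", "LG23"),
    length_bp = c(35e6, 30e6, 28e6, 27e6, 25e6),
    n_loci = c(24000L, 21000L, 20000L, 19000L, 16000L)
  )
}

#' Simulate a diploid genotype cohort with known truth
#'
#' Draws a [geno_matrix()] according to a [sim_config()] and returns it
#' with the simulation ground truth. Background genotypes are i.i.d.
#' Hardy-Weinberg draws independent of sex; planted loci realise the
#' configured sex-haplotype model before the noise layers are applied.
#' Identical configurations (including `seed`) give bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A list: `matrix` (the `geno_matrix`; samples carry their true
#'   sex as phenotype, population `"sim"`) and `truth` (list with
#'   `sexes` tibble, `planted` locus tibble with per-locus `lambda` and
#'   `polarity`, and the `config`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_m <- config$n_males
  n_f <- config$n_females
  n <- n_m + n_f
  sexes <- rep(c("female", "male"), c(n_f, n_m))
  heterogametic <- if (config$system == "XY") sexes == "male" else sexes == "female"

  # background loci
  lay <- config$chrom_layout
  bg <- purrr::pmap(lay, function(chrom, length_bp, n_loci) {
    tibble::tibble(chrom = chrom,
                   pos = sort(sample.int(length_bp, n_loci)),
                   planted = FALSE)
  }) %>% dplyr::bind_rows()

  # planted loci inside the sex interval
  pl <- config$planted
  if (pl$n_loci > 0) {
    span <- pl$stop - pl$start + 1L
    stopifnot(pl$n_loci <= span)
    planted_tb <- tibble::tibble(
      chrom = pl$chrom,
      pos = pl$start + sort(sample.int(span, pl$n_loci)) - 1L,
      planted = TRUE
    )
    loci <- dplyr::bind_rows(bg, planted_tb)
  } else {
    loci <- bg
  }
  loci <- dplyr::arrange(loci, match(.data$chrom, lay$chrom), .data$pos)
  loci <- loci[!duplicated(loci[, c("chrom", "pos")]), ]
  n_loci <- nrow(loci)

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_loci, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(alleles, r), 1),
                       character(1)))

  calls <- matrix(NA_integer_, nrow = n_loci, ncol = n)
  is_pl <- loci$planted
  n_bg <- sum(!is_pl)

  # background: HWE, sex-independent
  p_bg <- runif(n_bg, config$freq_range[1], config$freq_range[2])
  calls[!is_pl, ] <- rbinom(n_bg * n, 2L, rep(p_bg, times = n))

  # planted: homogametic homozygous, heterogametic HET w.p. lambda
  polarity <- rep(0L, n_loci)  # 0 = homogametic HOM_REF, 2 = HOM_ALT
  if (any(is_pl)) {
    k <- sum(is_pl)
    polarity[is_pl] <- ifelse(runif(k) < config$mixed_polarity, 2L, 0L)
    hom_code <- matrix(rep(polarity[is_pl], times = n), nrow = k)
    het_draw <- matrix(runif(k * n) < config$lambda, nrow = k)
    g_pl <- hom_code
    g_pl[, heterogametic][het_draw[, heterogametic]] <- 1L
    calls[is_pl, ] <- g_pl
  }

  # noise layers, fixed order: dropout -> error -> missingness
  if (config$het_dropout > 0) {
    het <- which(calls == 1L)
    drop <- het[runif(length(het)) < config$het_dropout]
    calls[drop] <- 2L * (runif(length(drop)) < 0.5)
  }
  if (config$genotype_error > 0) {
    err <- which(runif(length(calls)) < config$genotype_error)
    # reassign uniformly to one of the two other states
    shift <- 1L + (runif(length(err)) < 0.5)
    calls[err] <- (calls[err] + shift) %% 3L
  }
  if (config$missing_rate > 0) {
    calls[runif(length(calls)) < config$missing_rate] <- NA_integer_
  }

  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    sex = sexes,
    population = "sim"
  )
  loci_tb <- tibble::tibble(chrom = loci$chrom, pos = loci$pos,
                            ref = ref, alt = alt)
  g <- geno_matrix(calls, loci_tb, samples)

  truth <- list(
    sexes = tibble::tibble(sample_id = samples$sample_id, true_sex = sexes),
    planted = tibble::tibble(
      chrom = loci$chrom[is_pl], pos = loci$pos[is_pl],
      lambda = config$lambda,
      polarity = ifelse(polarity[is_pl] == 0L, "ref", "alt")
    ),
    config = config
  )
  list(matrix = g, truth = truth)
}

#' Write simulation truth to plain-text files
#'
#' The planted sex-haplotype loci go to a BED file (0-based half-open
#' intervals, one per locus) and the true sexes to a TSV.
#'
#' @param truth The `truth` element of [simulate_cohort()] output.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed_path <- file.path(dir, "planted.bed")
  tsv_path <- file.path(dir, "true_sexes.tsv")
  bed <- tibble::tibble(
    chrom = truth$planted$chrom,
    start = truth$planted$pos - 1L,   # 1-based inclusive -> 0-based half-open
    end = truth$planted$pos
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  readr::write_tsv(truth$sexes, tsv_path, progress = FALSE)
  invisible(c(bed = bed_path, sexes = tsv_path))
}

#' @rdname write_truth
#' @param dir_or_bed Directory written by `write_truth()`.
#' @return `read_truth()`: a list with `planted` (tibble `chrom`, `pos`,
#'   1-based) and `sexes`.
#' @export
read_truth <- function(dir_or_bed) {
  bed_path <- file.path(dir_or_bed, "planted.bed")
  bed <- if (file.size(bed_path) == 0) {
    tibble::tibble(chrom = character(), start = integer(), end = integer())
  } else {
    readr::read_tsv(bed_path, col_names = c("chrom", "start", "end"),
                    col_types = "cii", progress = FALSE)
  }
  sexes <- readr::read_tsv(file.path(dir_or_bed, "true_sexes.tsv"),
                           col_types = "cc", progress = FALSE)
  list(planted = tibble::tibble(chrom = bed$chrom, pos = bed$start + 1L),
       sexes = sexes)
}
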