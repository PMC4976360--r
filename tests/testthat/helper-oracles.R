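# Independent oracles and small fixture builders shared across tests.

# Exact enumeration oracle for the genotypic 2x3 test.
#
# Works in exact integer arithmetic: with margins fixed, every table's
# point probability is C(c0,a) C(c1,b) C(c2,c) / C(N,nf), and by
# Vandermonde the numerators sum to C(N,nf).  For N <= 30 every
# numerator is <= C(30,15) = 155117520, so all integers involved are
# exactly representable in doubles and the enumeration is exact.  The
# (1 + tie_tol) tie rule is part of the test's definition and is applied
# here on the integer scale.
oracle_fisher_2x3 <- function(f0, f1, f2, m0, m1, m2, tie_tol = 1e-7) {
  c0 <- f0 + m0; c1 <- f1 + m1; c2 <- f2 + m2
  nf <- f0 + f1 + f2
  N <- c0 + c1 + c2
  stopifnot(N <= 30)
  grid <- expand.grid(a = 0:min(c0, nf), b = 0:min(c1, nf))
  grid$cc <- nf - grid$a - grid$b
  grid <- grid[grid$cc >= 0 & grid$cc <= c2, ]
  num <- choose(c0, grid$a) * choose(c1, grid$b) * choose(c2, grid$cc)
  obs <- choose(c0, f0) * choose(c1, f1) * choose(c2, f2)
  sum(num[num <= obs * (1 + tie_tol)]) / choose(N, nf)
}

# All (c0, c1, c2, nf) margin configurations with total n in n_range and
# both sexes non-empty.
all_margin_configs <- function(n_range) {
  cfg <- list()
  for (N in n_range) {
    for (c0 in 0:N) for (c1 in 0:(N - c0)) {
      c2 <- N - c0 - c1
      for (nf in 1:(N - 1)) {
        cfg[[length(cfg) + 1L]] <- c(c0, c1, c2, nf)
      }
    }
  }
  do.call(rbind, cfg)
}

# A deterministic extreme observed table for given margins: pack females
# into the hom-ref column first, then het, then hom-alt.
extreme_table <- function(c0, c1, c2, nf) {
  f0 <- min(c0, nf)
  f1 <- min(c1, nf - f0)
  f2 <- nf - f0 - f1
  c(f0 = f0, f1 = f1, f2 = f2, m0 = c0 - f0, m1 = c1 - f1, m2 = c2 - f2)
}

# Tiny geno_matrix from an explicit call matrix, defaulting to one
# population and alternating-sex samples.
toy_matrix <- function(calls, sexes = NULL, chrom = "LG1",
                       pos = NULL, ref = "A", alt = "T") {
  calls <- rbind(calls)
  n <- ncol(calls)
  if (is.null(sexes)) sexes <- rep(c("female", "male"), length.out = n)
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 100L
  geno_matrix(
    calls,
    tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)), sex = sexes,
                   population = "pop1")
  )
}

# Random geno_matrix for round-trip / property tests.
random_matrix <- function(n_loci = 50, n_samples = 20, missing = 0.1) {
  calls <- matrix(sample(c(0:2, NA), n_loci * n_samples, replace = TRUE,
                         prob = c((1 - missing) / 3, (1 - missing) / 3,
                                  (1 - missing) / 3, missing)),
                  nrow = n_loci)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_loci, TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(alleles, r), 1),
                       character(1)))
  geno_matrix(
    calls,
    tibble::tibble(chrom = sample(c("LG1", "LG2"), n_loci, TRUE),
                   pos = sample.int(1e6, n_loci), ref = ref, alt = alt),
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(n_samples)),
                   sex = rep(c("female", "male"), length.out = n_samples),
                   population = rep(c("popA", "popB"),
                                    length.out = n_samples))
  )
}
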