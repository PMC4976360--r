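test_that("association-free tables give p = 1", {
  # single nonzero genotype row: no other table has the same margins
  res <- fisher_exact_2x3(10, 0, 0, 7, 0, 0)
  expect_equal(res$log_p, 0)
  expect_equal(res$neglog10_p, 0)
  res <- fisher_exact_2x3(0, 12, 0, 0, 9, 0)
  expect_equal(res$log_p, 0)
})

test_that("the full-cohort perfect-segregation table transforms to ~67", {
  res <- fisher_exact_2x3(116, 0, 0, 0, 110, 0)
  expect_equal(round(res$neglog10_p), 67)
  # closed form: unique most-extreme table, p = 1 / C(226, 116)
  expect_equal(res$log_p, -lchoose(226, 116), tolerance = 1e-12)
})

test_that("perfect segregation has p = 1/C(N, N_f) for unequal sex counts", {
  for (nn in list(c(27, 21), c(10, 5), c(8, 13), c(30, 29))) {
    nf <- nn[1]; nm <- nn[2]
    res <- fisher_exact_2x3(nf, 0, 0, 0, nm, 0)
    expect_equal(res$log_p, -lchoose(nf + nm, nf), tolerance = 1e-12)
    if (nf + nm <= 30) {
      expect_equal(exp(res$log_p),
                   oracle_fisher_2x3(nf, 0, 0, 0, nm, 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("log-space p agrees with the exact enumeration oracle on random small tables", {
  set.seed(51)
  for (rep in 1:200) {
    N <- sample(2:30, 1)
    nf <- sample(1:(N - 1), 1)
    splits <- sort(sample(0:N, 2, replace = TRUE))
    c0 <- splits[1]; c1 <- splits[2] - splits[1]; c2 <- N - splits[2]
    tb <- extreme_table(c0, c1, c2, nf)
    # scatter to a random (not extreme) table by moving females around
    f0 <- sample(0:min(c0, nf), 1)
    f1 <- sample(0:min(c1, nf - f0), 1)
    f2 <- nf - f0 - f1
    if (f2 > c2) next
    p_impl <- exp(fisher_exact_2x3(f0, f1, f2, c0 - f0, c1 - f1, c2 - f2)$log_p)
    p_oracle <- oracle_fisher_2x3(f0, f1, f2, c0 - f0, c1 - f1, c2 - f2)
    expect_equal(p_impl, p_oracle, tolerance = 1e-9)
  }
})

test_that("stats::fisher.test corroborates the exact p on moderate tables", {
  set.seed(52)
  for (rep in 1:20) {
    f <- rmultinom(1, 15, c(0.4, 0.4, 0.2))[, 1]
    m <- rmultinom(1, 12, c(0.2, 0.5, 0.3))[, 1]
    tab <- rbind(f, m)
    if (any(colSums(tab) == 0)) next
    p_impl <- exp(fisher_exact_2x3(f[1], f[2], f[3], m[1], m[2], m[3])$log_p)
    p_ref <- stats::fisher.test(tab)$p.value
    expect_equal(p_impl, p_ref, tolerance = 1e-6)
  }
})

test_that("the scan keeps genome order and flags untestable loci", {
  calls <- rbind(
    c(0L, 0L, 1L, 1L),          # testable
    c(NA, NA, 1L, 1L),          # no called females -> untestable
    c(0L, 0L, 0L, 0L)           # monomorphic -> p = 1
  )
  g <- toy_matrix(calls, sexes = c("female", "female", "male", "male"))
  sc <- scan_sex_association(g)
  expect_equal(sc$pos, g$loci$pos)
  expect_equal(sc$tested, c(TRUE, FALSE, TRUE))
  expect_true(is.na(sc$log_p[2]))
  expect_equal(sc$log_p[3], 0)
})

test_that("published discovery counts all scan to neglog10 p >= 10", {
  g <- cod_discovery_matrix()
  sc <- scan_sex_association(g)
  expect_equal(nrow(sc), 13L)
  expect_true(all(sc$tested))
  expect_true(all(sc$neglog10_p >= 10))
})

test_that("adding association-free loci leaves per-locus p unchanged", {
  g <- cod_discovery_matrix()
  p1 <- scan_sex_association(g)$log_p
  extra <- toy_matrix(matrix(0L, 3, 48), pos = c(1L, 2L, 3L),
                      sexes = g$samples$sex)
  g2 <- geno_matrix(rbind(g$calls, extra$calls),
                    dplyr::bind_rows(g$loci, extra$loci), g$samples)
  p2 <- scan_sex_association(g2)$log_p
  expect_equal(p2[1:13], p1)
})

test_that("exact-test p-values are conservative under sex permutation", {
  g <- cod_discovery_matrix()
  set.seed(53)
  pvals <- c()
  for (i in 1:30) {
    gp <- g
    gp$samples$sex <- sample(gp$samples$sex)
    pvals <- c(pvals, exp(scan_sex_association(gp)$log_p))
  }
  # stochastically >= uniform: empirical CDF below the diagonal
  for (q in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= q), q + 2 * sqrt(q * (1 - q) / length(pvals)))
  }
})

test_that("a planted cluster is called as one region with exact bounds", {
  set.seed(54)
  n <- 1000
  pos <- sort(sample.int(2e7, n))
  stat <- abs(rnorm(n, 0.5, 0.2))
  planted <- 480:484
  stat[planted] <- 50 + runif(length(planted))
  sc <- tibble::tibble(
    chrom = "LG03", pos = pos, maf = 0.3, tested = TRUE,
    log_p = -stat * log(10), neglog10_p = stat
  )
  r <- call_regions(sc)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, pos[min(planted)])
  expect_equal(r$stop, pos[max(planted)])
  expect_equal(r$size, r$stop - r$start)
  expect_equal(r$n_sex_linked, length(planted))
})

test_that("extreme loci far apart on one chromosome split into two regions", {
  set.seed(56)
  sc <- tibble::tibble(
    chrom = "LG08",
    pos = c(sort(sample.int(3e7, 1000)), 1784400L, 24118524L),
    maf = 0.3, tested = TRUE,
    neglog10_p = c(abs(rnorm(1000, 0.5, 0.2)), 40, 45)
  )
  sc$log_p <- -sc$neglog10_p * log(10)
  r <- call_regions(sc, merge_gap_bp = 1e6)
  expect_equal(nrow(r), 2L)  # ~22 Mb apart, well over the merge gap
  expect_equal(sort(r$start), c(1784400L, 24118524L))
})

test_that("degenerate scans with zero spread call no regions", {
  sc <- tibble::tibble(chrom = "LG01", pos = 1:10 * 1000L, maf = 0.3,
                       tested = TRUE, neglog10_p = 2, log_p = -2 * log(10))
  r <- call_regions(sc)
  expect_equal(nrow(r), 0L)
  expect_error(call_regions(sc[1, ]), ">= 2 tested loci")
})

test_that("region n_total applies the MAF cutoff while n_sex_linked does not", {
  set.seed(57)
  bg <- tibble::tibble(
    chrom = "LG05", pos = sort(sample.int(2e7, 1000)), maf = 0.25,
    tested = TRUE, neglog10_p = abs(rnorm(1000, 0.5, 0.2))
  )
  # three hits (one below the MAF cutoff) plus a low-MAF non-hit inside
  hits <- tibble::tibble(
    chrom = "LG05", pos = c(20000001L, 20001000L, 20001500L, 20002000L),
    maf = c(0.30, 0.02, 0.01, 0.30),
    tested = TRUE, neglog10_p = c(50, 49, 0.5, 48)
  )
  sc <- dplyr::bind_rows(bg, hits)
  sc$log_p <- -sc$neglog10_p * log(10)
  r <- call_regions(sc)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_sex_linked, 3L)   # includes the maf = 0.02 hit
  expect_equal(r$n_total, 2L)        # maf >= 0.05 loci inside [start, stop]
})

test_that("region accounting sums above-threshold loci across regions", {
  set.seed(55)
  sc <- tibble::tibble(
    chrom = rep(c("LG01", "LG02"), each = 200),
    pos = rep(sort(sample.int(3e7, 200)), 2),
    maf = 0.25, tested = TRUE,
    neglog10_p = abs(rnorm(400, 0.5, 0.3))
  )
  sc$neglog10_p[c(10:14, 250:252)] <- 25
  sc$log_p <- -sc$neglog10_p * log(10)
  r <- call_regions(sc)
  thr <- attr(r, "threshold")
  expect_equal(sum(r$n_sex_linked), sum(sc$neglog10_p > thr))
})

test_that("published region rows summarise to printed sizes and the 166 total", {
  s <- summarize_regions(cod_sex_regions())
  expect_equal(s$regions$size[s$regions$lg == "11"], 54264L)
  expect_equal(s$regions$size[s$regions$lg == "08a"], 413L)
  expect_equal(s$total_sex_linked, 166L)
  expect_equal(s$regions$max_p, c(47L, 19L, 67L, 22L, 41L, 26L))
  one <- summarize_regions(cod_sex_regions()[3, ])
  expect_equal(one$total_sex_linked, one$regions$n_sex_linked)
})

test_that("discovery rate reproduces the genome-wide screening arithmetic", {
  expect_equal(discovery_rate(55160622, 166), 332292)
  expect_equal(discovery_rate(1000, 3), 333)
})
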