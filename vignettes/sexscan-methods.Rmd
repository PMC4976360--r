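---
title: "Methods: sex-locus discovery, genetic sexing and exact association scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-locus discovery, genetic sexing and exact association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

`sexscan` finds and characterises small sex-determining regions in
diploid population genotype data, the situation typified by Atlantic
cod: a genetic XX-XY system whose footprint is a few tens of kilobases,
invisible to karyotyping and to sparse marker panels, but recoverable
from whole-genome genotypes of a modest wild cohort. This vignette
explains the statistical machinery, the tunable parameters, what the
simulator does and does not emulate, and the numerical and design
choices a maintainer should know about.

## The data model

Genotypes live in a `geno_matrix`: a loci table (chromosome, 1-based
position, REF/ALT alleles, SNP/biallelic flags, optional mean depth and
caller annotations), a sample table (id, phenotypic sex, population),
and a loci × samples matrix of zygosity codes — 0 hom-ref, 1 het, 2
hom-alt, `NA` missing. Phase is discarded and every heterozygous
configuration collapses to 1, because every downstream statistic
(segregation counts, homozygosity, the genotypic test) depends on
zygosity only. Half-calls are missing. Multi-allelic records are kept
but flagged; removing them is the job of the site filters, so no
information is silently lost at read time. Coordinates are 1-based
inclusive throughout; only the BED writer converts to 0-based
half-open.

## Site filters

`filter_sites()` reproduces a conventional short-read "filtered
dataset": hard annotation thresholds (FS > 60, MQRankSum < −12.5,
ReadPosRankSum < −8, QD < 2, MQ < 40), removal of SNPs within 10 bp of
an indel's REF footprint, restriction to biallelic SNPs, a mean-depth
cap of 30× (high depth flags repeats and paralogs), MAF ≥ 0.05, and
≤ 10% missing genotypes per population. Two readings are fixed
deliberately:

* thresholds are strict in the direction of the rule's wording
  ("higher than 30", "below 0.05", "more than 10%"), so boundary loci
  are kept;
* indel proximity is measured to the indel's whole REF footprint
  `[pos, pos + nchar(ref) − 1]`, which is well defined for multi-base
  deletions and conservative;
* a locus lacking an annotation is never removed for that annotation —
  simulated VCFs carry no caller annotations, and the filter must
  compose with them (it warns instead).

The mean-depth cap is computed over all samples jointly; a
per-population variant would be a trivial extension but is not what the
filter battery implements. Each filter appends to a report
(`filter_report()`) whose removed counts exactly reconcile input and
output; the filters are pure per-locus predicates, so their order
changes intermediate counts but never the final locus set.

Importantly, *discovery runs on the unfiltered matrix by default*: the
strict segregation criterion is itself a powerful filter, and quality
filtering demonstrably discards genuinely sex-linked indels and SNPs
(in the cod data, 13 loci pass unfiltered versus 3 filtered).

## Segregation discovery

Under XX-XY, a fully sex-linked locus has all females homozygous and
all males heterozygous. The discovery rule tolerates 2 discordant
genotypes per sex — heterozygote dropout is the signature failure of
low-coverage genotyping, and a zero-tolerance rule would discard real
loci — plus 10% missing genotypes. "Homozygous" in the heterogametic
condition counts hom-ref and hom-alt together (a male carrying one
hom-ref and one hom-alt discordance has 2 ≤ 2 and passes, matching the
published 1/18/1 male row). Missingness is assessed over all samples
jointly, the plain reading of "allowing 10% missing data"; a per-sex
mode (`per_sex = TRUE`) is available because the choice is genuinely
open. The thresholds are free parameters of `segregation_criterion()`;
relaxing any of them can only grow the passing set (a tested
invariant).

`orientation_sweep()` runs both orientations with identical
thresholds. On a real XY system the reverse (ZZ-ZW) orientation should
pass nothing; on the cod discovery fixture it is exactly 13 vs 0.
Swapping all sex labels is equivalent to swapping orientation, another
tested invariant.

## Genetic sexing by the inbreeding coefficient

Given a panel of sex-linked loci, each sample's method-of-moments F is
`(O − E)/(L − E)` with `E = Σ 1 − 2p̂(1−p̂)·2n/(2n−1)` over the sample's
called panel sites. Choices made here:

* **Small-sample correction.** The `2n/(2n−1)` factor on expected
  heterozygosity matches the standard per-individual heterozygosity
  estimator in common VCF tooling; an uncorrected mode exists for
  sensitivity analysis. On panels of ≥ 10 sites at n ≈ 200 the factor
  moves F by < 1%.
* **Frequencies from the full cohort**, both sexes pooled: at
  application time the classifier has no other cohort, and pooling is
  what makes the heterogametic sex's F strongly negative (p̂ ≈ 0.25 at
  a fully linked locus with balanced sexes, so E/L ≈ 0.63 while O ≈ 0).
* **Monomorphic panel sites are excluded** with a warning: they carry
  no information and a cohort-wide p̂ ∈ {0, 1} would make per-site
  expected heterozygosity 0, degenerating the estimator.
* **F = 0 exactly, an empty panel, or a vanishing denominator give
  "unknown"** rather than a forced call; F = 0 can occur on tiny
  panels and neither sign is defensible there.

F ≤ 1 always, with equality for a fully homozygous sample; F is
invariant under ref/alt relabelling at any site, and on a neutral HWE
cohort its mean is ~0 — both tested properties.

## The exact genotypic test and region calling

Each locus's 2×3 genotype-by-sex table is tested conditionally on both
margins. The p-value sums multivariate-hypergeometric point
probabilities over all tables with the observed margins whose point
probability is at most the observed one, with a relative tie tolerance
of `1 + 10⁻⁷` mirroring widespread exact-test implementations (ties
between tables are exact rational events; the tolerance keeps the rule
robust to floating-point log arithmetic). The enumeration is a grid
over the female row (at most ~1.3 × 10⁴ tables at n = 226), with all
log binomial coefficients taken from one precomputed `lgamma` table and
the tail accumulated by log-sum-exp — so a perfectly segregating locus
at 116♀/110♂ yields log p = −log C(226,116), i.e. −log₁₀ p ≈ 66.7,
representable exactly in log form where `p` itself would not underflow
until far later. The test suite checks this log-space path against an
independent exact integer enumeration (all numerators of the
conditional probabilities are integers ≤ C(30,15) for n ≤ 30, hence
exactly representable in doubles) and against `stats::fisher.test` on
moderate tables.

`call_regions()` thresholds −log₁₀ p at mean + k·SD computed over all
tested loci genome-wide (sample SD, n − 1; fixed for reproducibility,
numerically irrelevant at genome scale), then clusters strictly
above-threshold loci per chromosome, splitting where consecutive hits
are more than `merge_gap_bp` apart. The default 6 SD follows the
genome-scan convention this package reproduces; the default 1 Mb gap is
large enough to keep a ~55 kb cluster whole and small enough to split
two clusters ~22 Mb apart on one chromosome. Regions are delimited by
their first and last hit; `size = stop − start`; `n_total` counts all
tested loci with MAF ≥ 0.05 inside the interval (the MAF cutoff applies
*only* to `n_total`, so `n_sex_linked > n_total` is possible and not an
error). With zero spread in the statistic the threshold equals the mean
and no locus is strictly above it: zero regions, by design.

A caution that the test suite documents explicitly: under a *pure
null*, −log₁₀ p is approximately −log₁₀ of a uniform variate, whose
mean + 6 SD sits near 3.0 — i.e. p ≈ 10⁻³, which ~1 in 10³ null loci
exceeds. The 6-SD rule therefore yields a handful of isolated
single-locus "regions" per 10⁴ null loci, and it separates signal from
noise only because genuine sex-linked loci reach −log₁₀ p of 20-70,
orders of magnitude beyond the null tail. Users scanning small locus
sets should treat single-locus regions with modest statistics as noise;
the packaged type-I check (fraction of null loci with p < 0.05 is
≤ 0.05) is the calibration statement that actually holds.

## The simulator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with defaults set to the cod study design: 110 males and 116
females, 10⁵ background loci over five linkage groups, and 200 fully
linked planted loci in a 50 kb interval on LG11.

* Background loci: alt frequency ~ Uniform(0.05, 0.5), genotypes i.i.d.
  Hardy-Weinberg, independent of sex.
* Planted loci: homogametic sex homozygous; heterogametic sex
  heterozygous with probability λ per locus (λ < 1 emulates
  "inconsistently sex-linked" satellite regions). By default the sex
  haplotype carries the ALT allele everywhere; `mixed_polarity` flips a
  fraction of planted loci to hom-ALT homogametic genotypes, as seen at
  a minority of real sex-linked loci.
* Noise, in a fixed order — heterozygote dropout (δ, default 0.05, an
  observed het becomes either homozygote with equal probability), then
  uniform genotype error (ε, default 0.005), then missingness (m,
  default 0.05). The order matters only at second order in the rates;
  fixing it makes cohorts bit-reproducible from a single seed. δ is the
  effective stand-in for coverage-driven heterozygote loss at ~10×
  depth; read depths themselves are not modelled.

Not emulated: linkage disequilibrium and recombination maps (the
scan is per-locus and does not model LD), population structure,
depth-dependent error, and caller annotations. Consequently, passing
tests demonstrate the *statistical* correctness of the chain —
discovery, F-based sexing, scan and region calling recover planted
truth under HWE plus realistic genotype-level noise — but not
robustness to structure or LD artifacts in real data, where the site
filters and the user's judgment must do that work.

Tested end-to-end at the default scale (fixed seed): the scan calls
exactly one 6-SD region covering ≥ 90% of the planted loci, and F-based
classification of all 226 individuals against the panel discovered by
segregation is 100% concordant with the simulated truth. Problem sizes
in the routine test suite are chosen an order of magnitude smaller
(hundreds to thousands of loci, tens of samples) so that the whole
suite exercises every stage in a few minutes.

## Long-read end pairs

`make_end_pairs()` converts long reads into artificial fixed-length
paired-end reads — mate 1 the first `end_len` bases, mate 2 the reverse
complement of the last `end_len` bases (default 300 bp) — the standard
trick for probing assembly continuity across a region with a paired-end
aligner. Mate 2 is reverse-complemented to give forward-reverse
orientation; the generating convention is an assumption, stated and
toggleable (`revcomp = FALSE`). Reads shorter than `2·end_len` are
skipped and counted rather than emitted as overlapping mates, which
would misrepresent insert size. FASTQ qualities are sliced in register
and reversed with mate 2; FASTA input produces FASTA output, with no
fabricated qualities. Alignment and interpretation are out of scope.

## Pipeline and the discovery/classification split

`run_pipeline()` wires the stages with one seed and writes TSV reports
plus a run log. Its default design mirrors the two-stage study: a named
subset of samples is used for segregation discovery, and the remaining
samples — disjoint by construction — are classified against the
discovered panel, so the classification is an honest out-of-sample
check. When no subset is named, discovery and classification both use
the full cohort (appropriate for simulations where truth is known
independently). Stage outputs are pure functions of (inputs, config,
seed); rerunning a config reproduces byte-identical reports.

## Known limitations

* The per-locus exact test ignores LD; region membership, not per-locus
  significance, is the unit of interpretation.
* The 6-SD rule is a convention, not a calibrated error rate (see the
  null-tail caution above).
* The F-based sexer assumes the panel is genuinely sex-linked in the
  cohort being classified; applied across divergent populations a
  panel may decay (λ < 1 in simulation probes this).
* The simulator's independence assumptions make planted signals
  cleaner than real ones; treat its recovery rates as upper bounds.
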