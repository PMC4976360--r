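# sexscan

Sex-locus discovery, genetic sexing and exact association scans from
population genotype data.

In many fish and other non-model vertebrates the sex-determining region
is small, unknown, and detectable only as a handful of loci whose
genotypes track sex. `sexscan` implements the whole-genome-resequencing
route to finding such a region in a wild diploid cohort, as worked out
for Atlantic cod (*Gadus morhua*), where ~166 sex-associated loci in six
small regions — the core one ~55 kb on linkage group 11 — segregate
according to an XX-XY system. The package is aimed at population
geneticists with a jointly called VCF and phenotypic sex records who
want to (i) find candidate sex-linked loci, (ii) sex individuals
genetically, and (iii) delimit the associated genomic regions, with a
simulator to validate the whole chain against known truth.

## What it computes

**Segregation discovery.** Under male heterogamety (XX-XY), a
sex-linked locus is homozygous in females and heterozygous in males;
under ZZ-ZW the roles swap. A locus passes the discovery criterion if,
in the chosen orientation, the homogametic sex shows at most 2
heterozygous genotypes, the heterogametic sex at most 2 homozygous
genotypes (heterozygotes are easily lost from low-coverage data, hence
the tolerance), and missingness is ≤ 10%. Running both orientations
(`orientation_sweep()`) distinguishes XY from ZW systems.

**Genetic sexing.** Over a panel of sex-linked loci, each individual's
method-of-moments inbreeding coefficient is

F = (O − E) / (L − E),  E = Σ_sites [1 − 2p̂(1−p̂)·2n/(2n−1)],

with O the observed homozygous site count, L the called site count, p̂
the cohort allele frequency and n the called individuals at the site.
The heterogametic sex is systematically heterozygous at the panel, so
F < 0 calls a male and F > 0 a female (under XX-XY).

**Exact association scan.** Every locus is tested with a Fisher-type
exact test on the 2×3 genotype-by-sex table (general genotypic test,
not the allelic 2×2), with all tail accumulation in log-space so that
p-values down to 10⁻³⁰⁰ and far below stay exact in log form. Loci with
−log₁₀ p above mean + 6·SD (genome-wide) are clustered into regions
split at gaps > 1 Mb, reported with start/stop/size, locus counts and
the region's maximum statistic.

**Simulator.** `simulate_cohort()` draws Hardy-Weinberg background loci
independent of sex and plants a sex haplotype (XY or ZW, with tunable
linkage completeness), then applies heterozygote dropout, genotype
error and missingness — giving ground truth to validate discovery,
classification and region calling end to end.

## Worked example

The package ships the published genotype counts of the 48-fish
discovery cohort (27 females, 21 males from Lofoten) as a built-in
fixture; `cod_discovery_matrix()` expands them to an explicit cohort.

```r
library(sexscan)

g <- cod_discovery_matrix()
orientation_sweep(g)$summary
#> # A tibble: 2 × 3
#>   orientation heterogametic n_pass
#>   <chr>       <chr>          <int>
#> 1 XY          male              13
#> 2 ZW          female             0
```

All 13 loci pass under XX-XY and none under the reverse rule — the
signature of male heterogamety. Classifying the same cohort against the
discovered panel by the sign of F:

```r
panel <- find_sex_linked(g)
cl <- classify_cohort(g, panel)
cl
#> <sex_classification> 48 samples; 48/48 concordant with phenotypic sex
```

The exact genotypic test at the full-cohort composition (116 females
all hom-ref, 110 males all het) reproduces the strongest published
association:

```r
fisher_exact_2x3(116, 0, 0, 0, 110, 0)
#> # A tibble: 1 × 2
#>   log_p neglog10_p
#>   <dbl>      <dbl>
#> 1 -154.       66.7
```

i.e. −log₁₀ p ≈ 67: there is exactly one most-extreme table, so
p = 1/C(226,116). Summarising the six published sex-associated regions
recomputes their sizes and totals the sex-linked loci:

```r
s <- summarize_regions(cod_sex_regions())
s$regions
#> # A tibble: 6 × 7
#>   lg       start     stop  size n_sex_linked n_total max_p
#>   <chr>    <int>    <int> <int>        <int>   <int> <int>
#> 1 08a    1784400  1784813   413           11      23    47
#> 2 08b   24118524 24118864   340            8      14    19
#> 3 11    11864114 11918378 54264          127     472    67
#> 4 14    27062221 27062388   167            3       8    22
#> 5 15     3678047  3679605  1558           14      64    41
#> 6 17    18769676 18769822   146            3       6    26
s$total_sex_linked
#> [1] 166
```

For a full simulated run (simulate → discover → classify → scan →
regions, with TSV reports and a log):

```r
res <- run_pipeline(pipeline_config(sim = sim_config(), seed = 1))
res$regions
```

## Package tour

| Area | Functions |
|---|---|
| Data model & IO | `geno_matrix()`, `read_vcf()`, `write_vcf()`, `read_sample_meta()`, `count_genotypes()`, `alt_allele_freq()`, `maf()` |
| Site filters | `filter_sites()` and the individual `filter_*()` steps, `filter_report()` |
| Discovery | `segregation_criterion()`, `find_sex_linked()`, `orientation_sweep()` |
| Genetic sexing | `inbreeding_f()`, `classify_cohort()` (+ `tidy()`, `glance()`, `autoplot()`) |
| Association | `fisher_exact_2x3()`, `scan_sex_association()`, `call_regions()`, `summarize_regions()`, `discovery_rate()` |
| Simulation | `sim_config()`, `simulate_cohort()`, `write_truth()` |
| Long reads | `make_end_pairs()`, `end_pairs_file()` |
| Orchestration | `pipeline_config()`, `run_pipeline()` |

See `vignettes/sexscan-methods.Rmd` for the statistical model, the
simulator's assumptions, and the package's design choices.
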