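# hlapopgen

Population genetics of HLA-A, -B and -DRB1 from marrow-donor registry
genotypes.

Marrow-donor registries type tens of thousands of volunteers at HLA-A, -B
and -DRB1, usually at first-field (antigen-group) resolution with the
B14/B15/B40 families subdivided into serological splits. `hlapopgen`
implements the full statistical workup such registries publish, for anyone
analysing their own cohort or re-analysing published summary tables:

* **Nomenclature** — consolidation of full-resolution allele names to the
  first-field category system, with a user-extensible serological split map
  for B14/B15/B40 (`normalize_allele()`, `hla_serology_map()`), and
  readers/writers for genotype, frequency, haplotype and distance tables.
* **Allele statistics** — direct-counting allele frequencies
  (`allele_frequencies()`), Hardy-Weinberg equilibrium tests over genotype
  classes with rare-category pooling, by chi-square or Monte-Carlo
  permutation (`hwe_test()`), and sample composition summaries.
* **Haplotypes** — maximum-likelihood three-locus haplotype frequencies
  from unphased genotypes by expectation-maximization under random mating
  (`em_haplotype_frequencies()`), with filtering, ranking and
  frequency-band summaries. For a donor heterozygous at *h* loci the EM
  weighs all 2^(h−1) compatible diplotypes by *f*(h₁)·*f*(h₂) (doubled for
  heterozygous resolutions) and sets each frequency to its expected copy
  count over 2N.
* **Linkage disequilibrium** — the raw three-locus disequilibrium
  Δ = HF(a,b,d) − p(a)·p(b)·p(d) per haplotype (`three_locus_delta()`).
* **Population distances** — Nei's standard genetic distance
  D = −ln(J_XY / √(J_X·J_Y)) with locus-averaged identities
  (`nei_standard_distance()`, `distance_matrix()`) and a deterministic
  Saitou–Nei neighbor-joining implementation with Newick output
  (`neighbor_joining()`).
* **Simulation** — a seeded registry-genotype generator with known
  haplotype truth (`sample_genotypes()`), so every stage is testable
  end to end, and `run_pipeline()` to drive the whole analysis from one
  YAML configuration.

The package ships transcriptions of a published Liaoning registry dataset
(21,918 donors, six ethnic groups) as validation fixtures:
`liaoning_fixtures()` returns the sample composition, the per-group allele
frequencies and the 50 most frequent Han haplotypes with their LD values.

Everything is tidyverse-native: functions take a data frame first, return
tibbles, and fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(hlapopgen)
library(dplyr)

fx <- liaoning_fixtures()

# simulate a registry-like sample from the 20 most frequent Han haplotypes
truth <- filter(fx$haplotypes, rank <= 20) |> select(A, B, DRB1, frequency)
genotypes <- sample_genotypes(truth, n = 2000, population = "Han", seed = 1)

hwe_test(genotypes, loci = "A")[, 1:4]
#> # A tibble: 1 × 4
#>   locus  chi2    df p_value
#>   <chr> <dbl> <dbl>   <dbl>
#> 1 A      12.8    21   0.915

fit <- em_haplotype_frequencies(genotypes, tol = 1e-7)
glance(fit)
#> # A tibble: 1 × 5
#>       n n_haplotypes iterations converged log_likelihood
#>   <int>        <int>      <dbl> <lgl>              <dbl>
#> 1  2000          352         10 TRUE              -9695.
tidy(fit) |> head(3)
#> # A tibble: 3 × 4
#>   A     B     DRB1    frequency
#>   <chr> <chr> <chr>       <dbl>
#> 1 A*30  B*13  DRB1*07    0.226
#> 2 A*02  B*46  DRB1*09    0.0993
#> 3 A*02  B*13  DRB1*12    0.0790
```

The simulated cohort is in Hardy-Weinberg equilibrium (p = 0.92), and EM
recovers the generating haplotypes: `A*30-B*13-DRB1*07` is estimated at
0.226 against a generator value of 0.215 (the top-20 truth renormalized).

On the published tables themselves:

```r
han <- filter(fx$allele_frequencies, population == "Han")
three_locus_delta(fx$haplotypes, han) |> head(3)
#> # A tibble: 3 × 5
#>   A     B     DRB1        hf  delta
#>   <chr> <chr> <chr>    <dbl>  <dbl>
#> 1 A*30  B*13  DRB1*07 0.0488 0.0478
#> 2 A*02  B*46  DRB1*09 0.0238 0.0207
#> 3 A*02  B*13  DRB1*12 0.0161 0.0113

d <- distance_matrix(fx$allele_frequencies)
tidy(d) |> head(3)
#> # A tibble: 3 × 3
#>   item1  item2  distance
#>   <chr>  <chr>     <dbl>
#> 1 Manchu Han     0.00210
#> 2 Mongol Manchu  0.0156
#> 3 Mongol Han     0.0164

tree <- neighbor_joining(d)   # an ape::phylo; plot() or write_newick() it
```

The strongest haplotype, `A*30-B*13-DRB1*07`, sits 4.78 percentage points
above its linkage-equilibrium expectation, and the Manchu group is by far
the closest to the Han (D = 0.0021) — both matching the published analysis.
A full pipeline (frequencies, HWE, EM, LD, distances, tree, JSON run
report) runs from one configuration via `run_pipeline()`; see
`inst/scripts/hla-popgen.R` for a command-line wrapper.

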