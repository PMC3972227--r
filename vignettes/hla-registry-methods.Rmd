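---
title: "Methods: HLA registry population genetics with hlapopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA registry population genetics with hlapopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlapopgen)
library(dplyr)
```

`hlapopgen` implements the standard statistical workup of an HLA typing
registry — the kind of analysis marrow-donor programs publish when they
summarise tens of thousands of volunteers typed at HLA-A, -B and -DRB1.
This vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions that were genuinely open.

## Allele categories and nomenclature

Registry datasets of the SSP/SSO typing era are reported at *first-field*
(antigen-group) resolution: `A*02`, `DRB1*09`. Three HLA-B families are the
exception — B14, B15 and B40 are serologically heterogeneous, so summary
tables subdivide them into their serological splits (`B*15(62)`, `B*15(75)`,
`B*40(60)`, ...). `normalize_allele()` reproduces this consolidation:

* any full- or intermediate-resolution designation outside B14/B15/B40 is
  truncated to its first field;
* a B14/B15/B40 allele is looked up in the serological split map *before*
  truncation, and an allele missing from the map is an error — truncating
  `B*40:01` to `B*40` would silently merge categories that registry tables
  keep apart.

The shipped map (`hla_serology_map()`) is a curated subset of the WHO
serologic equivalents covering the common two-field alleles of these
families; it is deliberately user-extensible because serological
assignments are reference knowledge, not something this package defines.

Two nomenclature details deserve a note. First, a redundant split such as
`B*51(51)` — occasionally seen in legacy tables — canonicalizes to `B*51`,
*except* inside the three split families: there `B*40(40)` names the broad
B40 serological antigen, a category distinct from the unresolved group
`B*40`, and both can appear in one table. Second, the literal category
`"Unknown"` (used by registries for untypeable results, present in the
packaged Han column at 0.002%) is retained as a first-class category and
participates in frequency sums and distance computations like any allele;
whether the original analysis carried it downstream is not documentable, but
at 2 × 10⁻⁵ its effect is far below every tolerance used here.

## Allele frequencies and Hardy-Weinberg testing

With codominant typing every chromosome is observed, so allele frequencies
are estimated by *direct counting*: the frequency of category $c$ is its
count among the $2N$ allele slots divided by $2N$. No model enters; the
estimates sum to one exactly.

`hwe_test()` checks Hardy-Weinberg equilibrium with a chi-square over
*genotype classes*: for $k$ allele categories there are $k(k+1)/2$
unordered classes with expected counts $N p_i^2$ (homozygous) and
$2 N p_i p_j$ (heterozygous). Categories whose expected allele-copy count
$2 N p_i$ falls below `min_expected` (default 5 copies, the classic
validity rule) are pooled, rarest first, into one `other` category, and the
degrees of freedom are $k(k-1)/2$ for the $k$ post-pooling categories — the
multiallelic HWE convention. Because highly polymorphic loci still leave
many sparse heterozygote cells, a permutation alternative is provided:
`method = "monte_carlo_exact"` shuffles the $2N$ observed allele copies into
random pairs and reports the empirical tail probability of the same
statistic. The chi-square remains the default because it is the method
summary tables conventionally report, and at registry-scale $N$ with
pooling it holds its nominal size (the test suite verifies a rejection rate
of about 0.05 on data simulated under HWE at $N = 500$).

## EM haplotype frequencies

Three-locus haplotype frequencies cannot be counted from unphased
genotypes: a donor heterozygous at $h$ loci is compatible with $2^{h-1}$
unordered haplotype pairs. `em_haplotype_frequencies()` computes the
maximum-likelihood frequencies under random mating by
expectation-maximization:

* **E-step** — each compatible diplotype $(h_1, h_2)$ of a donor receives
  weight proportional to $f(h_1) f(h_2)$, doubled when $h_1 \neq h_2$ (the
  heterozygote multiplicity required for a Hardy-Weinberg-consistent
  likelihood);
* **M-step** — $f(h)$ becomes the expected number of copies of $h$ divided
  by $2N$.

Only haplotypes compatible with at least one observed genotype are carried;
all others have MLE zero, so this support restriction changes nothing while
keeping the state space manageable. Identical multi-locus genotypes are
collapsed into weighted classes, which makes the per-iteration cost depend
on the number of distinct genotypes rather than $N$.

Numerical choices: iteration stops when the largest absolute frequency
change drops below `tol` (default $10^{-7}$, which stabilises estimates to
well past the 4-decimal print precision of published haplotype tables) or
after `max_iter = 1000` iterations; the log-likelihood trace is returned and
asserted non-decreasing in the test suite. The default initialization is
the linkage-equilibrium product of single-locus frequencies over the
support — the documented default behaviour of the standard EM phasing tools
— with `uniform` and `random` alternatives and optional random restarts
(best final likelihood wins) for multimodality checks. Two fixed points are
worth knowing: a dataset with no phase ambiguity converges to direct
haplotype counting immediately, and a single doubly-heterozygous donor
under uniform initialization sits at the symmetric stationary point with
all four haplotypes at 0.25.

A useful exactness property of the M-step: summing the estimated haplotype
frequencies over two loci reproduces the direct-counting allele frequencies
of the third locus. The suite checks this to $10^{-6}$, and the
`delta_closure_check()` diagnostic exploits the same identity.

## Linkage disequilibrium

For each haplotype $(a, b, d)$ the package reports the raw global
three-locus disequilibrium

$$\Delta = \mathrm{HF}(a,b,d) - p_A(a)\, p_B(b)\, p_{DRB1}(d),$$

the excess of the haplotype's frequency over its linkage-equilibrium
expectation. This choice — rather than a normalized $D'$ — is forced by
back-computation: the LD column of the packaged 50-haplotype table equals
$\mathrm{HF} - p_A p_B p_{DRB1}$ exactly (to the printed 4 decimals on the
percent scale) for 47 of its 50 rows, and no normalized variant does.
$\Delta$ is bounded by $-\min(p_A p_B p_D,\; 1-\mathrm{HF}) \le \Delta \le
\mathrm{HF}$, far inside the nominal $[-1, 1]$ range. Of the three rows that
do not reproduce, each is arithmetically inconsistent with its own printed
haplotype frequency under any rounding, so they are documented as source
misprints rather than absorbed into a looser tolerance.

## Nei distance and neighbor joining

`nei_standard_distance()` implements Nei's (1972) standard genetic
distance. Per locus, the identities $j_X = \sum_i x_i^2$,
$j_Y = \sum_i y_i^2$ and $j_{XY} = \sum_i x_i y_i$ are computed over the
union of allele categories; the three are averaged arithmetically across
loci; and

$$D = -\ln \frac{J_{XY}}{\sqrt{J_X J_Y}}.$$

The standard $D$ was selected (over DA and other variants) because it
reproduces the published pairwise values from the packaged frequency table:
Han–Manchu computes to 0.002095 against a printed 0.002084 and Han–Mongol
to 0.016401 against 0.015929 — inside a ±0.0005 print-rounding tolerance —
and the full Han-to-X ranking (Manchu < Mongol < Hui < Korean < Xibe) is
reproduced. The DA (1983) distance remains available behind
`variant = "da"` for sensitivity checks. Frequencies are used as given by
default; `renormalize = TRUE` first rescales each locus column to sum to
one, which matters only when inputs come from a rounded printed table (it
shifts these distances by under $10^{-5}$). One published value resists
reproduction: Han–Xibe computes to 0.1042 against a printed 0.1070 under
every variant tried (raw, renormalized, split-collapsed), suggesting the
original was computed from unrounded counts or a slightly different input
vector; the package reports the honestly computed value.

`neighbor_joining()` is a direct implementation of the Saitou–Nei
agglomeration: join the pair minimizing
$Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$, attach branch lengths by the split
formula, shrink the matrix, and close the final three nodes out exactly.
Ties in $Q$ break towards the label-lexicographically smallest pair, so
input order cannot change the result beyond isomorphism. Negative branch
lengths — possible for non-additive input — are kept as computed (both
conventions exist; clamping to zero is available via `clamp_negative`).
The algorithm recovers any additive distance matrix exactly, which the test
suite verifies against 200 random trees of 4–10 taxa, and agrees with
`ape::nj()` as an independent cross-check. Trees are returned as `ape`
`phylo` objects and serialized as unrooted Newick; no bootstrap is
computed.

## The synthetic genotype generator

`sample_genotypes()` emulates a registry sample under the same model the
estimators assume: $2n$ haplotypes drawn i.i.d. from a known frequency
vector (random mating, linkage equilibrium *between* an individual's two
haplotypes — within-haplotype LD is carried entirely by the generator
frequencies), paired into diploid donors, phase discarded. Sampling is
inverse-CDF over the descending-sorted haplotype list so that a fixed seed
gives a bit-identical dataset on any platform. The optional `noise_floor`
diverts a chosen probability mass to rare haplotypes built by permuting
alleles across loci of the truth set — a stress test for frequency filters
that invents no new alleles.

The default truth used throughout the tests is the top-20 haplotype block
of the packaged Han table, renormalized to sum to one. Test problem sizes
were chosen to keep the full suite under a minute while leaving sampling
error well below the tolerances checked: $N = 2000$ donors (20 seeds) for
EM recovery, $N = 500$ (1000 replicates) for HWE calibration, $N = 50{,}000$
for generator-marginal convergence.

What passing tests on this generator do **not** show: real registries have
typing ambiguity and error, missing loci, population substructure and
deviations from random mating — none of which the generator produces. The
generator validates the *estimators under their own assumptions* (and the
pipeline's plumbing), not robustness to violations of those assumptions.

At $N = 2000$ the expected total-variation distance between even a
phase-observing oracle's counts and the generating 20-haplotype
distribution is about 0.025 (multinomial noise over 4000 draws); the EM
estimate attains this floor almost exactly, which is the strongest
recovery statement the design admits.

## Degenerate inputs and edge behaviour

Empty datasets, duplicated sample identifiers, empty cells, unknown
population labels, negative frequencies and unparseable categories all fail
fast with named errors. A locus left with a single category after pooling
is a degenerate HWE test and errors rather than returning $\chi^2 = 0$ on
zero degrees of freedom. Populations sharing no alleles have genetic
identity zero and raise an infinite-distance error rather than returning
`Inf`. The frequency filter uses $\ge$ (a haplotype exactly at the
threshold is kept) with the threshold always exposed, since published
wording ("higher than") leaves the boundary ambiguous.

## Reproducibility

Every function with any randomness takes an explicit seed (package default
`20140401`); `run_pipeline()` threads one seed through all stages, records
it in `report.json`, and reruns are byte-identical. The packaged registry
tables are checksummed on load.
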