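Package: hlapopgen
Title: Population Genetics of HLA-A, -B and -DRB1 from Registry Genotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workup of HLA typing registries at first-field
    (antigen-group) resolution: allele-name consolidation with serological
    splits for the B14/B15/B40 families, direct-counting allele frequencies,
    Hardy-Weinberg equilibrium chi-square and Monte-Carlo tests, EM
    estimation of three-locus haplotype frequencies from unphased
    genotypes, three-locus linkage disequilibrium, Nei genetic distances
    between populations and neighbor-joining phylogeny with Newick output.
    Ships transcriptions of a published Liaoning registry dataset for
    validation and a seeded genotype simulator with known haplotype truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
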