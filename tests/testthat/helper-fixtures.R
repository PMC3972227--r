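# shared helpers: packaged tables and small in-code datasets

fx <- liaoning_fixtures()

han_truth <- function(n_top = 20) {
  dplyr::filter(fx$haplotypes, rank <= n_top)[, c("A", "B", "DRB1", "frequency")]
}

han_freqs <- function() {
  dplyr::filter(fx$allele_frequencies, population == "Han")
}

# a tiny genotype tibble built directly (already-normalized categories)
make_genotypes <- function(A1, A2, B1 = "B*07", B2 = "B*07",
                           D1 = "DRB1*04", D2 = "DRB1*04",
                           population = "test") {
  n <- length(A1)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = rep_len(population, n),
    A_1 = pmin(A1, A2), A_2 = pmax(A1, A2),
    B_1 = pmin(rep_len(B1, n), rep_len(B2, n)),
    B_2 = pmax(rep_len(B1, n), rep_len(B2, n)),
    DRB1_1 = pmin(rep_len(D1, n), rep_len(D2, n)),
    DRB1_2 = pmax(rep_len(D1, n), rep_len(D2, n))
  )
}

# genotype counts (n_aa, n_ab, n_bb) at locus A for a biallelic HWE test
biallelic_genotypes <- function(n_aa, n_ab, n_bb) {
  make_genotypes(
    A1 = c(rep("A*01", n_aa), rep("A*01", n_ab), rep("A*02", n_bb)),
    A2 = c(rep("A*01", n_aa), rep("A*02", n_ab), rep("A*02", n_bb))
  )
}

tv_distance <- function(est, truth) {
  m <- dplyr::full_join(est, truth, by = c("A", "B", "DRB1"),
                        suffix = c(".e", ".t"))
  m[is.na(m)] <- 0
  sum(abs(m$frequency.e - m$frequency.t)) / 2
}

write_genotype_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
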