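# Registry-like genotype simulation with known haplotype truth, and the
# packaged Liaoning summary-table fixtures.

#' Simulate unphased registry genotypes from haplotype frequencies
#'
#' Draws `2 n` haplotypes i.i.d. from the (renormalized) truth distribution
#' — the random-mating model under which both the Hardy-Weinberg test and
#' the EM likelihood are exact — pairs them into `n` diploid donors, and
#' discards phase by recording only the unordered allele pair per locus.
#' Sampling is inverse-CDF over the haplotype list sorted by descending
#' frequency (ties lexicographic), so a given seed yields a bit-identical
#' dataset on any platform.
#'
#' An optional `noise_floor` diverts that much total probability mass to a
#' uniform cloud of extra rare haplotypes built by permuting alleles across
#' loci of the truth set — a stress test for downstream frequency filters
#' that invents no new alleles.
#'
#' @param truth Haplotype tibble (`A`, `B`, `DRB1`, `frequency`); the
#'   frequencies are renormalized to sum to 1 before sampling.
#' @param n Number of diploid individuals.
#' @param population Population label written on every record.
#' @param seed Integer seed; every random draw flows from it.
#' @param noise_floor Total probability mass assigned to the rare-haplotype
#'   cloud (default 0 = off).
#' @return A genotype tibble with columns `sample_id`, `population`, and
#'   per-locus sorted allele pairs, plus the attribute `truth` holding the
#'   sampling distribution actually used.
#' @export
#' @examples
#' truth <- liaoning_fixtures()$haplotypes[1:3, c("A", "B", "DRB1", "frequency")]
#' sample_genotypes(truth, n = 5, seed = 42)
sample_genotypes <- function(truth, n, population = "sim", seed = 20140401,
                             noise_floor = 0) {
  if (nrow(truth) == 0) abort("Empty generator haplotype table.")
  if (n < 1) abort("`n` must be at least 1.")
  if (noise_floor < 0 || noise_floor >= 1) abort("`noise_floor` must be in [0, 1).")
  truth <- truth |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$A, .data$B, .data$DRB1) |>
    dplyr::mutate(frequency = .data$frequency / sum(.data$frequency))
  if (noise_floor > 0) {
    cloud <- tibble::tibble(
      A = truth$A,
      B = truth$B[c(seq_len(nrow(truth))[-1], 1)],
      DRB1 = truth$DRB1[c(seq_len(nrow(truth))[-(1:2)], 1, 2)]
    ) |>
      dplyr::anti_join(truth, by = hla_loci()) |>
      dplyr::distinct()
    if (nrow(cloud) > 0) {
      cloud$frequency <- noise_floor / nrow(cloud)
      truth$frequency <- truth$frequency * (1 - noise_floor)
      truth <- dplyr::bind_rows(truth, cloud)
    }
  }
  cum <- cumsum(truth$frequency)
  cum[length(cum)] <- 1  # guard against accumulated rounding
  idx <- withr::with_seed(seed, findInterval(runif(2 * n), cum, left.open = TRUE) + 1L)
  h1 <- truth[idx[seq_len(n)], hla_loci()]
  h2 <- truth[idx[n + seq_len(n)], hla_loci()]
  g <- tibble::tibble(
    sample_id = sprintf("S%06d", seq_len(n)),
    population = population,
    A_1 = h1$A, A_2 = h2$A,
    B_1 = h1$B, B_2 = h2$B,
    DRB1_1 = h1$DRB1, DRB1_2 = h2$DRB1
  )
  g <- sort_genotype_pairs(g)
  attr(g, "truth") <- truth
  g
}

.fixture_md5 <- c(
  liaoning_table1_composition.tsv = "8667c3d2a1c5554b153b2c13960cc65e",
  liaoning_table2_gene_frequencies.tsv = "c5b5417b1127c2f12d697f4cab21dfe2",
  liaoning_table5_han_haplotypes.tsv = "dbb2f825facf116f9ab2801608a980a6"
)

#' Packaged Liaoning registry summary tables
#'
#' Loads the versioned transcriptions of the published Liaoning registry
#' summary tables that ship with the package: the sample composition by
#' ethnic group, the per-group HLA-A/-B/-DRB1 allele frequencies (six
#' ethnic groups), and the 50 most frequent Han three-locus haplotypes
#' with their frequencies and linkage disequilibrium values. File
#' checksums are verified on load so a corrupted installation fails
#' loudly rather than silently shifting downstream numbers.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{composition}{tibble `population`, `n` (donor counts).}
#'     \item{allele_frequencies}{long tibble `population`, `locus`,
#'       `allele`, `frequency` (proportions).}
#'     \item{haplotypes}{tibble `rank`, `A`, `B`, `DRB1`, `frequency`,
#'       `ld` (proportions), Han population.}
#'   }
#' @export
#' @examples
#' fx <- liaoning_fixtures()
#' sum(fx$composition$n)
liaoning_fixtures <- function() {
  dir <- system.file("extdata", package = "hlapopgen")
  for (f in names(.fixture_md5)) {
    got <- unname(tools::md5sum(file.path(dir, f)))
    if (!identical(got, unname(.fixture_md5[f]))) {
      abort(paste0("Checksum mismatch for packaged fixture ", f,
                   "; reinstall the package."))
    }
  }
  comp <- readr::read_tsv(file.path(dir, "liaoning_table1_composition.tsv"),
                          col_types = "ci")
  haps <- readr::read_tsv(file.path(dir, "liaoning_table5_han_haplotypes.tsv"),
                          col_types = "icccdd")
  list(
    composition = comp,
    allele_frequencies = read_frequency_table(
      file.path(dir, "liaoning_table2_gene_frequencies.tsv")),
    haplotypes = tibble::tibble(
      rank = haps$rank, A = haps$A, B = haps$B, DRB1 = haps$DRB1,
      frequency = haps$HF / 100, ld = haps$LD / 100, population = "Han")
  )
}
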