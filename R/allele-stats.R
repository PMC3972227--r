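# Direct-counting allele frequencies, Hardy-Weinberg chi-square testing and
# sample-composition summaries.

subset_population <- function(genotypes, population) {
  if (is.null(population)) return(genotypes)
  keep <- genotypes$population %in% population
  if (!any(keep)) {
    abort(paste0("No records with population label \"",
                 paste(population, collapse = ", "), "\"."))
  }
  genotypes[keep, , drop = FALSE]
}

#' Allele frequencies by direct counting
#'
#' For each population and locus, counts every allele over the `2N` allele
#' slots and divides by `2N`. This is the direct counting estimator: with
#' codominant typing every chromosome is observed, so no model is needed.
#'
#' @param genotypes Genotype tibble (see [read_genotype_table()]).
#' @param population Population label(s) to include, or `NULL` (default) for
#'   all populations in the data.
#' @param loci Loci to tabulate (default all three).
#' @return A tibble with columns `population`, `locus`, `allele`,
#'   `frequency` (proportion, summing to 1 per population and locus) and
#'   `n` (number of donors).
#' @export
#' @examples
#' truth <- liaoning_fixtures()$haplotypes[1:5, c("A", "B", "DRB1", "frequency")]
#' g <- sample_genotypes(truth, n = 100, seed = 1)
#' allele_frequencies(g)
allele_frequencies <- function(genotypes, population = NULL, loci = hla_loci()) {
  genotypes <- subset_population(genotypes, population)
  purrr::map_dfr(loci, function(locus) {
    genotypes |>
      dplyr::select("population", dplyr::all_of(paste0(locus, c("_1", "_2")))) |>
      tidyr::pivot_longer(-"population", values_to = "allele") |>
      dplyr::count(.data$population, .data$allele) |>
      dplyr::group_by(.data$population) |>
      dplyr::mutate(locus = locus,
                    frequency = .data$n / sum(.data$n),
                    n = as.integer(sum(.data$n) / 2)) |>
      dplyr::ungroup() |>
      dplyr::select("population", "locus", "allele", "frequency", "n")
  }) |>
    dplyr::arrange(.data$population, factor(.data$locus, hla_loci()), .data$allele)
}

#' Population composition of a genotype dataset
#'
#' @param genotypes Genotype tibble.
#' @return A tibble with `population`, `n` and `percent` (of the total
#'   sample, summing to 100 up to rounding), sorted by decreasing count.
#' @export
population_composition <- function(genotypes) {
  if (nrow(genotypes) == 0) abort("Empty genotype dataset.")
  genotypes |>
    dplyr::count(.data$population) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

# expected genotype-class counts under HWE, indexed by pair code
hwe_expected <- function(n, p, k) {
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  expct <- numeric(k * (k + 1) / 2)
  expct[pair_to_code(idx[, 2], idx[, 1], k)] <-
    ifelse(idx[, 1] == idx[, 2], n * p[idx[, 1]]^2,
           2 * n * p[idx[, 1]] * p[idx[, 2]])
  expct
}

# chi-square statistic over all k(k+1)/2 genotype classes
hwe_chi2_stat <- function(pair_code, expct) {
  obs <- tabulate(pair_code, nbins = length(expct))
  sum((obs - expct)^2 / expct)
}

# map an unordered pair (i, j) to a 1-based class index: row lo holds the
# k - lo + 1 classes (lo, lo), (lo, lo+1), ..., (lo, k)
pair_to_code <- function(i, j, k) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * k - (lo - 1) * lo / 2 + (lo - 1) + hi - lo + 1
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests each locus for deviation from Hardy-Weinberg genotype proportions
#' with a chi-square test over genotype classes: expected counts are
#' `N p_i^2` for homozygotes and `2 N p_i p_j` for heterozygotes, with
#' allele proportions `p` from direct counting. Allele categories whose
#' expected allele-copy count (`2 N p_i`) falls below `min_expected` are
#' pooled, rarest first, into a single `"other"` category before testing;
#' degrees of freedom are `k (k - 1) / 2` for `k` post-pooling categories.
#' `method = "monte_carlo_exact"` instead shuffles the `2N` observed allele
#' copies into random pairs and reports the empirical tail probability of
#' the chi-square statistic, which remains valid when expected genotype
#' counts are small.
#'
#' @param genotypes Genotype tibble.
#' @param population Population label(s), or `NULL` for all records pooled.
#' @param loci Loci to test (default all three).
#' @param min_expected Minimum expected allele copies before pooling
#'   (default 5).
#' @param method `"chi2_pooled"` (default) or `"monte_carlo_exact"`.
#' @param n_perm Permutations for the Monte-Carlo method.
#' @param seed Seed for the Monte-Carlo method.
#' @return A tibble with one row per locus: `locus`, `chi2`, `df`,
#'   `p_value`, `method`, `n`, and the list-column `pooled_categories`.
#' @export
hwe_test <- function(genotypes, population = NULL, loci = hla_loci(),
                     min_expected = 5, method = c("chi2_pooled", "monte_carlo_exact"),
                     n_perm = 2000, seed = 20140401) {
  method <- match.arg(method)
  genotypes <- subset_population(genotypes, population)
  n <- nrow(genotypes)
  purrr::map_dfr(loci, function(locus) {
    a1 <- genotypes[[paste0(locus, "_1")]]
    a2 <- genotypes[[paste0(locus, "_2")]]
    counts <- sort(table(c(a1, a2)))  # ascending: pool rarest first
    pooled <- names(counts)[counts < min_expected]
    lab <- function(x) ifelse(x %in% pooled, "other", x)
    cats <- sort(unique(lab(names(counts))))
    k <- length(cats)
    if (k < 2) {
      abort(paste0("Degenerate HWE test at locus ", locus,
                   ": a single allele category remains after pooling."))
    }
    i1 <- match(lab(a1), cats); i2 <- match(lab(a2), cats)
    p <- tabulate(c(i1, i2), nbins = k) / (2 * n)
    expct <- hwe_expected(n, p, k)
    chi2 <- hwe_chi2_stat(pair_to_code(i1, i2, k), expct)
    df <- k * (k - 1) / 2
    if (method == "chi2_pooled") {
      p_value <- pchisq(chi2, df, lower.tail = FALSE)
    } else {
      copies <- c(i1, i2)
      p_value <- withr::with_seed(seed, {
        perm_stats <- vapply(seq_len(n_perm), function(b) {
          s <- sample(copies)
          hwe_chi2_stat(pair_to_code(s[seq_len(n)], s[n + seq_len(n)], k), expct)
        }, numeric(1))
        (1 + sum(perm_stats >= chi2 - 1e-12)) / (n_perm + 1)
      })
    }
    tibble::tibble(locus = locus, chi2 = chi2, df = df, p_value = p_value,
                   method = method, n = n, pooled_categories = list(pooled))
  })
}
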