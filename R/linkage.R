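# Three-locus linkage disequilibrium: the raw global disequilibrium of a
# haplotype, Delta = HF - p(A) p(B) p(DRB1).

# named lookup vectors per locus from a long frequency tibble (one population)
freq_lookups <- function(freqs) {
  pops <- unique(freqs$population)
  if (length(pops) > 1) {
    abort("Frequency table must contain a single population; filter first.")
  }
  lapply(setNames(hla_loci(), hla_loci()), function(l) {
    f <- freqs[freqs$locus == l, ]
    setNames(f$frequency, f$allele)
  })
}

#' Three-locus linkage disequilibrium for each haplotype
#'
#' For each haplotype `(a, b, d)` computes the raw three-locus
#' disequilibrium `delta = HF - p(a) p(b) p(d)`, the excess of the
#' haplotype's frequency over its linkage-equilibrium expectation. Positive
#' values indicate alleles travelling together more often than chance.
#' Every allele of every haplotype must be present in the frequency table
#' (possibly at frequency zero); a missing allele is an inconsistency
#' between the two inputs and errors.
#'
#' @param haplotypes Haplotype tibble (`A`, `B`, `DRB1`, `frequency`).
#' @param freqs Long allele-frequency tibble for the same, single
#'   population (`population`, `locus`, `allele`, `frequency`).
#' @return A tibble in input order with columns `A`, `B`, `DRB1`, `hf` and
#'   `delta` (both proportions).
#' @export
#' @examples
#' fx <- liaoning_fixtures()
#' han <- dplyr::filter(fx$allele_frequencies, population == "Han")
#' three_locus_delta(fx$haplotypes, han)[1, ]
three_locus_delta <- function(haplotypes, freqs) {
  lk <- freq_lookups(freqs)
  pa <- lk$A[haplotypes$A]
  pb <- lk$B[haplotypes$B]
  pd <- lk$DRB1[haplotypes$DRB1]
  miss <- is.na(pa) | is.na(pb) | is.na(pd)
  if (any(miss)) {
    bad <- unique(unlist(lapply(which(miss), function(i) {
      h <- haplotypes[i, ]
      c(h$A, h$B, h$DRB1)[c(is.na(pa[i]), is.na(pb[i]), is.na(pd[i]))]
    })))
    abort(paste0("Allele(s) absent from the frequency table: ",
                 paste(bad, collapse = ", ")), class = "hla_inconsistent_input")
  }
  tibble::tibble(A = haplotypes$A, B = haplotypes$B, DRB1 = haplotypes$DRB1,
                 hf = haplotypes$frequency,
                 delta = unname(haplotypes$frequency - pa * pb * pd))
}

#' Closure diagnostic: sum of delta over the complete haplotype space
#'
#' Over the complete haplotype space implied by the allele categories, the
#' deltas of all haplotypes (taking HF = 0 for haplotypes absent from the
#' table) sum to `sum(HF) - prod_l(sum_i p_li)`, which is analytically zero
#' when the haplotype table is complete (sums to 1) and each locus's
#' frequencies sum to 1. Deviations diagnose inconsistent inputs.
#'
#' @inheritParams three_locus_delta
#' @return The sum of delta over the complete space (a single number).
#' @export
delta_closure_check <- function(haplotypes, freqs) {
  lk <- freq_lookups(freqs)
  sum(haplotypes$frequency) - prod(vapply(lk, sum, numeric(1)))
}
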