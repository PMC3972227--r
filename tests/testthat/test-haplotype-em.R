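test_that("diplotype enumeration yields 2^(h-1) unordered pairs", {
  hom <- list(A_1 = "A*01", A_2 = "A*01", B_1 = "B*07", B_2 = "B*07",
              DRB1_1 = "DRB1*04", DRB1_2 = "DRB1*04")
  expect_equal(nrow(enumerate_diplotypes(hom)), 1)

  het3 <- list(A_1 = "A*01", A_2 = "A*02", B_1 = "B*07", B_2 = "B*08",
               DRB1_1 = "DRB1*04", DRB1_2 = "DRB1*07")
  d3 <- enumerate_diplotypes(het3)
  expect_equal(nrow(d3), 4)
  expect_equal(nrow(dplyr::distinct(d3)), 4)
  # every pair reproduces the genotype locus-wise
  for (i in 1:4) {
    alleles <- strsplit(c(d3$hap1[i], d3$hap2[i]), "~", fixed = TRUE)
    expect_setequal(c(alleles[[1]][1], alleles[[2]][1]), c("A*01", "A*02"))
    expect_setequal(c(alleles[[1]][2], alleles[[2]][2]), c("B*07", "B*08"))
    expect_setequal(c(alleles[[1]][3], alleles[[2]][3]), c("DRB1*04", "DRB1*07"))
  }

  het1 <- list(A_1 = "A*01", A_2 = "A*02", B_1 = "B*07", B_2 = "B*07",
               DRB1_1 = "DRB1*04", DRB1_2 = "DRB1*04")
  expect_equal(nrow(enumerate_diplotypes(het1)), 1)
})

test_that("EM equals direct haplotype counting when there is no phase ambiguity", {
  # fully homozygous donors: 6 of one haplotype, 4 of another
  g <- make_genotypes(A1 = c(rep("A*01", 6), rep("A*02", 4)),
                      A2 = c(rep("A*01", 6), rep("A*02", 4)),
                      B1 = c(rep("B*07", 6), rep("B*08", 4)),
                      B2 = c(rep("B*07", 6), rep("B*08", 4)))
  fit <- em_haplotype_frequencies(g)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2)
  est <- tidy(fit)
  expect_equal(est$frequency, c(0.6, 0.4))
  expect_equal(est$A, c("A*01", "A*02"))
})

test_that("a doubly heterozygous singleton under uniform init sits at the symmetric fixed point", {
  g <- make_genotypes(A1 = "A*01", A2 = "A*02", B1 = "B*07", B2 = "B*08")
  fit <- em_haplotype_frequencies(g, init = "uniform")
  est <- tidy(fit)
  expect_equal(nrow(est), 4)
  expect_equal(est$frequency, rep(0.25, 4))
})

test_that("EM log-likelihood never decreases and marginals match direct counting", {
  truth <- han_truth(20)
  for (s in c(2, 9)) {
    g <- sample_genotypes(truth, n = 500, seed = s)
    fit <- em_haplotype_frequencies(g)
    expect_true(all(diff(fit$log_likelihood_trace) > -1e-8))
    expect_equal(sum(tidy(fit)$frequency), 1, tolerance = 1e-9)
    est <- tidy(fit)
    af <- allele_frequencies(g)
    for (l in hla_loci()) {
      em_marg <- tapply(est$frequency, est[[l]], sum)
      dc <- af[af$locus == l, ]
      expect_equal(as.numeric(em_marg[dc$allele]), dc$frequency, tolerance = 1e-6)
    }
  }
})

test_that("EM recovers generator frequencies up to the sampling noise floor", {
  # at N = 2000 the phase-observing oracle's TV to truth averages ~0.025
  # (multinomial noise over 20 cells at 4000 draws); EM must track it
  truth <- han_truth(20)
  g <- sample_genotypes(truth, n = 2000, seed = 1)
  fit <- em_haplotype_frequencies(g, tol = 1e-7)
  est <- tidy(fit)
  expect_lt(tv_distance(est, attr(g, "truth")), 0.04)
  # no generating haplotype of frequency >= 0.01 is lost
  big <- dplyr::filter(attr(g, "truth"), frequency >= 0.01)
  found <- dplyr::semi_join(dplyr::filter(est, frequency > 0), big,
                            by = c("A", "B", "DRB1"))
  expect_equal(nrow(found), nrow(big))
})

test_that("EM is invariant to record order and restarts do not degrade the fit", {
  truth <- han_truth(10)
  g <- sample_genotypes(truth, n = 300, seed = 4)
  f1 <- em_haplotype_frequencies(g)
  f2 <- em_haplotype_frequencies(g[rev(seq_len(nrow(g))), ])
  by_hap <- function(x) dplyr::arrange(tidy(x), A, B, DRB1)
  expect_equal(by_hap(f1)$frequency, by_hap(f2)$frequency, tolerance = 1e-8)
  expect_equal(by_hap(f1)[, hla_loci()], by_hap(f2)[, hla_loci()])
  f3 <- em_haplotype_frequencies(g, restarts = 3, seed = 99)
  expect_gte(max(f3$log_likelihood_trace), max(f1$log_likelihood_trace) - 1e-6)
  expect_error(em_haplotype_frequencies(g, tol = -1), "positive")
})

test_that("filtering and ranking reproduce the published frequent-haplotype counts", {
  haps <- fx$haplotypes
  expect_equal(nrow(filter_and_rank(haps, min_freq = 0.005)), 25)
  top1 <- filter_and_rank(haps, top_n = 1)
  expect_equal(unlist(top1[1, c("A", "B", "DRB1")], use.names = FALSE),
               c("A*30", "B*13", "DRB1*07"))
  expect_equal(top1$frequency, 0.0488)
  expect_equal(nrow(filter_and_rank(haps, min_freq = 0)), nrow(haps))
  expect_error(filter_and_rank(haps, min_freq = -0.1), "non-negative")
})

test_that("frequency bands count and accumulate like the published distribution table", {
  bands <- frequency_band_summary(fx$haplotypes)
  expect_equal(bands$n_haplotypes[bands$band == ">0.01"], 7)
  expect_equal(sum(bands$n_haplotypes), nrow(fx$haplotypes))
  expect_equal(sum(bands$percent_of_total), 100 * sum(fx$haplotypes$frequency))
  empty <- frequency_band_summary(fx$haplotypes[0, ])
  expect_true(all(empty$n_haplotypes == 0))
  expect_error(frequency_band_summary(fx$haplotypes, band_edges = c(0.001, 0.01)),
               "decreasing")
})
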