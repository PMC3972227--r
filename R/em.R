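# EM estimation of three-locus haplotype frequencies from unphased
# genotypes, with frequency filtering, ranking and band summaries.

HAP_SEP <- "~"

hap_paste <- function(a, b, d) paste(a, b, d, sep = HAP_SEP)

hap_split <- function(h) {
  parts <- stringr::str_split_fixed(h, stringr::fixed(HAP_SEP), 3)
  tibble::tibble(A = parts[, 1], B = parts[, 2], DRB1 = parts[, 3])
}

#' Enumerate the diplotypes compatible with an unphased genotype
#'
#' A donor heterozygous at `h` of the three loci admits `2^(h-1)` unordered
#' haplotype pairs (one when fully homozygous): each heterozygous locus
#' beyond the first doubles the number of phase resolutions. This support
#' set is what the EM algorithm sums over.
#'
#' @param genotype A one-row genotype tibble (or named list) with fields
#'   `A_1`, `A_2`, `B_1`, `B_2`, `DRB1_1`, `DRB1_2`.
#' @return A tibble with columns `hap1` and `hap2`, haplotypes written as
#'   `"A*30~B*13~DRB1*07"`; one row per unordered pair.
#' @export
#' @examples
#' enumerate_diplotypes(list(A_1 = "A*01", A_2 = "A*02",
#'                           B_1 = "B*07", B_2 = "B*08",
#'                           DRB1_1 = "DRB1*04", DRB1_2 = "DRB1*04"))
enumerate_diplotypes <- function(genotype) {
  pairs <- lapply(hla_loci(), function(l) {
    sort(c(genotype[[paste0(l, "_1")]][[1]], genotype[[paste0(l, "_2")]][[1]]))
  })
  het <- vapply(pairs, function(p) p[1] != p[2], logical(1))
  het_idx <- which(het)
  # assign, for each het locus, which allele goes to haplotype 1; the first
  # het locus is fixed to break the (h1, h2) <-> (h2, h1) symmetry
  n_free <- max(length(het_idx) - 1, 0)
  combos <- expand.grid(rep(list(1:2), n_free))
  h1 <- h2 <- matrix("", nrow = max(nrow(combos), 1), ncol = 3)
  for (l in 1:3) {
    if (!het[l]) {
      h1[, l] <- pairs[[l]][1]; h2[, l] <- pairs[[l]][1]
    } else if (l == het_idx[1]) {
      h1[, l] <- pairs[[l]][1]; h2[, l] <- pairs[[l]][2]
    } else {
      pick <- combos[[match(l, het_idx) - 1]]
      h1[, l] <- pairs[[l]][pick]
      h2[, l] <- pairs[[l]][3 - pick]
    }
  }
  tibble::tibble(hap1 = hap_paste(h1[, 1], h1[, 2], h1[, 3]),
                 hap2 = hap_paste(h2[, 1], h2[, 2], h2[, 3]))
}

# expand a whole dataset into (genotype class, hap1, hap2) triples over
# unique genotype classes; returns list(pairs, counts, haps)
build_em_support <- function(genotypes) {
  cols <- genotype_columns()[-(1:2)]
  key <- do.call(paste, c(genotypes[cols], sep = "/"))
  classes <- genotypes[!duplicated(key), cols]
  counts <- as.vector(table(key)[do.call(paste, c(classes, sep = "/"))])
  support <- purrr::map_dfr(seq_len(nrow(classes)), function(g) {
    dplyr::mutate(enumerate_diplotypes(classes[g, ]), g = g)
  })
  haps <- sort(unique(c(support$hap1, support$hap2)))
  list(g = support$g,
       h1 = match(support$hap1, haps),
       h2 = match(support$hap2, haps),
       counts = counts, haps = haps, n = nrow(genotypes))
}

em_initial <- function(sup, genotypes, init, jitter_seed = NULL) {
  nh <- length(sup$haps)
  f <- switch(init,
    uniform = rep(1 / nh, nh),
    marginal = {
      af <- allele_frequencies(dplyr::mutate(genotypes, population = "all"))
      lk <- setNames(af$frequency, paste(af$locus, af$allele, sep = ":"))
      hs <- hap_split(sup$haps)
      f0 <- lk[paste("A", hs$A, sep = ":")] *
            lk[paste("B", hs$B, sep = ":")] *
            lk[paste("DRB1", hs$DRB1, sep = ":")]
      unname(f0 / sum(f0))
    },
    random = {
      f0 <- rgamma(nh, shape = 1)
      f0 / sum(f0)
    })
  if (!is.null(jitter_seed)) {
    f <- f * rgamma(nh, shape = 5)
    f <- f / sum(f)
  }
  f
}

run_em_once <- function(sup, f, tol, max_iter) {
  mult <- ifelse(sup$h1 == sup$h2, 1, 2)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    num <- mult * f[sup$h1] * f[sup$h2]
    gsum <- as.vector(rowsum(num, sup$g))
    trace[iter] <- sum(sup$counts * log(gsum))
    w <- (num / gsum[sup$g]) * sup$counts[sup$g]
    copies <- numeric(length(f))
    agg <- rowsum(c(w, w), c(sup$h1, sup$h2))
    copies[as.integer(rownames(agg))] <- agg[, 1]
    f_new <- copies / (2 * sup$n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # log-likelihood at the returned frequencies
  num <- mult * f[sup$h1] * f[sup$h2]
  trace[iter + 1] <- sum(sup$counts * log(as.vector(rowsum(num, sup$g))))
  list(f = f, trace = trace, iterations = iter, converged = converged)
}

#' EM estimation of three-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from unphased genotypes under
#' random mating (Hardy-Weinberg) via expectation-maximization. The E-step
#' weights each diplotype resolution `(h1, h2)` of a donor proportionally
#' to `f(h1) f(h2)`, doubled for heterozygous resolutions; the M-step sets
#' each haplotype frequency to its expected copy count over `2N`. Only
#' haplotypes compatible with at least one observed genotype carry mass
#' (all others have MLE zero), which keeps the support linear in the data.
#'
#' The log-likelihood is non-decreasing across iterations — an invariant the
#' returned trace lets you audit. Iteration stops when the largest absolute
#' frequency change drops below `tol` or after `max_iter` iterations. With
#' `restarts > 1`, additional runs from randomly perturbed starts are
#' performed and the run with the highest final log-likelihood is returned
#' (the likelihood can be multimodal in principle, though rarely at
#' registry sample sizes).
#'
#' @param genotypes Genotype tibble.
#' @param population Population label(s), or `NULL` for all records.
#' @param tol Convergence tolerance on the max absolute frequency change
#'   (default `1e-7`).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param init `"marginal"` (default; linkage-equilibrium product of
#'   single-locus frequencies over the support), `"uniform"`, or
#'   `"random"`.
#' @param restarts Number of EM runs (default 1).
#' @param seed Seed for random initialization/restarts.
#' @return An object of class `hla_em`; `tidy()` it for the haplotype
#'   frequency tibble (`A`, `B`, `DRB1`, `frequency`, descending),
#'   `glance()` for a one-row run summary, `autoplot()` for the
#'   log-likelihood trace.
#' @export
#' @examples
#' truth <- liaoning_fixtures()$haplotypes[1:5, c("A", "B", "DRB1", "frequency")]
#' g <- sample_genotypes(truth, n = 200, seed = 1)
#' fit <- em_haplotype_frequencies(g)
#' tidy(fit)
#' glance(fit)
em_haplotype_frequencies <- function(genotypes, population = NULL, tol = 1e-7,
                                     max_iter = 1000,
                                     init = c("marginal", "uniform", "random"),
                                     restarts = 1, seed = 20140401) {
  init <- match.arg(init)
  if (tol <= 0 || max_iter <= 0) abort("`tol` and `max_iter` must be positive.")
  genotypes <- subset_population(genotypes, population)
  sup <- build_em_support(genotypes)
  runs <- withr::with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      f0 <- em_initial(sup, genotypes,
                       init = if (r == 1) init else "random",
                       jitter_seed = if (r > 1) r else NULL)
      run_em_once(sup, f0, tol, max_iter)
    })
  })
  best <- runs[[which.max(vapply(runs, function(r) max(r$trace), numeric(1)))]]
  freq <- dplyr::bind_cols(hap_split(sup$haps),
                           tibble::tibble(frequency = best$f)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$A, .data$B, .data$DRB1)
  structure(
    list(frequencies = freq,
         log_likelihood_trace = best$trace,
         iterations = best$iterations,
         converged = best$converged,
         n = sup$n,
         population = population %||% "all",
         tol = tol, init = init, restarts = restarts, seed = seed),
    class = "hla_em")
}

#' @export
print.hla_em <- function(x, ...) {
  cat(sprintf("<hla_em> %d haplotypes from %d donors (%s)\n",
              nrow(x$frequencies), x$n, paste(x$population, collapse = ", ")))
  cat(sprintf("  EM %s after %d iterations; log-likelihood %.4f\n",
              if (x$converged) "converged" else "did NOT converge",
              x$iterations, max(x$log_likelihood_trace)))
  print(head(x$frequencies, 10))
  invisible(x)
}

#' @rdname em_haplotype_frequencies
#' @param x,object An `hla_em` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hla_em <- function(x, ...) x$frequencies

#' @rdname em_haplotype_frequencies
#' @exportS3Method generics::glance
glance.hla_em <- function(x, ...) {
  tibble::tibble(n = x$n, n_haplotypes = nrow(x$frequencies),
                 iterations = x$iterations, converged = x$converged,
                 log_likelihood = max(x$log_likelihood_trace))
}

#' @rdname em_haplotype_frequencies
#' @exportS3Method ggplot2::autoplot
autoplot.hla_em <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$log_likelihood_trace),
                       log_likelihood = object$log_likelihood_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_likelihood)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood",
                  title = "EM log-likelihood trace")
}

#' Filter and rank a haplotype-frequency table
#'
#' Retains haplotypes at or above `min_freq`, sorted by descending
#' frequency with ties broken lexicographically by haplotype code, and
#' optionally truncated to the `top_n` most frequent.
#'
#' @param haplotypes Haplotype tibble (`A`, `B`, `DRB1`, `frequency`).
#' @param min_freq Minimum frequency retained (proportion; default 0).
#' @param top_n Keep only this many rows, or `NULL` for all.
#' @return The filtered, ranked tibble.
#' @export
filter_and_rank <- function(haplotypes, min_freq = 0, top_n = NULL) {
  if (min_freq < 0) abort("`min_freq` must be non-negative.")
  out <- haplotypes |>
    dplyr::filter(.data$frequency >= min_freq) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$A, .data$B, .data$DRB1)
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Haplotype counts and cumulative frequency by frequency band
#'
#' Summarises a haplotype table into descending frequency bands, in the
#' style of a published haplotype-distribution table: the first band is
#' strictly above the first edge, subsequent bands are half-open intervals
#' `(lower, upper]`, and a final band collects everything at or below the
#' last edge.
#'
#' @param haplotypes Haplotype tibble (`A`, `B`, `DRB1`, `frequency`).
#' @param band_edges Strictly decreasing frequency edges (proportions),
#'   default `c(0.01, 0.001, 0.0001)`.
#' @return A tibble with `band`, `n_haplotypes` and `percent_of_total`
#'   (summed frequency in the band, in percent).
#' @export
frequency_band_summary <- function(haplotypes, band_edges = c(0.01, 0.001, 0.0001)) {
  if (is.unsorted(rev(band_edges), strictly = TRUE)) {
    abort("`band_edges` must be strictly decreasing.")
  }
  labels <- c(paste0(">", band_edges[1]),
              if (length(band_edges) > 1)
                paste0(band_edges[-length(band_edges)], "-", band_edges[-1]),
              paste0("<=", band_edges[length(band_edges)]))
  idx <- length(band_edges) + 1 -
    findInterval(haplotypes$frequency, c(rev(band_edges), Inf), left.open = TRUE)
  purrr::map_dfr(seq_along(labels), function(i) {
    f <- haplotypes$frequency[idx == i]
    tibble::tibble(band = labels[i], n_haplotypes = length(f),
                   percent_of_total = 100 * sum(f))
  })
}
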