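# Nei genetic distances between populations and neighbor-joining phylogeny.

new_hla_dist <- function(m) {
  structure(m, class = c("hla_dist", "matrix"))
}

freqs_by_locus <- function(freqs, population, loci, universe) {
  sub <- freqs[freqs$population == population, ]
  lapply(setNames(loci, loci), function(l) {
    f <- sub[sub$locus == l, ]
    v <- setNames(rep(0, length(universe[[l]])), universe[[l]])
    v[f$allele] <- f$frequency
    v
  })
}

nei_from_vectors <- function(xs, ys, renormalize, variant) {
  if (renormalize) {
    xs <- lapply(xs, function(v) v / sum(v))
    ys <- lapply(ys, function(v) v / sum(v))
  }
  if (variant == "da") {
    # Nei et al. (1983) DA: 1 - mean over loci of sum_i sqrt(x_i y_i)
    return(1 - mean(vapply(seq_along(xs), function(l) {
      sum(sqrt(xs[[l]] * ys[[l]]))
    }, numeric(1))))
  }
  jx <- vapply(xs, function(v) sum(v^2), numeric(1))
  jy <- vapply(ys, function(v) sum(v^2), numeric(1))
  jxy <- vapply(seq_along(xs), function(l) sum(xs[[l]] * ys[[l]]), numeric(1))
  i_xy <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  if (i_xy <= 0) {
    abort("Populations share no alleles: genetic identity is zero, distance infinite.",
          class = "hla_infinite_distance")
  }
  -log(i_xy)
}

#' Nei's standard genetic distance between two populations
#'
#' Computes Nei's (1972) standard genetic distance from multi-locus allele
#' frequencies: per locus the identities `j_X = sum x_i^2`,
#' `j_Y = sum y_i^2` and `j_XY = sum x_i y_i` are computed over the union
#' of allele categories (absent categories at frequency 0), the three are
#' averaged arithmetically across loci, and
#' `D = -ln( J_XY / sqrt(J_X J_Y) )`. `D` is 0 for identical frequency
#' vectors and grows without bound as populations share fewer alleles.
#' The `"da"` variant gives Nei et al.'s (1983) DA distance instead, a
#' bounded alternative sometimes preferred for tree building.
#'
#' @param x,y Long allele-frequency tibbles (`population`, `locus`,
#'   `allele`, `frequency`), each containing a single population.
#' @param loci Loci to average over (default all three).
#' @param renormalize If `TRUE`, rescale each population's per-locus
#'   frequencies to sum to 1 first (useful when frequencies come from a
#'   rounded printed table). Default `FALSE`: frequencies used as given.
#' @param variant `"standard"` (Nei 1972, default) or `"da"` (Nei 1983).
#' @return A single non-negative number.
#' @export
#' @examples
#' fx <- liaoning_fixtures()$allele_frequencies
#' nei_standard_distance(dplyr::filter(fx, population == "Han"),
#'                       dplyr::filter(fx, population == "Manchu"))
nei_standard_distance <- function(x, y, loci = hla_loci(), renormalize = FALSE,
                                  variant = c("standard", "da")) {
  variant <- match.arg(variant)
  if (any(x$frequency < 0) || any(y$frequency < 0)) abort("Negative frequency.")
  universe <- lapply(setNames(loci, loci), function(l) {
    sort(unique(c(x$allele[x$locus == l], y$allele[y$locus == l])))
  })
  xs <- freqs_by_locus(x, unique(x$population), loci, universe)
  ys <- freqs_by_locus(y, unique(y$population), loci, universe)
  nei_from_vectors(xs, ys, renormalize, variant)
}

#' Pairwise Nei distance matrix across populations
#'
#' @param freqs Long allele-frequency tibble holding two or more
#'   populations.
#' @inheritParams nei_standard_distance
#' @return An `hla_dist` object: a symmetric, zero-diagonal labelled
#'   matrix. `tidy()` it for a long pair/distance tibble; `autoplot()`
#'   draws a heatmap.
#' @export
distance_matrix <- function(freqs, loci = hla_loci(), renormalize = FALSE,
                            variant = c("standard", "da")) {
  variant <- match.arg(variant)
  pops <- unique(freqs$population)
  if (length(pops) < 2) abort("Need at least two populations.")
  if (anyDuplicated(pops)) abort("Duplicate population labels.")
  universe <- lapply(setNames(loci, loci), function(l) {
    sort(unique(freqs$allele[freqs$locus == l]))
  })
  vecs <- lapply(setNames(pops, pops), function(p) freqs_by_locus(freqs, p, loci, universe))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1)) {
      d <- nei_from_vectors(vecs[[i]], vecs[[j]], renormalize, variant)
      m[i, j] <- m[j, i] <- d
    }
  }
  new_hla_dist(m)
}

#' @export
print.hla_dist <- function(x, ...) {
  cat("<hla_dist>", nrow(x), "populations\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' @rdname distance_matrix
#' @param x,object An `hla_dist` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hla_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(item1 = rownames(m)[idx[, 1]],
                 item2 = colnames(m)[idx[, 2]],
                 distance = m[idx]) |>
    dplyr::arrange(.data$distance)
}

#' @rdname distance_matrix
#' @exportS3Method ggplot2::autoplot
autoplot.hla_dist <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(item1 = rownames(m), item2 = colnames(m))
  df$distance <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$item1, .data$item2, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Nei D")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou and Nei's agglomerative algorithm: repeatedly join the pair
#' `(i, j)` minimizing `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (where `R`
#' are row sums over the `r` active nodes), with branch lengths from the
#' standard split formula, until three nodes remain; the final three are
#' closed out exactly onto one internal node. The result is the unrooted
#' binary tree that exactly reproduces any additive (four-point-condition)
#' distance matrix. Ties in `Q` are broken deterministically towards the
#' label-lexicographically smallest pair, so taxon input order does not
#' change the tree beyond isomorphism.
#'
#' @param d Symmetric labelled distance matrix (an `hla_dist`, plain
#'   matrix, or `dist`).
#' @param clamp_negative If `TRUE`, negative branch lengths (possible for
#'   non-additive input) are set to 0; default keeps them as computed.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' neighbor_joining(m)
neighbor_joining <- function(d, clamp_negative = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  m <- unclass(d)
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  if (n < 3) abort("Neighbor joining needs at least 3 taxa.")
  if (max(abs(m - t(m))) > 1e-12) abort("Distance matrix must be symmetric.")
  # each active node is a Newick fragment; smallest member label used for ties
  frag <- rownames(m)
  lab <- rownames(m)
  fmt <- function(x) sprintf("%.17g", x)
  while (nrow(m) > 3) {
    r <- nrow(m)
    rs <- rowSums(m)
    q <- (r - 2) * m - outer(rs, rs, "+")
    diag(q) <- Inf
    best <- which(q <= min(q) + 1e-12, arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    key <- paste(pmin(lab[best[, 1]], lab[best[, 2]]),
                 pmax(lab[best[, 1]], lab[best[, 2]]))
    pick <- best[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- m[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- m[i, j] - li
    if (clamp_negative) { li <- max(li, 0); lj <- max(lj, 0) }
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    new_lab <- min(lab[i], lab[j])
    du <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    m2 <- rbind(cbind(m[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    lab <- c(lab[keep], new_lab)
    m <- m2
  }
  la <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  lb <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
  lc <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
  if (clamp_negative) { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb), ",",
                frag[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}
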