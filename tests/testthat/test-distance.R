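test_that("Nei standard distance matches the closed form and is zero for identical inputs", {
  x <- tibble::tibble(population = "x", locus = "A",
                      allele = c("A*01", "A*02"), frequency = c(0.8, 0.2))
  y <- dplyr::mutate(x, population = "y", frequency = c(0.2, 0.8))
  # j_X = j_Y = 0.68, j_XY = 0.32, I = 0.470588, D = 0.753772
  expect_equal(nei_standard_distance(x, y, loci = "A"), 0.753772, tolerance = 1e-6)
  expect_equal(nei_standard_distance(x, dplyr::mutate(x, population = "y"), loci = "A"), 0)
  # no shared alleles: identity zero, infinite distance
  z <- dplyr::mutate(x, population = "z", allele = c("A*03", "A*11"))
  expect_error(nei_standard_distance(x, z, loci = "A"), class = "hla_infinite_distance")
  expect_error(nei_standard_distance(dplyr::mutate(x, frequency = c(-1, 2)), y, loci = "A"),
               "Negative")
})

test_that("Nei distances from the registry table reproduce the published Han comparisons", {
  af <- fx$allele_frequencies
  pick <- function(p) dplyr::filter(af, population == p)
  han <- pick("Han")
  # published values, print tolerance +/- 0.0005 (absolute)
  expect_lt(abs(nei_standard_distance(han, pick("Manchu")) - 0.002084), 5e-4)
  expect_lt(abs(nei_standard_distance(han, pick("Mongol")) - 0.015929), 5e-4)
  expect_lt(abs(nei_standard_distance(han, pick("Hui")) - 0.027006), 5e-4)
  expect_lt(abs(nei_standard_distance(han, pick("Korean")) - 0.036637), 5e-4)
  # the published Han-to-X ordering holds in full
  d <- distance_matrix(af)
  expect_equal(names(sort(d["Han", setdiff(rownames(d), "Han")])),
               c("Manchu", "Mongol", "Hui", "Korean", "Xibe"))
})

test_that("distance matrices are symmetric with zero diagonal and reject duplicates", {
  af <- fx$allele_frequencies
  d <- distance_matrix(af)
  m <- unclass(d)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  expect_true(all(m >= 0))
  two <- dplyr::filter(af, population %in% c("Han", "Manchu"))
  same <- dplyr::bind_rows(dplyr::filter(two, population == "Han"),
                           dplyr::mutate(dplyr::filter(two, population == "Han"),
                                         population = "Han2"))
  expect_equal(unclass(distance_matrix(same))["Han", "Han2"], 0)
  expect_error(distance_matrix(dplyr::filter(af, population == "Han")), "two populations")
  # round-trip through the square TSV writer
  path <- tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  expect_equal(unclass(read_distance_matrix(path)), m, tolerance = 1e-12)
})

test_that("neighbor joining closes out three taxa with the exact split formula", {
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(m)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens, c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(m[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers additive matrices exactly", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:10, 1)
    ref <- ape::rtree(n, rooted = FALSE)
    ref$edge.length <- runif(nrow(ref$edge), 0.1, 2)
    dm <- ape::cophenetic.phylo(ref)
    est <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(ref), est), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    dm_est <- ape::cophenetic.phylo(est)
    expect_equal(dm_est[rownames(dm), colnames(dm)], dm, tolerance = 1e-8)
  }
})

test_that("neighbor joining is order-invariant and agrees with the reference implementation", {
  af <- fx$allele_frequencies
  d <- unclass(distance_matrix(af))
  t1 <- neighbor_joining(d)
  perm <- c(4, 2, 6, 1, 3, 5)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(t2)[rownames(d), rownames(d)],
               ape::cophenetic.phylo(t1)[rownames(d), rownames(d)], tolerance = 1e-10)
  # independent oracle: ape's own NJ on the same matrix
  ref <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(t1, ref), structure(0, names = "PH85"), ignore_attr = TRUE)
  # Newick round-trip preserves topology and branch lengths
  path <- tempfile(fileext = ".nwk")
  write_newick(t1, path)
  back <- ape::read.tree(path)
  expect_equal(ape::cophenetic.phylo(back)[rownames(d), rownames(d)],
               ape::cophenetic.phylo(t1)[rownames(d), rownames(d)], tolerance = 1e-8)
})

test_that("negative branch lengths are kept by default and clamped on request", {
  # a deliberately non-additive matrix that forces a negative branch
  m <- matrix(c(0, 1, 10, 9, 1, 0, 9, 10, 10, 9, 0, 1, 9, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  t_raw <- neighbor_joining(m)
  t_cl <- neighbor_joining(m, clamp_negative = TRUE)
  expect_true(all(t_cl$edge.length >= 0))
  expect_equal(ape::dist.topo(t_raw, t_cl), structure(0, names = "PH85"),
               ignore_attr = TRUE)
})
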