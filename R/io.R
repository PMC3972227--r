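# Readers and writers for the tabular interchange formats: genotype tables,
# per-population allele-frequency tables (percent on disk, proportions in
# memory), haplotype tables, distance matrices and Newick trees.

genotype_columns <- function() {
  c("sample_id", "population",
    paste(rep(hla_loci(), each = 2), 1:2, sep = "_"))
}

# sniff the delimiter from the header line: tab wins if present, else comma
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_auto <- function(path) {
  readr::read_delim(path, delim = detect_delim(path),
                    col_types = readr::cols(.default = "c"),
                    na = character(), trim_ws = TRUE, progress = FALSE)
}

#' Read an unphased genotype table
#'
#' Reads a delimited text file (tab or comma, auto-detected) with one row
#' per donor and columns `sample_id`, `population`, `A_1`, `A_2`, `B_1`,
#' `B_2`, `DRB1_1`, `DRB1_2`. Every allele designation is passed through
#' [normalize_allele()], so full-resolution input collapses to the
#' first-field category system on read. Within each locus the pair is
#' stored in sorted order: phase carries no information in these tables.
#'
#' @param path Path to the genotype file.
#' @param mapping Serological split map for [normalize_allele()].
#' @return A tibble with the eight columns above, one row per donor.
#' @export
read_genotype_table <- function(path, mapping = hla_serology_map()) {
  dat <- read_delim_auto(path)
  missing_cols <- setdiff(genotype_columns(), names(dat))
  if (length(missing_cols)) {
    abort(paste0("Genotype table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dat <- dat[genotype_columns()]
  if (nrow(dat) == 0) abort("Genotype table has no records.")
  m <- as.matrix(dat)
  empty <- which(rowSums(is.na(m) | m == "") > 0)
  if (length(empty)) {
    abort(paste0("Malformed record: empty cell in row(s) ",
                 paste(head(empty, 5), collapse = ", "), " of ", path))
  }
  dup <- dat$sample_id[duplicated(dat$sample_id)]
  if (length(dup)) {
    abort(paste0("Duplicated sample_id(s): ", paste(unique(head(dup, 5)), collapse = ", ")))
  }
  for (col in genotype_columns()[-(1:2)]) {
    dat[[col]] <- normalize_allele(dat[[col]], mapping)
  }
  sort_genotype_pairs(dat)
}

# store each within-locus pair in sorted order (unordered-pair invariant)
sort_genotype_pairs <- function(dat) {
  for (locus in hla_loci()) {
    c1 <- paste0(locus, "_1"); c2 <- paste0(locus, "_2")
    swap <- dat[[c1]] > dat[[c2]]
    tmp <- dat[[c1]][swap]
    dat[[c1]][swap] <- dat[[c2]][swap]
    dat[[c2]][swap] <- tmp
  }
  tibble::as_tibble(dat)
}

#' Write a genotype table
#'
#' @param genotypes Genotype tibble as from [read_genotype_table()].
#' @param path Output path; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  readr::write_tsv(genotypes[genotype_columns()], path)
  invisible(path)
}

#' Read a per-population allele-frequency table
#'
#' The on-disk layout mirrors a published gene-frequency table: first column
#' `allele` (category codes), one column per population, values in percent.
#' Absent cells are read as frequency zero. In memory, frequencies are
#' proportions in `[0, 1]` and the table is long: one row per
#' (population, locus, allele).
#'
#' @param path Path to the frequency file (tab or comma delimited).
#' @return A tibble with columns `population`, `locus`, `allele`,
#'   `frequency` (proportion).
#' @export
read_frequency_table <- function(path) {
  dat <- read_delim_auto(path)
  if (names(dat)[1] != "allele") abort("First column must be `allele`.")
  bad <- !is_allele_category(dat$allele)
  if (any(bad)) {
    abort(paste0("Unparseable allele category: ", paste(dat$allele[bad], collapse = ", ")))
  }
  long <- tidyr::pivot_longer(dat, -"allele", names_to = "population",
                              values_to = "percent")
  long$percent[long$percent == ""] <- "0"
  pct <- suppressWarnings(as.numeric(long$percent))
  if (anyNA(pct)) abort("Non-numeric frequency value in table.")
  if (any(pct < 0)) abort("Negative frequency value in table.")
  tibble::tibble(
    population = long$population,
    locus = category_locus(long$allele),
    allele = canonicalize_category(long$allele),
    frequency = pct / 100
  ) |>
    dplyr::arrange(.data$population, factor(.data$locus, hla_loci()), .data$allele)
}

#' Write a per-population allele-frequency table
#'
#' Inverse of [read_frequency_table()]: emits the wide, percent-valued,
#' tab-delimited layout. Zero frequencies are written as empty cells, as in
#' the published tables.
#'
#' @param freqs Long frequency tibble (`population`, `locus`, `allele`,
#'   `frequency` as proportions).
#' @param path Output path.
#' @param digits Decimal places for the percent values (default 3).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freqs, path, digits = 3) {
  wide <- freqs |>
    dplyr::mutate(percent = ifelse(.data$frequency > 0,
                                   formatC(.data$frequency * 100, digits = digits,
                                           format = "f", drop0trailing = TRUE), "")) |>
    dplyr::select("allele", "locus", "population", "percent") |>
    tidyr::pivot_wider(names_from = "population", values_from = "percent",
                       values_fill = "") |>
    dplyr::arrange(factor(.data$locus, hla_loci()), .data$allele) |>
    dplyr::select(-"locus")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a three-locus haplotype-frequency table
#'
#' @param path Delimited file with columns `A`, `B`, `DRB1`, `frequency`
#'   (proportions) and optionally `population`.
#' @return A tibble with columns `A`, `B`, `DRB1`, `frequency` (and
#'   `population` if present), canonicalized categories.
#' @export
read_haplotype_table <- function(path) {
  dat <- read_delim_auto(path)
  need <- c(hla_loci(), "frequency")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols)) {
    abort(paste0("Haplotype table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(dat[intersect(c("population", need), names(dat))])
  for (locus in hla_loci()) out[[locus]] <- canonicalize_category(out[[locus]])
  out$frequency <- as.numeric(out$frequency)
  if (any(out$frequency < 0)) abort("Negative haplotype frequency.")
  out
}

#' Write a three-locus haplotype-frequency table
#'
#' @param haplotypes Haplotype tibble (`A`, `B`, `DRB1`, `frequency`).
#' @param path Output path; tab-delimited.
#' @param digits Decimal places used for `frequency` (default 4, matching
#'   the print precision of published haplotype tables).
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(haplotypes, path, digits = 4) {
  out <- haplotypes
  out$frequency <- round(out$frequency, digits)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write a labelled distance matrix
#'
#' `write_distance_matrix()` emits either a square labelled TSV or the
#' lower-triangle PHYLIP dialect; `read_distance_matrix()` reads the square
#' TSV form back.
#'
#' @param d Square symmetric matrix with dimnames (as from
#'   [distance_matrix()]).
#' @param path File path.
#' @param format `"tsv"` (square, labelled) or `"phylip"` (lower triangle).
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  m <- unclass(d)
  if (format == "tsv") {
    out <- tibble::as_tibble(m, rownames = "population")
    readr::write_tsv(out, path)
  } else {
    lines <- c(sprintf("%5d", nrow(m)))
    for (i in seq_len(nrow(m))) {
      vals <- if (i > 1) paste(sprintf("%.6f", m[i, seq_len(i - 1)]), collapse = "  ") else ""
      lines <- c(lines, trimws(sprintf("%-10s  %s", rownames(m)[i], vals), "right"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols("population" = "c", .default = "d"))
  m <- as.matrix(dat[-1])
  rownames(m) <- dat$population
  new_hla_dist(m)
}

#' Write a phylogenetic tree in Newick format
#'
#' @param tree An `ape` `phylo` object, as from [neighbor_joining()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
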