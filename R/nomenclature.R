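# Allele-category nomenclature: first-field consolidation with serological
# splits for the B14/B15/B40 families, as used in registry summary tables.

# category grammar: LOCUS*GG, LOCUS*GG(SS), or the literal "Unknown"
.category_rx <- "^(A|B|DRB1)\\*([0-9]{2})(\\(([0-9]{2})\\))?$"
# full/intermediate resolution: LOCUS*GG:SS[:...] or legacy 4-digit LOCUS*GGSS
.full_rx <- "^(A|B|DRB1)\\*?([0-9]{2,6})((:[0-9]{2,4})+[A-Z]?)?$"

#' Validate allele-category codes
#'
#' An allele category is a first-field HLA designation such as `"A*02"`,
#' optionally carrying a serological split such as `"B*15(62)"`, or the
#' literal `"Unknown"` used by registry tables for untypeable results.
#'
#' @param x Character vector of candidate codes.
#' @return Logical vector, `TRUE` where the code is a valid category.
#' @export
#' @examples
#' is_allele_category(c("A*02", "B*15(62)", "Unknown", "A*02:07"))
is_allele_category <- function(x) {
  grepl(.category_rx, x) | x == "Unknown"
}

# locus prefix of a category code ("Unknown" has no locus of its own; it is
# carried in Table 2 under HLA-A and treated as an A-locus category)
category_locus <- function(x) {
  out <- sub("\\*.*$", "", x)
  out[x == "Unknown"] <- "A"
  out
}

# drop a redundant split: B*51(51) -> B*51 (split equal to the group digits
# carries no serological information). The B14/B15/B40 split families are
# exempt: there a same-digit split like B*40(40) names the serological broad
# antigen, a category distinct from the unresolved group B*40.
canonicalize_category <- function(x) {
  m <- regmatches(x, regexec(.category_rx, x))
  vapply(seq_along(x), function(i) {
    mi <- m[[i]]
    if (length(mi) == 0) return(x[[i]])
    if (nzchar(mi[[5]]) && mi[[5]] == mi[[3]] &&
        !(mi[[2]] == "B" && mi[[3]] %in% c("14", "15", "40"))) {
      paste0(mi[[2]], "*", mi[[3]])
    } else {
      x[[i]]
    }
  }, character(1))
}

#' Serological split map for the B14, B15 and B40 families
#'
#' Returns the packaged map from full-resolution HLA-B alleles to their
#' serological split categories (B64/B65, B62/B63/B70/B71/B72/B75/B76/B77,
#' B60/B61), a curated subset of the WHO serologic equivalents. Rows supplied
#' via `extra` are appended and take precedence, so laboratories can extend
#' or override the reference map. Lookups outside the map fail loudly in
#' [normalize_allele()]: a B14/B15/B40 allele is never silently truncated.
#'
#' @param extra Optional data frame with columns `allele` (full-resolution
#'   code, e.g. `"B*15:01"`) and `category` (a valid allele category).
#' @return A tibble with columns `allele` and `category`.
#' @export
#' @examples
#' hla_serology_map()
#' hla_serology_map(extra = data.frame(allele = "B*15:99", category = "B*15"))
hla_serology_map <- function(extra = NULL) {
  path <- system.file("extdata", "serology_b_splits.tsv", package = "hlapopgen")
  map <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (!all(c("allele", "category") %in% names(extra))) {
      abort("`extra` must have columns `allele` and `category`.")
    }
    map <- dplyr::bind_rows(extra, map) |> dplyr::distinct(.data$allele, .keep_all = TRUE)
  }
  bad <- !is_allele_category(map$category)
  if (any(bad)) {
    abort(paste0("Invalid category in serology map: ", paste(map$category[bad], collapse = ", ")))
  }
  map
}

#' Normalize HLA allele names to first-field categories
#'
#' Converts full- or intermediate-resolution allele designations (colon
#' notation such as `"A*02:07"`, or legacy 4-digit notation such as
#' `"B1501"`) to the first-field category system. Alleles of the B14, B15
#' and B40 families are resolved through the serological split map *before*
#' truncation — `"B*40:01"` becomes `"B*40(60)"`, never `"B*40"` — and an
#' allele of those families that is absent from the map is an error.
#' Already-normalized category codes pass through unchanged (idempotence),
#' with a redundant split such as `"B*51(51)"` canonicalized to `"B*51"`.
#'
#' @param x Character vector of allele designations.
#' @param mapping Serological split map, as from [hla_serology_map()].
#' @return Character vector of allele categories, same length as `x`.
#' @export
#' @examples
#' normalize_allele(c("A*02:07", "B*40:01", "DRB1*09:01", "B*51(51)"))
normalize_allele <- function(x, mapping = hla_serology_map()) {
  stopifnot(is.character(x))
  lookup <- setNames(mapping$category, mapping$allele)
  out <- character(length(x))
  x <- trimws(x)
  already <- is_allele_category(x)
  out[already] <- canonicalize_category(x[already])
  todo <- which(!already)
  if (length(todo)) {
    m <- regmatches(x[todo], regexec(.full_rx, x[todo]))
    for (k in seq_along(todo)) {
      i <- todo[[k]]
      mi <- m[[k]]
      if (length(mi) == 0) {
        abort(paste0("Cannot parse allele designation: \"", x[[i]], "\""),
              class = "hla_format_error")
      }
      locus <- mi[[2]]
      digits <- mi[[3]]
      rest <- mi[[4]]
      if (!nzchar(rest) && nchar(digits) > 2) {
        # legacy concatenated digits, e.g. B1501 -> group 15, field 01
        if (nchar(digits) %% 2 != 0) {
          abort(paste0("Cannot parse allele designation: \"", x[[i]], "\""),
                class = "hla_format_error")
        }
        group <- substr(digits, 1, 2)
        rest <- paste0(":", substr(digits, 3, nchar(digits)))
      } else {
        group <- digits
      }
      if (locus == "B" && group %in% c("14", "15", "40")) {
        # serology is a protein-level property: key on the first two fields
        key <- paste0("B*", group, sub("^(:[0-9]{2,4}).*$", "\\1", rest))
        if (!nzchar(rest) || is.na(lookup[key])) {
          abort(paste0("B", group, " allele \"", x[[i]], "\" not in the serological split map; ",
                       "extend the map with hla_serology_map(extra = ...)."),
                class = "hla_unmapped_allele_error")
        }
        out[[i]] <- unname(lookup[key])
      } else {
        out[[i]] <- paste0(locus, "*", group)
      }
    }
  }
  out
}
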