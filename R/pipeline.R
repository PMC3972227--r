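# End-to-end pipeline: genotypes -> allele frequencies -> HWE -> EM
# haplotypes -> LD -> Nei distances -> NJ tree, from one configuration.

#' Build a pipeline configuration
#'
#' All thresholds and algorithm settings of [run_pipeline()] in one list,
#' with the package defaults filled in. A configuration can equally be
#' written as a YAML file and passed to [run_pipeline()] by path; values
#' given here override nothing — this is simply the validated container.
#'
#' @param genotypes Path to the genotype table to analyze.
#' @param out_dir Output directory (created if absent).
#' @param populations Populations to analyze, or `NULL` for all present.
#' @param min_haplotype_frequency Frequency filter applied to the reported
#'   haplotype tables (proportion; default `1e-4`, i.e. 0.01%).
#' @param hwe_alpha Nominal HWE significance level recorded in the report.
#' @param min_expected Pooling threshold for [hwe_test()].
#' @param em_tol,em_max_iter,em_restarts EM settings (see
#'   [em_haplotype_frequencies()]).
#' @param distance_variant,distance_renormalize Distance settings (see
#'   [nei_standard_distance()]).
#' @param seed Seed used for every stochastic stage.
#' @return A validated `hla_pipeline_config` list.
#' @export
pipeline_config <- function(genotypes, out_dir,
                            populations = NULL,
                            min_haplotype_frequency = 1e-4,
                            hwe_alpha = 0.05,
                            min_expected = 5,
                            em_tol = 1e-7, em_max_iter = 1000, em_restarts = 1,
                            distance_variant = "standard",
                            distance_renormalize = FALSE,
                            seed = 20140401) {
  cfg <- list(genotypes = genotypes, out_dir = out_dir,
              populations = populations,
              min_haplotype_frequency = min_haplotype_frequency,
              hwe_alpha = hwe_alpha, min_expected = min_expected,
              em_tol = em_tol, em_max_iter = em_max_iter,
              em_restarts = em_restarts,
              distance_variant = distance_variant,
              distance_renormalize = distance_renormalize,
              seed = seed)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$min_haplotype_frequency >= 0,
            cfg$hwe_alpha > 0, cfg$hwe_alpha < 1,
            cfg$min_expected >= 0,
            cfg$em_tol > 0, cfg$em_max_iter > 0, cfg$em_restarts >= 1)
  if (!cfg$distance_variant %in% c("standard", "da")) {
    abort("`distance_variant` must be \"standard\" or \"da\".")
  }
  if (!file.exists(cfg$genotypes)) {
    abort(paste0("Genotype file does not exist: ", cfg$genotypes))
  }
  structure(cfg, class = "hla_pipeline_config")
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage \"", name, "\" failed: ", conditionMessage(e)),
          parent = e)
  })
}

#' Run the full registry analysis pipeline
#'
#' Reads a genotype table and writes, per population: an allele-frequency
#' table, an HWE report, the EM haplotype table filtered at the configured
#' threshold, and the LD table; plus, across populations, the Nei distance
#' matrix (square TSV and PHYLIP lower triangle) and the neighbor-joining
#' tree in Newick format (three or more populations). A machine-readable
#' `report.json` lists every artifact with its row count and the exact
#' settings and seed used. Rerunning with the same configuration and seed
#' reproduces byte-identical numeric outputs.
#'
#' @param config An [pipeline_config()] list, a plain list of its fields,
#'   or the path of a YAML file holding them.
#' @param quiet Suppress progress messages (default `FALSE`; messages go
#'   to `stderr`, never into the numeric outputs).
#' @return Invisibly, a tibble of artifacts (`artifact`, `path`, `rows`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "hla_pipeline_config")) config <- do.call(pipeline_config, config)
  say <- function(...) if (!quiet) message("[hlapopgen] ", sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genotypes <- stage("read_genotypes", read_genotype_table(config$genotypes))
  pops <- config$populations %||% sort(unique(genotypes$population))
  say("loaded %d records, %d population(s); seed %d",
      nrow(genotypes), length(pops), config$seed)

  artifacts <- list()
  add <- function(artifact, path, rows) {
    artifacts[[length(artifacts) + 1]] <<- tibble::tibble(
      artifact = artifact, path = path, rows = rows)
  }

  all_freqs <- stage("allele_frequencies", allele_frequencies(genotypes))
  for (pop in pops) {
    pf <- all_freqs[all_freqs$population == pop, ]
    path <- file.path(config$out_dir, paste0(pop, "_frequencies.tsv"))
    write_frequency_table(pf, path)
    add(paste0("frequencies/", pop), path, nrow(pf))

    hwe <- stage("hwe", hwe_test(genotypes, pop, min_expected = config$min_expected,
                                 seed = config$seed))
    hwe_out <- dplyr::mutate(
      dplyr::select(hwe, "locus", "chi2", "df", "p_value", "method"),
      significant = .data$p_value < config$hwe_alpha)
    path <- file.path(config$out_dir, paste0(pop, "_hwe.tsv"))
    readr::write_tsv(hwe_out, path)
    add(paste0("hwe/", pop), path, nrow(hwe_out))

    fit <- stage("em", em_haplotype_frequencies(
      genotypes, pop, tol = config$em_tol, max_iter = config$em_max_iter,
      restarts = config$em_restarts, seed = config$seed))
    say("EM %s: %d haplotypes, %d iterations, converged=%s", pop,
        nrow(fit$frequencies), fit$iterations, fit$converged)
    haps <- filter_and_rank(tidy(fit), min_freq = config$min_haplotype_frequency)
    path <- file.path(config$out_dir, paste0(pop, "_haplotypes.tsv"))
    write_haplotype_table(haps, path)
    add(paste0("haplotypes/", pop), path, nrow(haps))

    ld <- stage("ld", three_locus_delta(haps, pf))
    path <- file.path(config$out_dir, paste0(pop, "_ld.tsv"))
    readr::write_tsv(dplyr::mutate(ld, hf = round(.data$hf, 6),
                                   delta_percent = round(100 * .data$delta, 4),
                                   delta = NULL), path)
    add(paste0("ld/", pop), path, nrow(ld))
  }

  if (length(pops) >= 2) {
    d <- stage("distance", distance_matrix(
      all_freqs[all_freqs$population %in% pops, ],
      renormalize = config$distance_renormalize,
      variant = config$distance_variant))
    path <- file.path(config$out_dir, "distances.tsv")
    write_distance_matrix(d, path, "tsv")
    add("distances/tsv", path, nrow(d))
    path <- file.path(config$out_dir, "distances.phy")
    write_distance_matrix(d, path, "phylip")
    add("distances/phylip", path, nrow(d))
    if (length(pops) >= 3) {
      tree <- stage("tree", neighbor_joining(d))
      path <- file.path(config$out_dir, "tree.nwk")
      write_newick(tree, path)
      add("tree", path, length(tree$tip.label))
    }
  }

  report <- list(settings = unclass(config),
                 artifacts = dplyr::bind_rows(artifacts))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote %d artifacts to %s", nrow(report$artifacts), config$out_dir)
  invisible(report$artifacts)
}
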