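with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "': ", conditionMessage(e)))
  })
}

log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
  invisible(NULL)
}

#' Run the full genotyping-and-association pipeline
#'
#' Orchestrates the chain simulate (or ingest) -> observation filtering
#' -> polymorphic-site discovery and genotype calling -> site filtering
#' -> PLL aggregation -> allele-group Wilcoxon scan, writing every
#' intermediate artifact plus a checksum manifest into `out_dir`. With a
#' fixed `cfg$random_seed` the run is deterministic and the manifest
#' checksums reproduce exactly.
#'
#' In real-data mode, pass paths to a base-observation table and a
#' phenotype table in the interchange formats written by
#' [write_fixtures()]; the simulator is then bypassed.
#'
#' @param cfg A [sim_config()]; also supplies the parent ids and seed.
#' @param out_dir Output directory, created if needed.
#' @param obs_file,pheno_file Optional real-data inputs (both required
#'   together).
#' @param write_observations Write the (large) simulated pileup table to
#'   disk? Default `TRUE`.
#' @param verbose Emit per-stage record counts via [message()].
#' @return Invisibly, a list with `calls`, `summaries` (filter-annotated
#'   site summaries), `pll`, `scan` (a `gbs_scan`), `paths` and
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(n_progeny = 30, n_chromosomes = 3,
#'                   markers_per_chromosome = 5, random_seed = 11)
#' res <- run_pipeline(cfg, tempfile("gbsrun"))
#' glance(res$scan)
#' }
run_pipeline <- function(cfg = sim_config(), out_dir,
                         obs_file = NULL, pheno_file = NULL,
                         write_observations = TRUE, verbose = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort(paste0("cannot create output directory '", out_dir, "'"))
  paths <- character()
  real_mode <- !is.null(obs_file) || !is.null(pheno_file)
  if (real_mode) {
    obs <- with_stage("ingest", {
      if (is.null(obs_file) || !file.exists(obs_file))
        abort("base-observation file is missing")
      read_observations(obs_file)
    })
    pheno <- with_stage("ingest", {
      if (is.null(pheno_file) || !file.exists(pheno_file))
        abort("phenotype file is missing")
      read_phenotypes(pheno_file)
    })
    log_stage(verbose, "ingest: %d observations, %d shoot measurements",
              nrow(obs), nrow(pheno))
  } else {
    sim <- with_stage("simulate", simulate_f1_dataset(cfg))
    obs <- sim$observations
    pheno <- sim$phenotypes
    log_stage(verbose,
              "simulate: %d markers, %d samples, %d observations, %d shoots",
              nrow(sim$map), length(unique(sim$truth$sample_id)),
              nrow(obs), nrow(pheno))
    paths["marker_map"] <- file.path(out_dir, "marker_map.tsv")
    write_tsv(sim$map, paths[["marker_map"]])
    paths["truth_vcf"] <- file.path(out_dir, "truth.vcf")
    write_vcf(genotypes_from_truth(sim$truth), paths[["truth_vcf"]],
              susceptible_parent = cfg$parent_ids[1],
              parents = cfg$parent_ids)
    if (write_observations) {
      paths["observations"] <- file.path(out_dir, "observations.tsv")
      write_tsv(obs, paths[["observations"]])
    }
    paths["phenotypes"] <- file.path(out_dir, "phenotypes.csv")
    write_csv(pheno, paths[["phenotypes"]])
  }

  counts <- with_stage("genotype", filter_observations(obs))
  calls <- with_stage("genotype", call_genotypes(counts))
  n_sites <- nrow(distinct(calls, .data$chrom, .data$pos))
  log_stage(verbose, "genotype: %d polymorphic sites discovered", n_sites)
  paths["calls_vcf"] <- file.path(out_dir, "calls.vcf")
  write_vcf(calls, paths[["calls_vcf"]],
            susceptible_parent = cfg$parent_ids[1],
            parents = cfg$parent_ids)

  summaries <- with_stage("filter", {
    summarize_sites(calls, parents = cfg$parent_ids) |>
      apply_site_filters()
  })
  calls <- impute_genotypes(calls)  # pass-through; external imputer slot
  kept_sites <- filter(summaries, .data$kept)
  log_stage(verbose, "filter: %d/%d sites kept (%s)",
            nrow(kept_sites), nrow(summaries),
            paste(utils::capture.output(
              print(table(summaries$reason[!summaries$kept]))),
              collapse = " "))
  paths["filter_report"] <- file.path(out_dir, "filter_report.tsv")
  write_tsv(summaries, paths[["filter_report"]])
  kept_calls <- semi_join(calls, kept_sites, by = c("chrom", "pos"))

  pll_table <- with_stage("phenotype", aggregate_pll(pheno))
  paths["pll"] <- file.path(out_dir, "pll.tsv")
  write_tsv(pll_table, paths[["pll"]])

  scan <- with_stage("associate", {
    run_scan(kept_calls, pll_table,
             susceptible_parent = cfg$parent_ids[1],
             parents = cfg$parent_ids)
  })
  log_stage(verbose,
            "associate: %d SNPs tested, threshold %.3f, %d significant",
            scan$n_tested, scan$threshold, sum(scan$results$significant))
  paths["association"] <- file.path(out_dir, "association.tsv")
  assoc_header <- c(sprintf("# bonferroni_neglog10_threshold=%.6g",
                            scan$threshold),
                    sprintf("# n_snps_tested=%d", scan$n_tested),
                    sprintf("# alpha=%g", scan$alpha))
  writeLines(assoc_header, paths[["association"]])
  readr::write_tsv(scan$results, paths[["association"]], append = TRUE,
                   col_names = TRUE)

  manifest <- tibble(file = basename(unname(paths)),
                     md5 = unname(tools::md5sum(unname(paths))))
  paths["manifest"] <- file.path(out_dir, "manifest.tsv")
  write_tsv(manifest, paths[["manifest"]])

  invisible(list(calls = calls, summaries = summaries, pll = pll_table,
                 scan = scan, paths = paths, manifest = manifest))
}
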