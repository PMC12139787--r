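# End-to-end reproducible pipeline: simulate (or load) -> assign -> natives
# -> fitness -> scan -> liability, with a manifest for provenance.

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Run one pipeline stage; on error, abort naming the stage (outputs written
# by earlier stages are left in place).
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Validate pipeline inputs
#'
#' Checks SNP-grid congruence between calls and panel, coordinate ranges,
#' and duplicate identifiers. Returns every violation rather than stopping
#' at the first.
#'
#' @param panel A [genotype_panel()].
#' @param calls A [sample_calls()].
#' @param sites Tibble with `site_id`, `lat`, `lon`.
#' @return A tibble of violations (`check`, `detail`); zero rows when clean.
#' @export
validate_inputs <- function(panel, calls, sites) {
  v <- list()
  add <- function(check, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(check = check, detail = detail)
  }
  if (anyDuplicated(panel$accessions$accession_id)) {
    add("duplicate_accession_id",
        paste(unique(panel$accessions$accession_id[
          duplicated(panel$accessions$accession_id)]), collapse = ", "))
  }
  if (anyDuplicated(calls$samples$sample_id)) {
    add("duplicate_sample_id",
        paste(unique(calls$samples$sample_id[
          duplicated(calls$samples$sample_id)]), collapse = ", "))
  }
  panel_key <- paste(panel$snps$chrom, panel$snps$pos)
  calls_key <- paste(calls$snps$chrom, calls$snps$pos)
  extra <- setdiff(calls_key, panel_key)
  if (length(extra)) {
    add("snp_absent_from_panel", paste(utils::head(extra, 10), collapse = "; "))
  }
  if (!identical(panel_key, calls_key) && !length(extra)) {
    add("snp_order_mismatch", "same SNPs, different order")
  }
  bad_lat <- abs(panel$accessions$lat) > 90 | abs(panel$accessions$lon) > 180
  if (any(bad_lat, na.rm = TRUE)) {
    add("accession_coordinates_out_of_range",
        paste(panel$accessions$accession_id[which(bad_lat)], collapse = ", "))
  }
  bad_site <- abs(sites$lat) > 90 | abs(sites$lon) > 180
  if (any(bad_site, na.rm = TRUE)) {
    add("site_coordinates_out_of_range",
        paste(sites$site_id[which(bad_site)], collapse = ", "))
  }
  unknown_sites <- setdiff(unique(calls$samples$site_id), sites$site_id)
  if (length(unknown_sites)) {
    add("sample_site_not_declared", paste(unknown_sites, collapse = ", "))
  }
  if (length(v)) dplyr::bind_rows(v) else tibble::tibble(check = character(0),
                                                         detail = character(0))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation (from a [sim_config()]) or loading
#' (from file paths), validation, sample assignment, native-contamination
#' filtering, fitness estimation, the drift selection scan with combined
#' p-values, and (optionally) the liability-model fit on simulated survival
#' data. Every intermediate is written as TSV/CSV under `out_dir`, plus a
#' JSON manifest recording inputs, parameters, seed and per-stage row
#' counts. Identical configs produce byte-identical outputs.
#'
#' @param config A list with either `sim` (a [sim_config()]) or `paths`
#'   (named list: `panel_tsv`, `panel_meta`, `calls_tsv`, `calls_meta`,
#'   `sites_csv`); optional per-stage blocks `assign`
#'   (`mismatch_threshold`, `min_informative`, `het_threshold`), `natives`
#'   (`cutoff_km`, `home_away_ratio`, `min_home_freq`, `mode`), `scan`
#'   (`center`, `maf_floor`, `ne` named vector), `liability` (`tau_mild`,
#'   `tau_harsh`, `sigma_mild`, `sigma_harsh`, `n_trials`, `mu_sd`); and
#'   `seed` (root seed, defaults to the sim config's).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  has_sim <- !is.null(config$sim)
  has_paths <- !is.null(config$paths)
  if (!has_sim && !has_paths) {
    stop("config must supply either `sim` or `paths`", call. = FALSE)
  }
  if (has_sim) stopifnot(inherits(config$sim, "sim_config"))
  assign_par <- utils::modifyList(
    list(mismatch_threshold = 0.015, min_informative = 10000, het_threshold = 0.05),
    config$assign %||% list()
  )
  natives_par <- utils::modifyList(
    list(cutoff_km = 5.6, home_away_ratio = 3.0, min_home_freq = 0.10,
         mode = "ratio"),
    config$natives %||% list()
  )
  scan_par <- utils::modifyList(
    list(center = TRUE, maf_floor = 0.03, ne = NULL),
    config$scan %||% list()
  )
  seed <- config$seed %||% (if (has_sim) config$sim$seed else 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  if (has_sim) {
    pipeline_log("simulate", "generating synthetic study (seed %d)", seed)
    study <- simulate_study(config$sim)
    panel <- study$panel
    calls <- study$calls
    sites <- config$sim$sites
    readr::write_tsv(study$truth, path("truth.tsv"))
  } else {
    pipeline_log("load", "reading inputs from disk")
    panel <- read_panel_tsv(config$paths$panel_tsv, config$paths$panel_meta)
    calls <- read_calls_tsv(config$paths$calls_tsv, config$paths$calls_meta)
    sites <- readr::read_csv(config$paths$sites_csv, show_col_types = FALSE,
                             progress = FALSE)
  }
  write_panel_tsv(panel, path("panel.tsv"), path("accessions.csv"))
  write_vcf(panel, path("panel.vcf"))
  write_calls_tsv(calls, path("calls.tsv"), path("samples.csv"))
  readr::write_csv(sites, path("sites.csv"))

  pipeline_log("validate", "checking inputs")
  violations <- validate_inputs(panel, calls, sites)
  if (nrow(violations)) {
    readr::write_tsv(violations, path("violations.tsv"))
    stop(sprintf("input validation failed (%d violation(s)); see %s",
                 nrow(violations), path("violations.tsv")), call. = FALSE)
  }

  pipeline_log("assign", "assigning %d samples against %d accessions",
               ncol(calls$calls), ncol(panel$genotypes))
  assignments <- run_stage("assign", assign_samples(
    calls, panel,
    mismatch_threshold = assign_par$mismatch_threshold,
    min_informative = assign_par$min_informative,
    het_threshold = assign_par$het_threshold
  ))
  readr::write_tsv(assignments, path("assignments.tsv"))
  composition <- summarize_composition(
    assignments,
    accession_ids = panel$accessions$accession_id,
    site_ids = sites$site_id
  )
  readr::write_tsv(composition$classes, path("composition_classes.tsv"))
  readr::write_tsv(composition$accessions, path("composition_accessions.tsv"))

  pipeline_log("natives", "flagging potential natives within %.1f km",
               natives_par$cutoff_km)
  nat_flags <- flag_potential_natives(panel$accessions, sites,
                                      cutoff_km = natives_par$cutoff_km)
  exclusions <- run_stage("natives", flag_frequency_outliers(
    composition, nat_flags,
    home_away_ratio = natives_par$home_away_ratio,
    min_home_freq = natives_par$min_home_freq,
    mode = natives_par$mode
  ))
  readr::write_tsv(exclusions, path("native_flags.tsv"))

  pipeline_log("fitness", "estimating per-accession fitness")
  freq_table <- run_stage("fitness", accession_frequencies(
    composition, exclusions, n_start = ncol(panel$genotypes)))
  readr::write_tsv(freq_table, path("fitness.tsv"))
  groups <- group_summaries(freq_table, panel$accessions)
  readr::write_tsv(groups, path("group_summaries.tsv"))

  pipeline_log("scan", "drift selection scan")
  scan <- run_stage("scan", drift_scan(panel, composition, ne = scan_par$ne,
                     center = scan_par$center, maf_floor = scan_par$maf_floor))
  write_scan(scan$table, path("scan.tsv"))
  readr::write_tsv(scan$ne_estimates, path("ne_estimates.tsv"))
  combined <- combine_experiments(scan)
  write_scan(combined, path("scan_combined.tsv"))

  liability_out <- NULL
  if (!is.null(config$liability)) {
    lp <- utils::modifyList(
      list(tau_mild = 0.5, tau_harsh = -0.7, sigma_mild = 1, sigma_harsh = 1,
           n_trials = 24, mu_sd = 1.5),
      config$liability
    )
    pipeline_log("liability", "fitting liability-threshold model")
    mu <- withr::with_seed(derive_seed(seed, "liability:mu"),
                           stats::rnorm(ncol(panel$genotypes), 0, lp$mu_sd))
    pairs <- simulate_survival_pair(
      mu, lp$tau_mild, lp$tau_harsh, lp$sigma_mild, lp$sigma_harsh,
      n_trials = lp$n_trials, seed = derive_seed(seed, "liability:trials")
    )
    readr::write_tsv(pairs, path("survival_pairs.tsv"))
    fit <- run_stage("liability", fit_liability(pairs))
    liability_out <- list(
      alpha = fit$alpha, beta = fit$beta,
      se_alpha = fit$se_alpha, se_beta = fit$se_beta,
      converged = fit$converged,
      alpha_true = attr(pairs, "alpha"), beta_true = attr(pairs, "beta")
    )
    jsonlite::write_json(liability_out, path("liability.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "fieldsel",
    version = as.character(utils::packageVersion("fieldsel")),
    seed = seed,
    inputs = if (has_sim) "synthetic" else unlist(config$paths),
    parameters = list(assign = assign_par, natives = natives_par,
                      scan = scan_par, liability = config$liability),
    stages = list(
      n_accessions = ncol(panel$genotypes),
      n_snps = nrow(panel$genotypes),
      n_samples = ncol(calls$calls),
      n_assignments = nrow(assignments),
      n_excluded = sum(exclusions$excluded, na.rm = TRUE),
      n_fitness_rows = nrow(freq_table),
      n_scan_rows = nrow(scan$table),
      n_combined_snps = nrow(combined),
      ne_estimates = stats::setNames(
        round(scan$ne_estimates$ne, 4), scan$ne_estimates$site_id
      ),
      liability = liability_out
    )
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("done", "outputs in %s", out_dir)
  invisible(manifest)
}
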