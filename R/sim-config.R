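# Study-design configuration for the synthetic generator.

#' Default experimental sites
#'
#' Four field sites — two on the Swedish north-east coast (NA, NB) and two in
#' the south (SR, ST) — with the per-site sample sizes and drift effective
#' sizes that define the default study conditions.
#'
#' @return A tibble with columns `site_id`, `lat`, `lon`, `n_sample`, `ne`.
#' @export
default_sites <- function() {
  tibble::tibble(
    site_id  = c("NA", "NB", "SR", "ST"),
    lat      = c(62.862, 62.87, 55.906, 55.60),
    lon      = c(18.338, 18.381, 14.260, 14.304),
    n_sample = c(171L, 199L, 208L, 137L),
    ne       = c(17L, 70L, 34L, 16L)
  )
}

#' Build a synthetic-study configuration
#'
#' Houses every knob of the generator. Defaults emulate the sow-and-sequence
#' design the package targets: 200 inbred accessions in 4 differentiated
#' groups sown at equal frequency (40 seeds each, 8,000 per subplot), small
#' per-site drift effective sizes, per-site sample sizes in the 137-208
#' range, 15.8% native volunteers and 8.8% heterozygous/contaminated samples,
#' plus low-coverage missingness and genotype error.
#'
#' @param n_accessions Number of inbred panel accessions.
#' @param n_snps Number of biallelic SNPs to simulate.
#' @param n_groups Number of differentiated ancestry groups.
#' @param differentiation Balding-Nichols-style Fst parameter in `[0, 1)`
#'   controlling group divergence.
#' @param fitness Per-accession relative fitness weights (recycled to
#'   `n_accessions`); all equal means neutrality.
#' @param sites Data frame of sites as in [default_sites()].
#' @param native_fraction Proportion of field samples that are native
#'   volunteers rather than experimental descendants.
#' @param het_fraction Proportion of field samples that are extensively
#'   heterozygous (outcrossing or contamination; the two are not
#'   distinguished).
#' @param genotype_error_rate Per-call probability that a homozygous call is
#'   flipped to the other allele.
#' @param missing_rate Per-call probability that a call is dropped to missing.
#' @param het_call_portion Among a contaminated sample's sites where its two
#'   source genomes differ, the fraction reported as heterozygous (the rest
#'   are called as one of the two alleles at random).
#' @param seeds_per_accession Seeds sown per accession per subplot.
#' @param seed_density_m2 Sowing density in seeds per accession per square
#'   metre.
#' @param seed Root RNG seed; every stage derives its own substream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 200,
                       n_snps = 20000,
                       n_groups = 4,
                       differentiation = 0.2,
                       fitness = rep(1, n_accessions),
                       sites = default_sites(),
                       native_fraction = 0.158,
                       het_fraction = 0.088,
                       genotype_error_rate = 0.005,
                       missing_rate = 0.5,
                       het_call_portion = 0.5,
                       seeds_per_accession = 40,
                       seed_density_m2 = 120,
                       seed = 1L) {
  check_count(n_accessions, "n_accessions")
  check_count(n_snps, "n_snps", min = 0)
  check_count(n_groups, "n_groups")
  if (n_groups > n_accessions) stop("`n_groups` cannot exceed `n_accessions`", call. = FALSE)
  if (!is.numeric(differentiation) || differentiation < 0 || differentiation >= 1) {
    stop("`differentiation` must lie in [0, 1)", call. = FALSE)
  }
  fitness <- rep_len(fitness, n_accessions)
  if (any(!is.finite(fitness)) || any(fitness <= 0)) {
    stop("`fitness` weights must be strictly positive", call. = FALSE)
  }
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("site_id", "lat", "lon", "n_sample", "ne") %in% names(sites)))
  check_count(sites$n_sample, "sites$n_sample")
  check_count(sites$ne, "sites$ne")
  check_latlon(sites$lat, sites$lon)
  check_proportion(native_fraction, "native_fraction")
  check_proportion(het_fraction, "het_fraction")
  check_proportion(genotype_error_rate, "genotype_error_rate")
  check_proportion(missing_rate, "missing_rate")
  check_proportion(het_call_portion, "het_call_portion")
  structure(
    list(
      n_accessions = as.integer(n_accessions),
      n_snps = as.integer(n_snps),
      n_groups = as.integer(n_groups),
      differentiation = differentiation,
      fitness = fitness,
      sites = sites,
      native_fraction = native_fraction,
      het_fraction = het_fraction,
      genotype_error_rate = genotype_error_rate,
      missing_rate = missing_rate,
      het_call_portion = het_call_portion,
      seeds_per_accession = as.integer(seeds_per_accession),
      seed_density_m2 = seed_density_m2,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d accessions / %d SNPs / %d groups (Fst %.2f), %d sites, seed %d\n",
    x$n_accessions, x$n_snps, x$n_groups, x$differentiation, nrow(x$sites), x$seed
  ))
  invisible(x)
}

#' Sowing-design bookkeeping
#'
#' Expands a configuration into the per-subplot sowing layout: seeds per
#' accession, total seeds per subplot, and the implied subplot area at the
#' configured density.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row: `n_accessions`, `seeds_per_accession`,
#'   `seeds_per_subplot`, `seed_density_m2`, `subplot_area_m2`.
#' @export
sowing_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tibble::tibble(
    n_accessions = config$n_accessions,
    seeds_per_accession = config$seeds_per_accession,
    seeds_per_subplot = config$n_accessions * config$seeds_per_accession,
    seed_density_m2 = config$seed_density_m2,
    subplot_area_m2 = config$seeds_per_accession / config$seed_density_m2
  )
}
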