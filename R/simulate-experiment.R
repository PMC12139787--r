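# Wright-Fisher selection experiment simulation and call degradation.

#' Simulate one site's selection experiment
#'
#' Two-stage sampling from a sown population in which every accession starts
#' at equal frequency `1/N`: stage 1 draws the surviving population as a
#' multinomial of size `ne` with probabilities proportional to the fitness
#' weights (Wright-Fisher reproduction with selection); stage 2 draws
#' `n_sample` sampled individuals multinomially from the realized stage-1
#' composition. Each sampled individual carries its source accession's full
#' genotype.
#'
#' @param panel A [genotype_panel()].
#' @param fitness Positive fitness weight per accession.
#' @param ne Drift effective population size (stage-1 multinomial size).
#' @param n_sample Number of individuals genotyped from the site.
#' @param seed Integer seed for this site's substream.
#' @param site_id Site label attached to the samples.
#' @return A list with elements `calls` (a [sample_calls()]) and `truth`
#'   (tibble: `sample_id`, `site_id`, `source`, `class`).
#' @export
simulate_selection_experiment <- function(panel, fitness, ne, n_sample,
                                          seed = 1L, site_id = "S1") {
  stopifnot(inherits(panel, "genotype_panel"))
  n_acc <- ncol(panel$genotypes)
  if (n_acc == 0) stop("cannot simulate from an empty panel", call. = FALSE)
  fitness <- rep_len(fitness, n_acc)
  if (any(fitness <= 0)) stop("`fitness` weights must be strictly positive", call. = FALSE)
  check_count(ne, "ne")
  check_count(n_sample, "n_sample")

  withr::with_seed(as.integer(seed), {
    pop <- as.vector(stats::rmultinom(1, ne, fitness / sum(fitness)))
    picks <- sample.int(n_acc, n_sample, replace = TRUE, prob = pop / ne)
  })

  calls <- panel$genotypes[, picks, drop = FALSE]
  samples <- tibble::tibble(
    sample_id = sprintf("%s_s%03d", site_id, seq_len(n_sample)),
    site_id = site_id
  )
  truth <- tibble::tibble(
    sample_id = samples$sample_id,
    site_id = site_id,
    source = panel$accessions$accession_id[picks],
    class = "experimental"
  )
  colnames(calls) <- samples$sample_id
  list(
    calls = sample_calls(calls, samples, panel$snps),
    truth = truth
  )
}

#' Degrade genotype calls to low-coverage field quality
#'
#' Emulates genotyping of tiny, half-dead field samples: each homozygous call
#' is independently flipped to the other allele with `error_rate`; a chosen
#' share of samples is made extensively heterozygous by mixing in a second,
#' random panel accession (at sites where the two genomes differ, a portion
#' `het_call_portion` of calls become heterozygous and the rest are called as
#' one of the two alleles at random); finally each call is independently
#' dropped to missing with `missing_rate`.
#'
#' @param calls A [sample_calls()].
#' @param missing_rate,error_rate Per-call probabilities in `[0, 1]`.
#' @param het_fraction_of_samples Share of samples to contaminate; ignored
#'   when `het_idx` is supplied.
#' @param seed Integer seed.
#' @param panel Panel supplying the second genome for contamination
#'   (required when any sample is to be made heterozygous).
#' @param het_call_portion Portion of discordant sites called heterozygous in
#'   a contaminated sample.
#' @param het_idx Optional explicit column indices of samples to contaminate.
#' @return A [sample_calls()] whose `samples` tibble gains a logical
#'   `het_spiked` column.
#' @export
degrade_calls <- function(calls, missing_rate = 0, error_rate = 0,
                          het_fraction_of_samples = 0, seed = 1L,
                          panel = NULL, het_call_portion = 0.5,
                          het_idx = NULL) {
  stopifnot(inherits(calls, "sample_calls"))
  check_proportion(missing_rate, "missing_rate")
  check_proportion(error_rate, "error_rate")
  check_proportion(het_fraction_of_samples, "het_fraction_of_samples")
  check_proportion(het_call_portion, "het_call_portion")
  m <- calls$calls
  n_samp <- ncol(m)

  withr::with_seed(as.integer(seed), {
    if (error_rate > 0 && length(m)) {
      hom <- !is.na(m) & m != HET_CALL
      flip <- hom & stats::runif(length(m)) < error_rate
      m[flip] <- 1L - m[flip]
    }
    if (is.null(het_idx)) {
      n_het <- round(het_fraction_of_samples * n_samp)
      het_idx <- if (n_het > 0) sample.int(n_samp, n_het) else integer(0)
    }
    if (length(het_idx)) {
      if (is.null(panel)) {
        stop("`panel` is required to generate heterozygous/contaminated samples",
             call. = FALSE)
      }
      check_snp_congruence(calls, panel)
      mates <- sample.int(ncol(panel$genotypes), length(het_idx), replace = TRUE)
      for (j in seq_along(het_idx)) {
        s <- het_idx[j]
        g2 <- panel$genotypes[, mates[j]]
        diffs <- which(!is.na(m[, s]) & !is.na(g2) & m[, s] != HET_CALL & m[, s] != g2)
        if (length(diffs)) {
          u <- stats::runif(length(diffs))
          as_het <- diffs[u < het_call_portion]
          as_mate <- diffs[u >= het_call_portion & u < het_call_portion +
                             (1 - het_call_portion) / 2]
          m[as_het, s] <- HET_CALL
          m[as_mate, s] <- g2[as_mate]
        }
      }
    }
    if (missing_rate > 0 && length(m)) {
      m[stats::runif(length(m)) < missing_rate] <- NA_integer_
    }
  })

  samples <- calls$samples
  samples$het_spiked <- seq_len(n_samp) %in% het_idx
  sample_calls(m, samples, calls$snps)
}

# Mismatch rate of one homozygous call vector against every panel accession.
mismatch_to_panel <- function(v, genotypes) {
  s1 <- as.numeric(!is.na(v) & v == 1L)
  s0 <- as.numeric(!is.na(v) & v == 0L)
  g1 <- (genotypes == 1L) * 1
  g1[is.na(g1)] <- 0
  g0 <- (genotypes == 0L) * 1
  g0[is.na(g0)] <- 0
  mis <- as.vector(crossprod(g0, s1) + crossprod(g1, s0))
  inf <- as.vector(crossprod(g0 + g1, s0 + s1))
  rate <- ifelse(inf > 0, mis / inf, NA_real_)
  list(rate = rate, informative = inf)
}

#' Replace a fraction of samples with native volunteers
#'
#' Natives are wild individuals of the local population, not descended from
#' sown seed. Each is drawn as a homozygous genotype from the allele
#' frequencies of a randomly chosen ancestry group, and is redrawn until its
#' mismatch to every panel accession exceeds `mismatch_min`, so that natives
#' are distinguishable from experimental samples by construction.
#'
#' @param calls A [sample_calls()].
#' @param panel The [genotype_panel()] the calls were generated from.
#' @param native_fraction Share of samples to replace; ignored when
#'   `native_idx` is supplied.
#' @param seed Integer seed.
#' @param mismatch_min Required mismatch to every panel accession.
#' @param native_idx Optional explicit column indices to replace.
#' @param max_tries Redraws allowed per native before giving up.
#' @return A list with `calls` (modified [sample_calls()]) and `native_idx`
#'   (integer indices of the replaced samples).
#' @export
spike_natives <- function(calls, panel, native_fraction = 0, seed = 1L,
                          mismatch_min = 0.015, native_idx = NULL,
                          max_tries = 50L) {
  stopifnot(inherits(calls, "sample_calls"), inherits(panel, "genotype_panel"))
  check_proportion(native_fraction, "native_fraction")
  check_snp_congruence(calls, panel)
  m <- calls$calls
  n_samp <- ncol(m)
  n_snp <- nrow(m)
  gf <- panel_group_freqs(panel)

  withr::with_seed(as.integer(seed), {
    if (is.null(native_idx)) {
      n_nat <- round(native_fraction * n_samp)
      native_idx <- if (n_nat > 0) sample.int(n_samp, n_nat) else integer(0)
    }
    for (s in native_idx) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        g <- stats::rbinom(n_snp, 1L, gf[, sample.int(ncol(gf), 1)])
        mm <- mismatch_to_panel(g, panel$genotypes)
        if (all(mm$rate > mismatch_min, na.rm = TRUE)) {
          m[, s] <- g
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "could not draw a native distinguishable from all accessions at %d SNPs",
          n_snp
        ), call. = FALSE)
      }
    }
  })

  list(
    calls = sample_calls(m, calls$samples, calls$snps),
    native_idx = sort(as.integer(native_idx))
  )
}

#' Simulate a complete multi-site selection study
#'
#' Runs the full generative chain for every configured site: Wright-Fisher
#' selection experiment, native-volunteer replacement, and call degradation
#' (genotype error, heterozygous contamination, missingness). Native and
#' heterozygous samples are disjoint sets whose counts are assigned exactly
#' from the configured fractions, so the truth record's class composition is
#' deterministic given the sample sizes.
#'
#' @param config A [sim_config()].
#' @return A list of class `field_study`: `panel`, `calls` (all sites),
#'   `truth` (per-sample tibble: `sample_id`, `site_id`, `source`, `class`),
#'   `composition` (true per-site experimental accession counts), `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- simulate_panel(config)
  per_site <- purrr::pmap(
    list(config$sites$site_id, config$sites$ne, config$sites$n_sample),
    function(site, ne, n_sample) {
      exp <- simulate_selection_experiment(
        panel, config$fitness, ne, n_sample,
        seed = derive_seed(config$seed, paste0("experiment:", site)),
        site_id = site
      )
      n_nat <- round(config$native_fraction * n_sample)
      n_het <- round(config$het_fraction * n_sample)
      idx <- withr::with_seed(
        derive_seed(config$seed, paste0("classes:", site)),
        sample.int(n_sample, n_nat + n_het)
      )
      nat_idx <- idx[seq_len(n_nat)]
      het_idx <- idx[n_nat + seq_len(n_het)]
      spiked <- spike_natives(
        exp$calls, panel,
        seed = derive_seed(config$seed, paste0("natives:", site)),
        native_idx = nat_idx
      )
      degraded <- degrade_calls(
        spiked$calls,
        missing_rate = config$missing_rate,
        error_rate = config$genotype_error_rate,
        seed = derive_seed(config$seed, paste0("degrade:", site)),
        panel = panel,
        het_call_portion = config$het_call_portion,
        het_idx = het_idx
      )
      truth <- exp$truth
      truth$class[nat_idx] <- "native_volunteer"
      truth$source[nat_idx] <- NA_character_
      truth$class[het_idx] <- "heterozygous"
      list(calls = degraded, truth = truth)
    }
  )

  all_calls <- do.call(cbind, purrr::map(per_site, ~ .x$calls$calls))
  all_samples <- purrr::map_dfr(per_site, ~ .x$calls$samples)
  truth <- purrr::map_dfr(per_site, "truth")
  composition <- truth |>
    dplyr::filter(.data$class == "experimental") |>
    dplyr::count(.data$site_id, .data$source, name = "n") |>
    dplyr::rename(accession_id = "source") |>
    tidyr::complete(
      site_id = config$sites$site_id,
      accession_id = panel$accessions$accession_id,
      fill = list(n = 0L)
    )

  structure(
    list(
      panel = panel,
      calls = sample_calls(all_calls, all_samples, panel$snps),
      truth = truth,
      composition = composition,
      config = config
    ),
    class = "field_study"
  )
}

#' @export
print.field_study <- function(x, ...) {
  cat(sprintf(
    "<field_study> %d sites, %d samples, panel %d x %d\n",
    nrow(x$config$sites), ncol(x$calls$calls),
    ncol(x$panel$genotypes), nrow(x$panel$genotypes)
  ))
  invisible(x)
}
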