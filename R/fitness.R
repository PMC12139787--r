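# Frequency-based fitness estimation and exact group-pattern statistics.
#
# Because every accession starts the experiment at equal frequency 1/N, the
# sampled frequency of an accession among experimental-class descendants is
# itself the fitness readout: relative fitness = frequency / (1/N).

#' Per-accession sampled frequencies and relative fitness
#'
#' Frequencies are computed over experimental-class samples only (native
#' volunteers, heterozygous and low-data samples never enter the
#' denominator). Accessions excluded by the native filter are removed and
#' the remaining frequencies renormalized; zero-count accessions keep
#' frequency 0.
#'
#' @param composition A [summarize_composition()] result.
#' @param exclusions Optional [flag_frequency_outliers()] tibble; rows with
#'   `excluded = TRUE` are dropped at that site.
#' @param n_start Number of accessions sown (start frequency `1/n_start`);
#'   defaults to the number of accessions in `composition`.
#' @return A tibble: `site_id`, `accession_id`, `n`, `included`, `frequency`,
#'   `relative_fitness` (frequency x number of included accessions at the
#'   site), `fold_change` (frequency / start frequency). Sites with zero
#'   experimental samples are dropped with a warning.
#' @export
accession_frequencies <- function(composition, exclusions = NULL,
                                  n_start = NULL) {
  stopifnot(inherits(composition, "site_composition"))
  tab <- composition$accessions
  n_start <- n_start %||% dplyr::n_distinct(tab$accession_id)
  tab$included <- TRUE
  if (!is.null(exclusions)) {
    excl <- dplyr::filter(exclusions, .data$excluded)
    if (nrow(excl)) {
      tab <- tab |>
        dplyr::left_join(
          dplyr::mutate(excl[, c("accession_id", "site_id")], drop = TRUE),
          by = c("accession_id", "site_id")
        ) |>
        dplyr::mutate(included = is.na(.data$drop)) |>
        dplyr::select(-"drop")
    }
  }
  empty <- tab |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(tot = sum(.data$n[.data$included]), .groups = "drop") |>
    dplyr::filter(.data$tot == 0)
  if (nrow(empty)) {
    warning(sprintf("dropping site(s) with zero experimental samples: %s",
                    paste(empty$site_id, collapse = ", ")), call. = FALSE)
    tab <- dplyr::filter(tab, !.data$site_id %in% empty$site_id)
  }
  tab |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(
      frequency = ifelse(.data$included,
                         .data$n / sum(.data$n[.data$included]), NA_real_),
      relative_fitness = .data$frequency * sum(.data$included),
      fold_change = .data$frequency * n_start
    ) |>
    dplyr::ungroup() |>
    dplyr::select("site_id", "accession_id", "n", "included", "frequency",
                  "relative_fitness", "fold_change")
}

#' Relative fitness from a sampled frequency
#'
#' Rescales a frequency by the expected frequency in the absence of
#' selection, `1/n_accessions`: a frequency of 0.20 in a 200-accession
#' experiment is a 40-fold increase.
#'
#' @param freq Sampled frequency in `[0, 1]`.
#' @param n_accessions Number of accessions sown at equal frequency.
#' @return `freq * n_accessions`.
#' @export
relative_fitness <- function(freq, n_accessions) {
  check_proportion(freq, "freq")
  check_count(n_accessions, "n_accessions")
  freq * n_accessions
}

#' Probability that some one group is consistently extreme
#'
#' Under exchangeability of `n_groups` groups, the chance that any single
#' group occupies the same extreme rank (e.g. last) in every one of
#' `n_experiments` independent experiments:
#' `n_groups * (1/n_groups)^n_experiments = (1/n_groups)^(n_experiments-1)`.
#'
#' @param n_groups Number of exchangeable groups (>= 2).
#' @param n_experiments Number of independent experiments (>= 1).
#' @return The exact probability.
#' @export
prob_any_group_extreme <- function(n_groups, n_experiments) {
  check_count(n_groups, "n_groups", min = 2)
  check_count(n_experiments, "n_experiments")
  n_groups * (1 / n_groups)^n_experiments
}

#' Exact upper-tail binomial probability
#'
#' `P(X >= successes)` for `X ~ Binomial(trials, p_success)`, computed
#' exactly (no normal approximation).
#'
#' @param successes Observed count (0..trials).
#' @param trials Number of trials.
#' @param p_success Per-trial success probability.
#' @return The exact one-tailed probability.
#' @export
binomial_tail <- function(successes, trials, p_success) {
  check_count(successes, "successes", min = 0)
  check_count(trials, "trials", min = 0)
  check_proportion(p_success, "p_success")
  if (successes > trials) stop("`successes` cannot exceed `trials`", call. = FALSE)
  if (successes == 0) return(1)
  stats::pbinom(successes - 1, trials, p_success, lower.tail = FALSE)
}

#' Group-wise fitness summaries
#'
#' Distribution of relative fitness by ancestry group and site, with the
#' per-site rank of each group's median (rank 1 = highest).
#'
#' @param freq_table Output of [accession_frequencies()].
#' @param group_labels Tibble with `accession_id`, `group`.
#' @return A tibble: `site_id`, `group`, `n`, `median`, `q25`, `q75`,
#'   `rank_median`.
#' @export
group_summaries <- function(freq_table, group_labels) {
  stopifnot(all(c("accession_id", "group") %in% names(group_labels)))
  missing <- setdiff(freq_table$accession_id, group_labels$accession_id)
  if (length(missing)) {
    stop(sprintf("no group label for accession(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  freq_table |>
    dplyr::filter(.data$included) |>
    dplyr::left_join(group_labels[, c("accession_id", "group")], by = "accession_id") |>
    dplyr::group_by(.data$site_id, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$relative_fitness),
      q25 = stats::quantile(.data$relative_fitness, 0.25, names = FALSE),
      q75 = stats::quantile(.data$relative_fitness, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    tidyr::complete(
      site_id = unique(freq_table$site_id),
      group = unique(group_labels$group),
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(rank_median = rank(-.data$median, ties.method = "min",
                                     na.last = "keep")) |>
    dplyr::ungroup()
}
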