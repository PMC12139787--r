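# Assignment of field-sampled genotypes to panel accessions.
#
# A sample is compared to every accession at its informative sites: positions
# where the sample call is homozygous and the accession call is present.
# Heterozygous and missing calls enter neither numerator nor denominator.

#' Mismatch rate between one sample and one accession
#'
#' The fraction of informative sites (sample homozygous, accession
#' non-missing) at which the homozygous calls disagree.
#'
#' @param sample Integer call vector (0/1 hom, 2 het, NA missing).
#' @param accession Integer genotype vector (0/1, NA), same SNP order.
#' @return Mismatch fraction in `[0, 1]`, or `NA` with a warning when there
#'   are no informative sites.
#' @export
mismatch_rate <- function(sample, accession) {
  if (length(sample) != length(accession)) {
    stop("sample and accession call vectors differ in length", call. = FALSE)
  }
  inf <- !is.na(sample) & sample != HET_CALL & !is.na(accession)
  n <- sum(inf)
  if (n == 0) {
    warning("no informative sites; mismatch undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(sample[inf] != accession[inf]) / n
}

# All-pairs mismatch engine: samples x accessions matrices of discordance
# counts and informative-site counts, via four crossproducts.
mismatch_matrix <- function(calls, panel) {
  s <- calls$calls
  g <- panel$genotypes
  s1 <- (s == 1L) * 1; s1[is.na(s1)] <- 0
  s0 <- (s == 0L) * 1; s0[is.na(s0)] <- 0
  g1 <- (g == 1L) * 1; g1[is.na(g1)] <- 0
  g0 <- (g == 0L) * 1; g0[is.na(g0)] <- 0
  mis <- crossprod(s1, g0) + crossprod(s0, g1)
  inf <- crossprod(s1 + s0, g1 + g0)
  n_called <- colSums(!is.na(s))
  n_het <- colSums(s == HET_CALL, na.rm = TRUE)
  list(
    mismatches = mis, informative = inf,
    het_fraction = ifelse(n_called > 0, n_het / n_called, NA_real_)
  )
}

#' Assign field samples to panel accessions
#'
#' Replicates the genotyping classification workflow. In order:
#' \enumerate{
#'   \item a sample whose heterozygous-call fraction exceeds `het_threshold`
#'     is classed `heterozygous` (contamination or recent outcrossing) —
#'     this takes precedence over any match;
#'   \item otherwise, if the best-matching accession is supported by fewer
#'     than `min_informative` informative sites, the sample is `low_data`;
#'   \item otherwise the minimum-mismatch accession is found; an exact tie is
#'     refused (`low_data`, candidates reported) rather than broken
#'     arbitrarily;
#'   \item a unique best match at mismatch `<= mismatch_threshold` is
#'     `experimental`; anything else is a `native_volunteer`.
#' }
#'
#' @param calls A [sample_calls()].
#' @param panel A [genotype_panel()] on the same SNP grid.
#' @param mismatch_threshold Maximum mismatch for a positive identification.
#' @param min_informative Minimum informative sites for any identification.
#' @param het_threshold Heterozygous-call fraction above which a sample is
#'   classed contaminated/outcrossed.
#' @return A tibble with one row per sample: `sample_id`, `site_id`,
#'   `class`, `best_accession`, `mismatch`, `n_informative`, `het_fraction`,
#'   `note`.
#' @export
assign_samples <- function(calls, panel, mismatch_threshold = 0.015,
                           min_informative = 10000, het_threshold = 0.05) {
  stopifnot(inherits(calls, "sample_calls"), inherits(panel, "genotype_panel"))
  if (ncol(panel$genotypes) == 0) stop("panel is empty", call. = FALSE)
  check_snp_congruence(calls, panel)
  mm <- mismatch_matrix(calls, panel)
  rate <- ifelse(mm$informative > 0, mm$mismatches / mm$informative, Inf)
  acc_ids <- panel$accessions$accession_id

  rows <- purrr::map(seq_len(ncol(calls$calls)), function(i) {
    hf <- mm$het_fraction[i]
    r <- rate[i, ]
    best <- which.min(r)
    n_inf <- mm$informative[i, best]
    out <- list(
      class = NA_character_, best_accession = NA_character_,
      mismatch = NA_real_, n_informative = as.integer(unname(n_inf)),
      het_fraction = hf, note = NA_character_
    )
    if (!is.na(hf) && hf > het_threshold) {
      out$class <- "heterozygous"
      return(out)
    }
    if (!is.finite(r[best]) || n_inf < min_informative) {
      out$class <- "low_data"
      return(out)
    }
    out$mismatch <- unname(r[best])
    if (r[best] <= mismatch_threshold) {
      # a tie below the identification threshold is refused, not broken
      ties <- which(mm$mismatches[i, ] * mm$informative[i, best] ==
                      mm$mismatches[i, best] * mm$informative[i, ] &
                      mm$informative[i, ] > 0)
      if (length(ties) > 1) {
        out$class <- "low_data"
        out$note <- paste0("ambiguous: ", paste(acc_ids[ties], collapse = ","))
        return(out)
      }
      out$class <- "experimental"
      out$best_accession <- acc_ids[best]
    } else {
      out$class <- "native_volunteer"
    }
    out
  })

  dplyr::bind_cols(
    calls$samples[, c("sample_id", "site_id")],
    dplyr::bind_rows(rows)
  )
}

#' Assign a single sample
#'
#' Convenience wrapper around [assign_samples()] for one call vector.
#'
#' @param sample Integer call vector aligned to the panel SNP order, or a
#'   one-sample [sample_calls()].
#' @param panel A [genotype_panel()].
#' @inheritParams assign_samples
#' @return A one-row assignment tibble (see [assign_samples()]).
#' @export
assign_sample <- function(sample, panel, mismatch_threshold = 0.015,
                          min_informative = 10000, het_threshold = 0.05) {
  if (!inherits(sample, "sample_calls")) {
    sample <- sample_calls(
      matrix(as.integer(sample), ncol = 1),
      tibble::tibble(sample_id = "sample1", site_id = "site1"),
      panel$snps
    )
  }
  assign_samples(sample, panel, mismatch_threshold, min_informative, het_threshold)
}

#' Minimum SNP count for unambiguous genotyping, by simulation
#'
#' For each candidate SNP count `k` (ascending grid), draws `n_reps` random
#' `k`-SNP subsets of the panel and checks that every accession is uniquely
#' identified: its own mismatch is 0 and its mismatch to every other
#' accession exceeds `mismatch_threshold`. Returns the smallest `k` at which
#' identification succeeds in every replicate, together with any accession
#' pairs that are indistinguishable on the full panel (those can never be
#' separated and are excluded from the criterion).
#'
#' @param panel A [genotype_panel()].
#' @param k_grid Ascending integer vector of SNP counts to try.
#' @param n_reps Random subsets per `k`.
#' @param mismatch_threshold Separation required between distinct accessions.
#' @param seed Integer seed.
#' @return A list of class `min_snps_result`: `k_min` (integer or `NA`),
#'   `indistinguishable` (tibble of permanently inseparable pairs), and
#'   `by_k` (tibble: `k`, `prop_reps_ok`, `min_separation`).
#' @export
min_snps_by_simulation <- function(panel, k_grid, n_reps = 10,
                                   mismatch_threshold = 0.015, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.unsorted(k_grid, strictly = TRUE)) {
    stop("`k_grid` must be strictly ascending", call. = FALSE)
  }
  g <- panel$genotypes
  n_snp <- nrow(g)
  acc_ids <- panel$accessions$accession_id
  if (any(k_grid > n_snp)) stop("`k_grid` exceeds the panel SNP count", call. = FALSE)

  pair_rate <- function(sub) {
    g1 <- (sub == 1L) * 1; g1[is.na(g1)] <- 0
    g0 <- (sub == 0L) * 1; g0[is.na(g0)] <- 0
    mis <- crossprod(g1, g0)
    mis <- mis + t(mis)
    inf <- crossprod(g1 + g0)
    ifelse(inf > 0, mis / inf, NA_real_)
  }

  full <- pair_rate(g)
  diag(full) <- NA
  dup <- which(full <= mismatch_threshold, arr.ind = TRUE)
  dup <- dup[dup[, 1] < dup[, 2], , drop = FALSE]
  indist <- tibble::tibble(
    accession_1 = acc_ids[dup[, 1]],
    accession_2 = acc_ids[dup[, 2]]
  )
  dup_mask <- matrix(FALSE, nrow(full), ncol(full))
  if (nrow(dup)) dup_mask[dup] <- dup_mask[dup[, c(2, 1), drop = FALSE]] <- TRUE

  by_k <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(k_grid, function(k) {
      ok <- logical(n_reps)
      min_sep <- Inf
      for (r in seq_len(n_reps)) {
        sub <- g[sample.int(n_snp, k), , drop = FALSE]
        pr <- pair_rate(sub)
        diag(pr) <- NA
        pr[dup_mask] <- NA
        sep <- min(pr, na.rm = TRUE)
        min_sep <- min(min_sep, sep)
        ok[r] <- sep > mismatch_threshold
      }
      tibble::tibble(k = k, prop_reps_ok = mean(ok), min_separation = min_sep)
    })
  })

  k_ok <- by_k$k[by_k$prop_reps_ok == 1]
  structure(
    list(
      k_min = if (length(k_ok)) min(k_ok) else NA_integer_,
      indistinguishable = indist,
      by_k = by_k
    ),
    class = "min_snps_result"
  )
}

#' @export
print.min_snps_result <- function(x, ...) {
  cat(sprintf(
    "<min_snps_result> k_min = %s; %d permanently indistinguishable pair(s)\n",
    ifelse(is.na(x$k_min), "not reached on grid", as.character(x$k_min)),
    nrow(x$indistinguishable)
  ))
  invisible(x)
}

#' Summarize per-site sample composition
#'
#' Per-site counts of each assignment class plus per-accession counts among
#' experimental-class samples.
#'
#' @param assignments Assignment tibble from [assign_samples()].
#' @param accession_ids Optional full vector of panel accession ids, so that
#'   accessions sampled zero times appear with count 0.
#' @param site_ids Optional full vector of site ids (empty sites appear with
#'   all counts 0).
#' @return A list of class `site_composition`: `classes` (tibble `site_id`,
#'   `class`, `n`, `fraction`), `accessions` (tibble `site_id`,
#'   `accession_id`, `n`), and `n_experimental` (tibble `site_id`, `n`).
#' @export
summarize_composition <- function(assignments, accession_ids = NULL,
                                  site_ids = NULL) {
  all_classes <- c("experimental", "native_volunteer", "heterozygous", "low_data")
  site_ids <- site_ids %||% unique(assignments$site_id)
  classes <- assignments |>
    dplyr::count(.data$site_id, .data$class, name = "n") |>
    tidyr::complete(
      site_id = site_ids, class = all_classes,
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0) |>
    dplyr::ungroup()
  experimental <- dplyr::filter(assignments, .data$class == "experimental")
  accession_ids <- accession_ids %||% sort(unique(experimental$best_accession))
  accessions <- experimental |>
    dplyr::count(.data$site_id, best_accession = .data$best_accession, name = "n") |>
    dplyr::rename(accession_id = "best_accession") |>
    tidyr::complete(
      site_id = site_ids, accession_id = accession_ids,
      fill = list(n = 0L)
    )
  n_experimental <- accessions |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  structure(
    list(classes = classes, accessions = accessions,
         n_experimental = n_experimental),
    class = "site_composition"
  )
}

#' @export
print.site_composition <- function(x, ...) {
  cat(sprintf(
    "<site_composition> %d site(s); experimental n: %s\n",
    nrow(x$n_experimental),
    paste(sprintf("%s=%d", x$n_experimental$site_id, x$n_experimental$n),
          collapse = ", ")
  ))
  invisible(x)
}
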