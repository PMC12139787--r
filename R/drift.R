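# Drift-null allele-frequency selection scan.
#
# Under neutrality the experimental population is a Wright-Fisher multinomial
# sample of size Ne from the sown population (all accessions at 1/N), and the
# observed frequency adds binomial sampling noise of known size n. For an
# allele at starting frequency p0 this gives E[dp] = 0 and
#   Var[dp] = (1/n + 1/Ne + 1/(n Ne)) p0 (1 - p0).
# Ne is estimated from the slope of (dp)^2 on p0(1-p0) through the origin,
# deviations are z-standardized, and per-site p-values are combined across
# experiments by multiplication.

#' Starting allele frequencies of a panel
#'
#' Unweighted mean of accession alleles per SNP (every accession was sown at
#' equal frequency). Missing panel calls are excluded from that SNP's mean;
#' SNPs missing in every accession are dropped with a warning.
#'
#' @param panel A [genotype_panel()].
#' @return A tibble: `chrom`, `pos`, `p0`.
#' @export
starting_freqs <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(panel$genotypes) == 0 || ncol(panel$genotypes) == 0) {
    stop("panel is empty", call. = FALSE)
  }
  p0 <- rowMeans(panel$genotypes, na.rm = TRUE)
  out <- tibble::tibble(chrom = panel$snps$chrom, pos = panel$snps$pos, p0 = p0)
  if (anyNA(p0)) {
    warning(sprintf("dropping %d SNP(s) missing in all accessions", sum(is.na(p0))),
            call. = FALSE)
    out <- out[!is.na(p0), ]
  }
  out
}

#' Sampled allele frequencies from site composition
#'
#' Converts per-site accession counts into per-SNP allele-frequency
#' estimates: `p_hat = sum_a count_a * genotype_a / n`. This is the estimate
#' genotyped field samples provide once assigned to accessions.
#'
#' @param panel A [genotype_panel()].
#' @param composition A [summarize_composition()] result, or a tibble with
#'   `site_id`, `accession_id`, `n`.
#' @return A tibble: `site_id`, `chrom`, `pos`, `p0`, `p_hat`, `delta`,
#'   `n_sample`.
#' @export
sample_allele_freqs <- function(panel, composition) {
  counts <- if (inherits(composition, "site_composition")) {
    composition$accessions
  } else {
    tibble::as_tibble(composition)
  }
  stopifnot(all(c("site_id", "accession_id", "n") %in% names(counts)))
  p0_tab <- starting_freqs(panel)
  keep <- paste(panel$snps$chrom, panel$snps$pos) %in%
    paste(p0_tab$chrom, p0_tab$pos)
  g <- panel$genotypes[keep, , drop = FALSE]
  g0 <- g
  g0[is.na(g0)] <- 0L
  purrr::map_dfr(split(counts, counts$site_id), function(cc) {
    n_tot <- sum(cc$n)
    idx <- match(cc$accession_id, panel$accessions$accession_id)
    if (anyNA(idx)) stop("composition names accessions absent from the panel", call. = FALSE)
    p_hat <- if (n_tot > 0) {
      as.vector(g0[, idx, drop = FALSE] %*% cc$n) / n_tot
    } else {
      rep(NA_real_, nrow(g0))
    }
    tibble::tibble(
      site_id = cc$site_id[1],
      chrom = p0_tab$chrom, pos = p0_tab$pos, p0 = p0_tab$p0,
      p_hat = p_hat, delta = p_hat - p0_tab$p0,
      n_sample = n_tot
    )
  })
}

#' Null variance of the allele-frequency change
#'
#' The exact three-term drift-plus-sampling variance
#' `(1/n + 1/Ne + 1/(n Ne)) p0 (1 - p0)`.
#'
#' @param p0 Starting frequency (vectorized).
#' @param n_sample Genotyped sample size.
#' @param ne Drift effective population size.
#' @return Variance(s); 0 exactly when `p0` is 0 or 1.
#' @export
null_variance <- function(p0, n_sample, ne) {
  check_proportion(p0, "p0")
  check_count(n_sample, "n_sample")
  if (any(ne < 1)) stop("`ne` must be >= 1", call. = FALSE)
  (1 / n_sample + 1 / ne + 1 / (n_sample * ne)) * p0 * (1 - p0)
}

#' Estimate effective population size from the variance slope
#'
#' Regresses per-SNP `(dp)^2` on `p0(1-p0)` through the origin (unbinned
#' least squares over SNPs above the MAF floor) and inverts the exact
#' variance formula: slope `s = 1/n + (1 + 1/n)/Ne`, so
#' `Ne = (1 + 1/n)/(s - 1/n)`. A slope at or below `1/n` (less dispersion
#' than pure sampling noise) is reported as invalid rather than inverted.
#'
#' @param delta Per-SNP frequency changes.
#' @param p0 Matching starting frequencies.
#' @param n_sample Genotyped sample size.
#' @param maf_floor Minor-allele-frequency floor for SNPs entering the fit.
#' @param site_id Optional site label carried into the result.
#' @return An object of class `ne_estimate`: `site_id`, `n_sample`, `slope`,
#'   `ne`, `valid`, `n_snps`, `maf_floor`.
#' @export
estimate_ne <- function(delta, p0, n_sample, maf_floor = 0.03,
                        site_id = NA_character_) {
  stopifnot(length(delta) == length(p0))
  check_count(n_sample, "n_sample")
  keep <- !is.na(delta) & !is.na(p0) & pmin(p0, 1 - p0) >= maf_floor
  if (sum(keep) < 100) {
    stop(sprintf("only %d SNPs above the MAF floor; need >= 100", sum(keep)),
         call. = FALSE)
  }
  x <- p0[keep] * (1 - p0[keep])
  y <- delta[keep]^2
  slope <- sum(x * y) / sum(x * x)
  valid <- slope > 1 / n_sample
  ne <- if (valid) (1 + 1 / n_sample) / (slope - 1 / n_sample) else NA_real_
  structure(
    list(site_id = site_id, n_sample = as.integer(n_sample), slope = slope,
         ne = ne, valid = valid, n_snps = sum(keep), maf_floor = maf_floor),
    class = "ne_estimate"
  )
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "<ne_estimate>%s n = %d, slope = %.4g, Ne = %s (%d SNPs, MAF >= %.2g)\n",
    ifelse(is.na(x$site_id), "", paste0(" ", x$site_id, ":")),
    x$n_sample, x$slope,
    ifelse(x$valid, sprintf("%.1f", x$ne), "invalid (slope <= 1/n)"),
    x$n_snps, x$maf_floor
  ))
  invisible(x)
}

#' Standardize frequency changes against the drift null
#'
#' `z = (dp - c) / sqrt(var0)` with `c` the genome-wide mean `dp` when
#' `center = TRUE` (absorbing reference-genome bias) and 0 otherwise;
#' two-sided p-values from the standard normal. SNPs with zero null variance
#' are excluded and reported via an attribute.
#'
#' @param delta Per-SNP frequency changes.
#' @param var0 Matching null variances ([null_variance()]).
#' @param center Subtract the mean `dp` before standardizing?
#' @return A tibble: `delta`, `var0`, `z`, `p_value` (rows with `var0 = 0`
#'   dropped; their count is in attribute `n_excluded`).
#' @export
scan_z <- function(delta, var0, center = TRUE) {
  stopifnot(length(delta) == length(var0))
  if (any(var0 < 0, na.rm = TRUE)) stop("`var0` must be non-negative", call. = FALSE)
  keep <- !is.na(var0) & var0 > 0 & !is.na(delta)
  n_excluded <- sum(!keep)
  d <- delta[keep]
  v <- var0[keep]
  c0 <- if (center) mean(d) else 0
  z <- (d - c0) / sqrt(v)
  out <- tibble::tibble(delta = d, var0 = v, z = z,
                        p_value = 2 * stats::pnorm(-abs(z)))
  attr(out, "n_excluded") <- n_excluded
  attr(out, "centering") <- c0
  out
}

#' Per-site drift scan
#'
#' Chains [sample_allele_freqs()], [estimate_ne()] (unless `ne` is supplied)
#' and [scan_z()] for every site in a composition.
#'
#' @param panel A [genotype_panel()].
#' @param composition A [summarize_composition()] result or count tibble.
#' @param ne Optional named vector of per-site Ne overrides; sites not named
#'   get Ne estimated from the data.
#' @param center Passed to [scan_z()].
#' @param maf_floor Passed to [estimate_ne()].
#' @return A list of class `drift_scan`: `table` (long tibble: `site_id`,
#'   `chrom`, `pos`, `p0`, `p_hat`, `delta`, `var0`, `z`, `p_value`) and
#'   `ne_estimates` (tibble per site).
#' @export
drift_scan <- function(panel, composition, ne = NULL, center = TRUE,
                       maf_floor = 0.03) {
  freqs <- sample_allele_freqs(panel, composition)
  sites <- unique(freqs$site_id)
  per_site <- purrr::map(sites, function(s) {
    d <- dplyr::filter(freqs, .data$site_id == s)
    n <- d$n_sample[1]
    ne_s <- if (!is.null(ne) && s %in% names(ne)) {
      list(site_id = s, n_sample = n, slope = NA_real_, ne = unname(ne[s]),
           valid = TRUE, n_snps = NA_integer_, maf_floor = NA_real_)
    } else {
      unclass(estimate_ne(d$delta, d$p0, n, maf_floor, site_id = s))
    }
    if (!isTRUE(ne_s$valid)) {
      stop(sprintf("Ne estimate invalid at site %s (slope <= 1/n)", s), call. = FALSE)
    }
    v0 <- null_variance(d$p0, n, ne_s$ne)
    keep <- v0 > 0
    zz <- scan_z(d$delta[keep], v0[keep], center = center)
    tab <- d[keep, c("site_id", "chrom", "pos", "p0", "p_hat", "delta")]
    tab$var0 <- zz$var0
    tab$z <- zz$z
    tab$p_value <- zz$p_value
    list(table = tab, ne = tibble::as_tibble(ne_s[c("site_id", "n_sample",
                                                    "slope", "ne", "valid",
                                                    "n_snps", "maf_floor")]))
  })
  structure(
    list(
      table = purrr::map_dfr(per_site, "table"),
      ne_estimates = purrr::map_dfr(per_site, "ne")
    ),
    class = "drift_scan"
  )
}

#' @export
print.drift_scan <- function(x, ...) {
  cat(sprintf("<drift_scan> %d SNP-site rows, %d site(s)\n",
              nrow(x$table), nrow(x$ne_estimates)))
  print(x$ne_estimates)
  invisible(x)
}

#' Combine per-site scans by multiplying p-values
#'
#' The combined score of a SNP is the product of its per-site p-values
#' (sites where the SNP is absent are skipped and counted). The product is a
#' score, not a calibrated p-value; `fisher_p` applies the chi-square
#' transform (`-2 ln` product on `2k` df) for users needing calibrated
#' tails.
#'
#' @param scan A `drift_scan` object, or its long `table` tibble.
#' @return A tibble: `chrom`, `pos`, `n_sites`, `combined_score`,
#'   `neg_log10_combined`, `fisher_p`, sorted by (`chrom`, `pos`).
#' @export
combine_experiments <- function(scan) {
  tab <- if (inherits(scan, "drift_scan")) scan$table else tibble::as_tibble(scan)
  stopifnot(all(c("site_id", "chrom", "pos", "p_value") %in% names(tab)))
  out <- tab |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      n_sites = sum(!is.na(.data$p_value)),
      combined_score = prod(.data$p_value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_sites > 0) |>
    dplyr::mutate(
      neg_log10_combined = -log10(.data$combined_score),
      fisher_p = stats::pchisq(-2 * log(.data$combined_score),
                               df = 2 * .data$n_sites, lower.tail = FALSE)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  if (nrow(out) == 0) stop("no overlapping SNPs across experiments", call. = FALSE)
  out
}

#' Write a scan table to TSV
#'
#' Rows sorted by (`chrom`, `pos`), stable column order, lossless
#' round-trip via [read_scan()].
#'
#' @param table A scan tibble (long per-site table or combined table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(table, path) {
  stopifnot(all(c("chrom", "pos") %in% names(table)))
  table <- dplyr::arrange(table, .data$chrom, .data$pos)
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read a scan table written by [write_scan()]
#'
#' Uses the base-R numeric parser, which is correctly rounded to the last
#' ulp, so write -> read -> write reproduces identical bytes.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_scan <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           colClasses = NA, stringsAsFactors = FALSE)
  if ("chrom" %in% names(tab)) tab$chrom <- as.character(tab$chrom)
  tibble::as_tibble(tab)
}
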