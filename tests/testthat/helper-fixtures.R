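# Shared fixtures, built in code.

# Small two-site study configuration for fast end-to-end runs.
tiny_config <- function(n_accessions = 20, n_snps = 600, seed = 11,
                        fitness = rep(1, n_accessions), ...) {
  sim_config(
    n_accessions = n_accessions, n_snps = n_snps, n_groups = 4,
    fitness = fitness,
    sites = tibble::tibble(
      site_id = c("S1", "S2"),
      lat = c(56.0, 62.8), lon = c(14.2, 18.3),
      n_sample = c(60L, 80L), ne = c(30L, 50L)
    ),
    seed = seed, ...
  )
}

# A deterministic hand-built panel: `n_acc` accessions whose genotypes are
# fixed bit patterns, useful for exact-arithmetic assertions.
toy_panel <- function(genotypes, lat = NULL, lon = NULL, group = "G1") {
  n_acc <- ncol(genotypes)
  genotype_panel(
    genotypes,
    tibble::tibble(
      accession_id = sprintf("acc%03d", seq_len(n_acc)),
      group = rep_len(group, n_acc),
      lat = lat %||% rep(56, n_acc),
      lon = lon %||% rep(14, n_acc)
    ),
    tibble::tibble(chrom = "1", pos = seq_len(nrow(genotypes)) * 10L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-sample sample_calls aligned to a panel.
as_one_sample <- function(v, panel, site = "S1") {
  sample_calls(
    matrix(as.integer(v), ncol = 1),
    tibble::tibble(sample_id = "s1", site_id = site),
    panel$snps
  )
}

# Hudson Fst estimator (ratio of averages over SNPs) between two groups of
# haploid genotype columns — the independent textbook oracle.
hudson_fst <- function(g1, g2) {
  p1 <- rowMeans(g1)
  p2 <- rowMeans(g2)
  n1 <- ncol(g1)
  n2 <- ncol(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Exhaustive enumeration oracle: probability that some one of k exchangeable
# groups is last in all m experiments (all k^m equally likely last-place
# sequences).
enumerate_consistent_last <- function(k, m) {
  seqs <- expand.grid(rep(list(seq_len(k)), m))
  mean(apply(seqs, 1, function(r) length(unique(r)) == 1))
}

# composition with chosen per-site frequencies for one focal accession
outlier_composition <- function(home_freq, away_freqs, n_site = 500,
                                n_other = 19) {
  sites <- c("HOME", paste0("AWAY", seq_along(away_freqs)))
  focal_n <- round(c(home_freq, away_freqs) * n_site)
  rows <- purrr::map_dfr(seq_along(sites), function(i) {
    rest <- n_site - focal_n[i]
    per <- rest %/% n_other
    cnt <- rep(per, n_other)
    cnt[1] <- cnt[1] + rest - sum(cnt)
    tibble::tibble(
      site_id = sites[i],
      accession_id = c("focal", sprintf("other%02d", seq_len(n_other))),
      n = c(focal_n[i], cnt)
    )
  })
  asn <- rows[rep(seq_len(nrow(rows)), rows$n), ] |>
    dplyr::mutate(
      sample_id = sprintf("s%05d", dplyr::row_number()),
      class = "experimental", best_accession = accession_id,
      mismatch = 0, n_informative = 10000L, het_fraction = 0,
      note = NA_character_
    )
  summarize_composition(asn, accession_ids = unique(rows$accession_id),
                        site_ids = sites)
}

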