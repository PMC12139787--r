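# Structured genotype panel simulation.

#' Simulate a structured inbred genotype panel
#'
#' Draws a panel of homozygous accessions from `n_groups` differentiated
#' ancestry groups under a Balding-Nichols model: each SNP has an ancestral
#' frequency drawn Uniform(0.05, 0.95); each group's frequency is a Beta
#' draw around it with variance governed by `differentiation` (the Fst-like
#' parameter); each accession is a homozygous Bernoulli draw from its group
#' frequency. Collection coordinates are spatially clustered by group along
#' a south-to-north gradient so that geographic structure mirrors genetic
#' structure.
#'
#' @param config A [sim_config()].
#' @return A [genotype_panel()].
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_acc <- config$n_accessions
  n_snp <- config$n_snps
  k <- config$n_groups
  f <- config$differentiation

  withr::with_seed(derive_seed(config$seed, "panel"), {
    anc <- stats::runif(n_snp, 0.05, 0.95)
    group_freq <- matrix(0, nrow = n_snp, ncol = k)
    for (g in seq_len(k)) {
      group_freq[, g] <- if (f > 0) {
        stats::rbeta(n_snp, anc * (1 - f) / f, (1 - anc) * (1 - f) / f)
      } else {
        anc
      }
    }
    group_of <- sort(rep_len(seq_len(k), n_acc))
    genotypes <- matrix(0L, nrow = n_snp, ncol = n_acc)
    for (a in seq_len(n_acc)) {
      genotypes[, a] <- stats::rbinom(n_snp, 1L, group_freq[, group_of[a]])
    }
    # group home ranges: ~1 degree latitude bands from southern Sweden north
    centre_lat <- seq(55.6, 63.0, length.out = k)
    centre_lon <- seq(14.2, 18.3, length.out = k)
    lat <- centre_lat[group_of] + stats::rnorm(n_acc, 0, 0.15)
    lon <- centre_lon[group_of] + stats::rnorm(n_acc, 0, 0.15)
  })

  group_names <- if (k == 4) c("B", "S2", "S1", "N") else paste0("G", seq_len(k))
  accessions <- tibble::tibble(
    accession_id = sprintf("acc%03d", seq_len(n_acc)),
    group = group_names[group_of],
    lat = lat,
    lon = lon
  )
  snps <- tibble::tibble(
    chrom = rep("1", n_snp),
    pos = if (n_snp > 0) seq_len(n_snp) * 100L else integer(0)
  )
  panel <- genotype_panel(genotypes, accessions, snps)
  attr(panel, "group_freq") <- group_freq
  panel
}

# Per-group allele frequencies of an existing panel (used when spiking
# natives into a panel whose generating frequencies are unknown).
panel_group_freqs <- function(panel) {
  gf <- attr(panel, "group_freq")
  if (!is.null(gf)) return(gf)
  groups <- unique(panel$accessions$group)
  sapply(groups, function(g) {
    cols <- panel$accessions$group == g
    rowMeans(panel$genotypes[, cols, drop = FALSE], na.rm = TRUE)
  })
}
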