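# Synthetic-study generator: panel structure, selection sampling, call
# degradation, native spiking, truth bookkeeping.

test_that("panel simulation handles degenerate sizes and is deterministic", {
  cfg <- sim_config(n_accessions = 4, n_snps = 0, n_groups = 2, seed = 3)
  p <- simulate_panel(cfg)
  expect_equal(dim(p), c(0L, 4L))
  expect_equal(nrow(p$accessions), 4)

  cfg2 <- tiny_config(seed = 42)
  expect_identical(simulate_panel(cfg2)$genotypes, simulate_panel(cfg2)$genotypes)
  expect_false(identical(simulate_panel(tiny_config(seed = 43))$genotypes,
                         simulate_panel(cfg2)$genotypes))
  expect_error(sim_config(n_accessions = 0), "count")
  expect_error(sim_config(differentiation = 1), "\\[0, 1\\)")
})

test_that("group differentiation matches the configured Fst (Hudson oracle)", {
  cfg <- sim_config(n_accessions = 200, n_snps = 10000, n_groups = 4,
                    differentiation = 0.2, seed = 101)
  p <- simulate_panel(cfg)
  groups <- split(seq_len(200), p$accessions$group)
  pairs <- utils::combn(names(groups), 2)
  fst <- apply(pairs, 2, function(pr) {
    hudson_fst(p$genotypes[, groups[[pr[1]]]], p$genotypes[, groups[[pr[2]]]])
  })
  expect_lt(abs(mean(fst) - 0.2), 0.05)
})

test_that("selection sampling has the weighted-multinomial expectation", {
  cfg <- sim_config(n_accessions = 200, n_snps = 5, seed = 7)
  panel <- simulate_panel(cfg)
  fitness <- c(20, rep(1, 199))
  n_rep <- 10000
  freq <- vapply(seq_len(n_rep), function(r) {
    exp <- simulate_selection_experiment(panel, fitness, ne = 100,
                                         n_sample = 50, seed = r)
    mean(exp$truth$source == "acc001")
  }, numeric(1))
  # closed form: E[sampled frequency] = 20 / (20 + 199)
  expected <- 20 / 219
  se <- stats::sd(freq) / sqrt(n_rep)
  expect_lt(abs(mean(freq) - expected), 3 * se + 1e-12)
})

test_that("equal fitness with large Ne and n approaches uniform composition", {
  cfg <- sim_config(n_accessions = 100, n_snps = 5, seed = 9)
  panel <- simulate_panel(cfg)
  exp <- simulate_selection_experiment(panel, rep(1, 100), ne = 100000,
                                       n_sample = 100000, seed = 5)
  freq <- table(factor(exp$truth$source,
                       levels = panel$accessions$accession_id)) / 100000
  expect_lt(max(abs(freq - 1 / 100)), 5 * sqrt(0.01 * 0.99 * 2e-5))
  # fixed seed: identical composition across runs
  exp2 <- simulate_selection_experiment(panel, rep(1, 100), ne = 100000,
                                        n_sample = 100000, seed = 5)
  expect_identical(exp$truth$source, exp2$truth$source)
})

test_that("degrade_calls respects identity, boundary and error-rate laws", {
  cfg <- tiny_config(n_snps = 500)
  panel <- simulate_panel(cfg)
  exp <- simulate_selection_experiment(panel, rep(1, 20), 30, 20, seed = 2)

  same <- degrade_calls(exp$calls, 0, 0, 0, seed = 4)
  expect_identical(same$calls, exp$calls$calls)

  gone <- degrade_calls(exp$calls, missing_rate = 1, seed = 4)
  expect_true(all(is.na(gone$calls)))

  exp2 <- simulate_selection_experiment(panel, rep(1, 20), 30, 20, seed = 8)
  flipped <- degrade_calls(exp2$calls, 0, error_rate = 0.01, seed = 12)
  n_flips <- sum(flipped$calls != exp2$calls$calls)
  n_calls <- length(exp2$calls$calls)  # 10,000 calls
  interval <- stats::qbinom(c(0.005, 0.995), n_calls, 0.01)
  expect_gte(n_flips, interval[1])
  expect_lte(n_flips, interval[2])
})

test_that("native spiking replaces the exact count, all beyond the threshold", {
  cfg <- sim_config(n_accessions = 50, n_snps = 1500, seed = 21,
                    sites = tibble::tibble(site_id = "S1", lat = 56, lon = 14,
                                           n_sample = 1000L, ne = 200L))
  panel <- simulate_panel(cfg)
  exp <- simulate_selection_experiment(panel, rep(1, 50), 200, 1000, seed = 1)

  none <- spike_natives(exp$calls, panel, native_fraction = 0, seed = 2)
  expect_identical(none$calls$calls, exp$calls$calls)
  expect_length(none$native_idx, 0)

  sp <- spike_natives(exp$calls, panel, native_fraction = 0.158, seed = 2)
  expect_length(sp$native_idx, 158)
  # every native is beyond the assignment threshold for every accession
  asn <- assign_samples(sp$calls, panel, min_informative = 500)
  expect_true(all(asn$class[sp$native_idx] == "native_volunteer"))
})

test_that("study truth is complete and class counts are assigned exactly", {
  cfg <- tiny_config(n_snps = 400, seed = 31)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$truth), ncol(st$calls$calls))
  counts <- dplyr::count(st$truth, site_id, class)
  for (i in seq_len(nrow(cfg$sites))) {
    n <- cfg$sites$n_sample[i]
    sid <- cfg$sites$site_id[i]
    get <- function(cl) {
      r <- counts$n[counts$site_id == sid & counts$class == cl]
      if (length(r)) r else 0L
    }
    expect_equal(get("native_volunteer"), round(cfg$native_fraction * n))
    expect_equal(get("heterozygous"), round(cfg$het_fraction * n))
  }
  # determinism of the full study under the root seed
  st2 <- simulate_study(cfg)
  expect_identical(st$calls$calls, st2$calls$calls)
  expect_identical(st$truth, st2$truth)
})

test_that("neutral frequency changes are centred and follow the variance law", {
  cfg <- sim_config(n_accessions = 200, n_snps = 5000, seed = 55,
                    sites = tibble::tibble(site_id = "S1", lat = 56, lon = 14,
                                           n_sample = 208L, ne = 34L))
  panel <- simulate_panel(cfg)
  ne <- 34; n <- 208
  stats_rep <- purrr::map_dfr(1:10, function(r) {
    exp <- simulate_selection_experiment(panel, rep(1, 200), ne, n, seed = 100 + r)
    counts <- dplyr::count(exp$truth, accession_id = source, name = "n") |>
      dplyr::mutate(site_id = "S1")
    f <- sample_allele_freqs(panel, counts)
    keep <- pmin(f$p0, 1 - f$p0) >= 0.03
    x <- f$p0[keep] * (1 - f$p0[keep])
    tibble::tibble(mean_dp = mean(f$delta),
                   slope = sum(x * f$delta[keep]^2) / sum(x^2))
  })
  expect_lt(abs(mean(stats_rep$mean_dp)),
            3 * stats::sd(stats_rep$mean_dp) / sqrt(10))
  expected_slope <- 1 / n + 1 / ne + 1 / (n * ne)
  expect_lt(abs(stats::median(stats_rep$slope) / expected_slope - 1), 0.2)
})
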