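# Mismatch computation and sample classification.

test_that("mismatch_rate counts discordant homozygous calls over informative sites", {
  acc <- rep(c(0L, 1L), 500)
  expect_equal(mismatch_rate(acc, acc), 0)
  expect_equal(mismatch_rate(1L - acc, acc), 1)

  s <- acc
  s[1:5] <- 1L - s[1:5]          # 5 discordant
  expect_equal(mismatch_rate(s, acc), 5 / 1000)

  # het and missing sites enter neither numerator nor denominator
  s2 <- acc
  s2[1:5] <- 1L - s2[1:5]
  s2[6:105] <- 2L
  s2[106:205] <- NA_integer_
  expect_equal(mismatch_rate(s2, acc), 5 / 800)
  expect_warning(expect_true(is.na(mismatch_rate(rep(NA_integer_, 10), acc[1:10]))),
                 "informative")
  expect_error(mismatch_rate(1L, c(1L, 0L)), "length")
})

test_that("the fast mismatch engine agrees with a brute-force scan", {
  cfg <- tiny_config(n_snps = 300, seed = 17)
  panel <- simulate_panel(cfg)
  st <- simulate_study(cfg)
  mm <- fieldsel:::mismatch_matrix(st$calls, panel)
  rate_fast <- mm$mismatches / mm$informative
  for (i in c(1, 7, 50)) {
    brute <- suppressWarnings(vapply(
      seq_len(ncol(panel$genotypes)),
      function(a) mismatch_rate(st$calls$calls[, i], panel$genotypes[, a]),
      numeric(1)
    ))
    expect_equal(unname(rate_fast[i, ]), brute)
  }
})

test_that("classification follows the workflow ordering", {
  cfg <- tiny_config(n_snps = 1200, seed = 23)
  panel <- simulate_panel(cfg)

  # noiseless sample from an accession: experimental at mismatch 0
  clean <- as_one_sample(panel$genotypes[, 7], panel)
  a <- assign_samples(clean, panel, min_informative = 1000)
  expect_equal(a$class, "experimental")
  expect_equal(a$best_accession, "acc007")
  expect_equal(a$mismatch, 0)

  # constructed native: flip 5% of an accession's calls; brute-force check
  # that it now mismatches every accession, then expect native_volunteer
  v <- panel$genotypes[, 7]
  flip <- withr::with_seed(5, sample.int(1200, 60))
  v[flip] <- 1L - v[flip]
  brute <- vapply(seq_len(ncol(panel$genotypes)),
                  function(a) mismatch_rate(v, panel$genotypes[, a]), numeric(1))
  expect_true(all(brute >= 0.05 | seq_along(brute) == 7))
  expect_gte(brute[7], 0.015)
  a2 <- assign_samples(as_one_sample(v, panel), panel, min_informative = 1000)
  expect_equal(a2$class, "native_volunteer")

  # insufficient informative sites: low_data
  v3 <- panel$genotypes[, 7]
  v3[1:400] <- NA_integer_   # 800 informative < 1000
  a3 <- assign_samples(as_one_sample(v3, panel), panel, min_informative = 1000)
  expect_equal(a3$class, "low_data")

  # extensive heterozygosity takes precedence over a perfect match
  v4 <- panel$genotypes[, 7]
  v4[1:120] <- 2L
  a4 <- assign_samples(as_one_sample(v4, panel), panel,
                       min_informative = 1000, het_threshold = 0.05)
  expect_equal(a4$class, "heterozygous")
})

test_that("exact mismatch ties are refused, not broken arbitrarily", {
  g <- withr::with_seed(3, matrix(rbinom(400 * 4, 1, 0.5), ncol = 4))
  g[, 2] <- g[, 1]   # duplicated accession
  panel <- toy_panel(g)
  a <- assign_samples(as_one_sample(g[, 1], panel), panel, min_informative = 100)
  expect_equal(a$class, "low_data")
  expect_match(a$note, "ambiguous")
  expect_match(a$note, "acc001")
  expect_match(a$note, "acc002")
})

test_that("raising min_informative never turns low_data into experimental", {
  cfg <- tiny_config(n_snps = 900, seed = 29, missing_rate = 0.4)
  st <- simulate_study(cfg)
  lo <- assign_samples(st$calls, st$panel, min_informative = 200)
  hi <- assign_samples(st$calls, st$panel, min_informative = 500)
  exp_hi <- hi$sample_id[hi$class == "experimental"]
  exp_lo <- lo$sample_id[lo$class == "experimental"]
  expect_true(all(exp_hi %in% exp_lo))
})

test_that("min SNP simulation flags duplicates and finds a sufficient k", {
  # 20-accession toy panel, all pairs differing at >= 10% of sites
  g <- withr::with_seed(11, matrix(rbinom(2500 * 20, 1, 0.5), ncol = 20))
  panel <- toy_panel(g)
  res <- min_snps_by_simulation(panel, k_grid = c(200L, 600L, 2000L),
                                n_reps = 8, seed = 13)
  expect_lte(res$k_min, 2000)
  expect_equal(nrow(res$indistinguishable), 0)
  # brute-force oracle at k_min: every pair separated on a random subset
  sub <- withr::with_seed(13, g[sample.int(2500, res$k_min), ])
  pairs <- utils::combn(20, 2)
  seps <- apply(pairs, 2, function(p) mean(sub[, p[1]] != sub[, p[2]]))
  expect_true(all(seps > 0.015))

  # duplicated accessions are permanently indistinguishable at every k
  g2 <- cbind(g, g[, 1])
  panel2 <- toy_panel(g2)
  res2 <- min_snps_by_simulation(panel2, k_grid = c(200L, 600L), n_reps = 4, seed = 13)
  expect_equal(nrow(res2$indistinguishable), 1)
  expect_setequal(unlist(res2$indistinguishable[1, ]), c("acc001", "acc021"))

  # determinism
  res3 <- min_snps_by_simulation(panel, k_grid = c(200L, 600L, 2000L),
                                 n_reps = 8, seed = 13)
  expect_identical(res$by_k, res3$by_k)
})

test_that("composition summaries count classes and accessions per site", {
  one <- tibble::tibble(
    sample_id = sprintf("s%d", 1:10), site_id = "A",
    class = "experimental", best_accession = "acc001",
    mismatch = 0, n_informative = 1000L, het_fraction = 0, note = NA_character_
  )
  comp <- summarize_composition(one, accession_ids = c("acc001", "acc002"),
                                site_ids = c("A", "B"))
  expect_equal(comp$accessions$n[comp$accessions$site_id == "A" &
                                   comp$accessions$accession_id == "acc001"], 10)
  fr <- comp$classes$fraction[comp$classes$site_id == "A"]
  expect_equal(sort(fr, decreasing = TRUE), c(1, 0, 0, 0))
  # empty site: all counts 0
  expect_true(all(comp$classes$n[comp$classes$site_id == "B"] == 0))
  expect_equal(comp$n_experimental$n[comp$n_experimental$site_id == "B"], 0)
})

test_that("noiseless assignment recovers the designed class mixture exactly", {
  cfg <- sim_config(
    n_accessions = 50, n_snps = 2500, seed = 41,
    sites = tibble::tibble(site_id = "S1", lat = 56, lon = 14,
                           n_sample = 500L, ne = 100L),
    native_fraction = 0.158, het_fraction = 0.088,
    genotype_error_rate = 0, missing_rate = 0
  )
  st <- simulate_study(cfg)
  asn <- assign_samples(st$calls, st$panel, min_informative = 2000)
  comp <- summarize_composition(asn, accession_ids = st$panel$accessions$accession_id)
  fr <- tibble::deframe(comp$classes[, c("class", "fraction")])
  expect_equal(unname(fr["experimental"]), (500 - 79 - 44) / 500)
  expect_equal(unname(fr["native_volunteer"]), 79 / 500)
  expect_equal(unname(fr["heterozygous"]), 44 / 500)
  expect_equal(unname(fr["low_data"]), 0)
  # and the per-sample labels agree with the generator truth
  merged <- dplyr::inner_join(asn, st$truth, by = c("sample_id", "site_id"))
  expect_true(all(merged$class.x == merged$class.y))
  exp_rows <- merged[merged$class.x == "experimental", ]
  expect_true(all(exp_rows$best_accession == exp_rows$source))
})
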