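# Geographic native-contamination filter.

test_that("haversine distance behaves like the textbook formula", {
  expect_equal(geo_distance(55.9, 14.2, 55.9, 14.2), 0)
  expect_equal(geo_distance(55.9, 14.2, 62.8, 18.3),
               geo_distance(62.8, 18.3, 55.9, 14.2))
  # hand haversine oracle, R = 6371 km
  hand <- function(a, b) {
    a <- a * pi / 180; b <- b * pi / 180
    2 * 6371 * asin(sqrt(sin((b[1] - a[1]) / 2)^2 +
                           cos(a[1]) * cos(b[1]) * sin((b[2] - a[2]) / 2)^2))
  }
  d <- geo_distance(55.906, 14.260, 55.60, 14.304)
  expect_equal(d, hand(c(55.906, 14.260), c(55.60, 14.304)), tolerance = 1e-6)
  expect_equal(d, 34.1, tolerance = 0.01)
  expect_error(geo_distance(95, 0, 0, 0), "latitude")
})

test_that("ibd decay recovers an exponential identity curve's cutoff", {
  # pairs generated directly from identity probability exp(-d / d0), d0 = 2 km
  d0 <- 2; fl <- 0.05
  pairs <- withr::with_seed(91, {
    d <- stats::runif(30000, 0, 15)
    tibble::tibble(distance_km = d,
                   identical = stats::runif(30000) < exp(-d / d0))
  })
  dec <- ibd_decay(pairs, bin_width_km = 0.5, floor = fl)
  analytic <- -d0 * log(fl)
  expect_lt(abs(dec$cutoff_km / analytic - 1), 0.2)
  expect_true(all(diff(dec$bins$prop_fit) <= 1e-12))  # monotone non-increasing

  # no identical pairs anywhere: cutoff 0
  none <- ibd_decay(tibble::tibble(distance_km = 1:10, identical = FALSE))
  expect_equal(none$cutoff_km, 0)
})

test_that("a panel of co-located clones is all-identical in the zero bin", {
  g <- matrix(rep(c(0L, 1L), 50), nrow = 100, ncol = 6)
  panel <- toy_panel(g, lat = rep(56, 6), lon = rep(14, 6))
  dec <- identity_vs_distance(panel, bin_width_km = 1)
  expect_equal(nrow(dec$bins), 1)
  expect_equal(dec$bins$prop_identical, 1)
  expect_true(is.na(dec$cutoff_km))  # single occupied bin: no decay to fit
})

test_that("potential-native flagging is boundary-inclusive and monotone", {
  site <- tibble::tibble(site_id = "SR", lat = 55.906, lon = 14.260)
  dlat <- (5.6 / 6371) * 180 / pi   # due-north displacement of exactly 5.6 km
  acc <- tibble::tibble(
    accession_id = c("at_site", "at_cutoff", "far", "nocoord"),
    lat = c(55.906, 55.906 + dlat, 56.9, NA),
    lon = c(14.260, 14.260, 14.260, NA)
  )
  fl <- flag_potential_natives(acc, site, cutoff_km = 5.6)
  expect_equal(fl$potential_native[fl$accession_id == "at_site"], TRUE)
  expect_equal(fl$distance_km[fl$accession_id == "at_cutoff"], 5.6, tolerance = 1e-9)
  # boundary inclusivity: an accession at exactly the cutoff distance is flagged
  d_exact <- fl$distance_km[fl$accession_id == "at_cutoff"]
  fl_exact <- flag_potential_natives(acc, site, cutoff_km = d_exact)
  expect_equal(fl_exact$potential_native[fl_exact$accession_id == "at_cutoff"], TRUE)
  expect_equal(fl$potential_native[fl$accession_id == "far"], FALSE)
  expect_true(is.na(fl$potential_native[fl$accession_id == "nocoord"]))
  expect_match(fl$note[fl$accession_id == "nocoord"], "unflaggable")
  expect_error(flag_potential_natives(acc, site, cutoff_km = 0), "positive")

  # flags at a smaller cutoff are a subset of flags at a larger one
  accs <- withr::with_seed(7, tibble::tibble(
    accession_id = sprintf("a%02d", 1:40),
    lat = 55.9 + stats::rnorm(40, 0, 0.15), lon = 14.26 + stats::rnorm(40, 0, 0.15)
  ))
  f_small <- flag_potential_natives(accs, site, cutoff_km = 3)
  f_big <- flag_potential_natives(accs, site, cutoff_km = 9)
  expect_true(all(f_big$potential_native[f_small$potential_native]))
})

test_that("frequency-outlier exclusion reproduces the worked rules", {
  flags_for <- function(comp) {
    tibble::tibble(
      accession_id = unique(comp$accessions$accession_id),
      site_id = "HOME",
      distance_km = ifelse(accession_id == "focal", 3.5, 50),
      potential_native = accession_id == "focal",
      note = NA_character_
    )
  }

  # home 33%, away 5.0/2.4/7.8%: ratio 4.2 >= 3 and 33% >= 10% -> excluded
  comp_var <- outlier_composition(0.33, c(0.050, 0.024, 0.078))
  out_var <- flag_frequency_outliers(comp_var, flags_for(comp_var))
  expect_true(out_var$excluded[out_var$accession_id == "focal" &
                                 out_var$site_id == "HOME"])

  # home 20%, away max 7.3%: ratio 2.7 < 3 -> not excluded under defaults,
  # but excluded in top-home mode (largest frequency at its home site)
  comp_bar <- outlier_composition(0.20, c(0.073, 0.05, 0.06))
  out_bar <- flag_frequency_outliers(comp_bar, flags_for(comp_bar))
  expect_false(out_bar$excluded[out_bar$accession_id == "focal" &
                                  out_bar$site_id == "HOME"])
  out_bar2 <- flag_frequency_outliers(comp_bar, flags_for(comp_bar),
                                      mode = "top_home")
  expect_true(out_bar2$excluded[out_bar2$accession_id == "focal" &
                                  out_bar2$site_id == "HOME"])

  # uniform composition: nothing excluded in either mode
  comp_unif <- outlier_composition(0.05, c(0.05, 0.05, 0.05))
  for (md in c("ratio", "top_home")) {
    out_u <- flag_frequency_outliers(comp_unif, flags_for(comp_unif), mode = md)
    expect_false(any(out_u$excluded))
  }
})

test_that("exclusion only renormalizes, never changes other counts", {
  comp <- outlier_composition(0.33, c(0.05))
  flags <- tibble::tibble(
    accession_id = unique(comp$accessions$accession_id), site_id = "HOME",
    distance_km = 3, potential_native = accession_id == "focal",
    note = NA_character_
  )
  excl <- flag_frequency_outliers(comp, flags)
  with_excl <- accession_frequencies(comp, excl)
  without <- accession_frequencies(comp)
  merged <- dplyr::inner_join(with_excl, without,
                              by = c("site_id", "accession_id"))
  expect_identical(merged$n.x, merged$n.y)
  # per-site included frequencies still sum to 1 after renormalization
  sums <- with_excl |>
    dplyr::filter(included) |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(s = sum(frequency))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})
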