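# Geographic filtering of cryptic native contamination.
#
# An experimental accession originally collected close to a field site may be
# indistinguishable from wild individuals of the local population; its
# frequency estimate at that site is then confounded. The filter combines an
# isolation-by-distance argument (genotype identity decays rapidly with
# distance, giving a km cutoff) with frequency-outlier rules.

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over rows.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
geo_distance <- function(lat1, lon1, lat2, lon2) {
  check_latlon(c(lat1, lat2), c(lon1, lon2))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}

#' Genotype-identity pairs by geographic distance
#'
#' All accession pairs of a panel, with their collection distance and whether
#' they are genotype-identical at the given mismatch ceiling (a small
#' nonzero ceiling tolerates genotyping error).
#'
#' @param panel A [genotype_panel()] with collection coordinates.
#' @param identity_mismatch_max Mismatch at or below which a pair counts as
#'   identical.
#' @return A tibble: `accession_1`, `accession_2`, `distance_km`,
#'   `identical`.
#' @export
panel_identity_pairs <- function(panel, identity_mismatch_max = 0.015) {
  stopifnot(inherits(panel, "genotype_panel"))
  acc <- panel$accessions
  if (nrow(acc) < 2) stop("need at least two accessions with coordinates", call. = FALSE)
  g <- panel$genotypes
  g1 <- (g == 1L) * 1; g1[is.na(g1)] <- 0
  g0 <- (g == 0L) * 1; g0[is.na(g0)] <- 0
  mis <- crossprod(g1, g0)
  mis <- mis + t(mis)
  inf <- crossprod(g1 + g0)
  rate <- ifelse(inf > 0, mis / inf, NA_real_)
  ij <- which(upper.tri(rate), arr.ind = TRUE)
  tibble::tibble(
    accession_1 = acc$accession_id[ij[, 1]],
    accession_2 = acc$accession_id[ij[, 2]],
    distance_km = geo_distance(
      acc$lat[ij[, 1]], acc$lon[ij[, 1]],
      acc$lat[ij[, 2]], acc$lon[ij[, 2]]
    ),
    identical = rate[ij] <= identity_mismatch_max
  )
}

# Weighted pool-adjacent-violators: monotone non-increasing fit of y on
# ascending x with weights w.
pava_decreasing <- function(y, w) {
  n <- length(y)
  yhat <- y
  wts <- w
  blocks <- as.list(seq_len(n))
  i <- 1
  while (i < length(yhat)) {
    if (yhat[i] < yhat[i + 1] - 1e-15) {
      merged_w <- wts[i] + wts[i + 1]
      merged_y <- (yhat[i] * wts[i] + yhat[i + 1] * wts[i + 1]) / merged_w
      yhat[i] <- merged_y
      wts[i] <- merged_w
      blocks[[i]] <- c(blocks[[i]], blocks[[i + 1]])
      yhat <- yhat[-(i + 1)]
      wts <- wts[-(i + 1)]
      blocks[[i + 1]] <- NULL
      if (i > 1) i <- i - 1
    } else {
      i <- i + 1
    }
  }
  out <- numeric(n)
  for (b in seq_along(blocks)) out[blocks[[b]]] <- yhat[b]
  out
}

#' Fit a monotone isolation-by-distance decay and locate its cutoff
#'
#' Bins identity/distance pairs, computes the proportion of identical pairs
#' per bin, fits a monotone non-increasing curve by weighted
#' pool-adjacent-violators, and reports the smallest distance at which the
#' fitted identity probability falls below `floor` (linear interpolation
#' between bin midpoints).
#'
#' @param pairs Tibble with columns `distance_km` and `identical` (logical),
#'   e.g. from [panel_identity_pairs()].
#' @param bin_width_km Width of the distance bins.
#' @param floor Identity probability defining the cutoff.
#' @return An object of class `ibd_decay`: `bins` (tibble `dist_mid`,
#'   `n_pairs`, `prop_identical`, `prop_fit`), `cutoff_km` (0 when no pair is
#'   identical anywhere; `NA` when the fit never falls below `floor` or only
#'   one bin is occupied), and `floor`.
#' @export
ibd_decay <- function(pairs, bin_width_km = 1, floor = 0.01) {
  stopifnot(all(c("distance_km", "identical") %in% names(pairs)))
  check_proportion(floor, "floor")
  if (!any(pairs$identical)) {
    return(structure(
      list(bins = tibble::tibble(
        dist_mid = numeric(0), n_pairs = integer(0),
        prop_identical = numeric(0), prop_fit = numeric(0)
      ), cutoff_km = 0, floor = floor),
      class = "ibd_decay"
    ))
  }
  bins <- pairs |>
    dplyr::mutate(bin = floor(.data$distance_km / bin_width_km)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      prop_identical = mean(.data$identical),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(dist_mid = (.data$bin + 0.5) * bin_width_km)
  if (nrow(bins) < 2) {
    # all pairs in one bin: no decay to fit, return the raw proportion
    bins$prop_fit <- bins$prop_identical
    return(structure(
      list(bins = bins[, c("dist_mid", "n_pairs", "prop_identical", "prop_fit")],
           cutoff_km = NA_real_, floor = floor),
      class = "ibd_decay"
    ))
  }
  bins$prop_fit <- pava_decreasing(bins$prop_identical, bins$n_pairs)
  below <- which(bins$prop_fit < floor)
  cutoff <- if (!length(below)) {
    NA_real_
  } else if (below[1] == 1) {
    bins$dist_mid[1]
  } else {
    i <- below[1]
    x0 <- bins$dist_mid[i - 1]; y0 <- bins$prop_fit[i - 1]
    x1 <- bins$dist_mid[i]; y1 <- bins$prop_fit[i]
    x0 + (y0 - floor) / (y0 - y1) * (x1 - x0)
  }
  structure(
    list(bins = bins[, c("dist_mid", "n_pairs", "prop_identical", "prop_fit")],
         cutoff_km = cutoff, floor = floor),
    class = "ibd_decay"
  )
}

#' @export
print.ibd_decay <- function(x, ...) {
  cat(sprintf(
    "<ibd_decay> %d bins; identity falls below %.3g at %.2f km\n",
    nrow(x$bins), x$floor, x$cutoff_km
  ))
  invisible(x)
}

#' Isolation-by-distance decay of a genotype panel
#'
#' Convenience chain: [panel_identity_pairs()] then [ibd_decay()].
#'
#' @inheritParams panel_identity_pairs
#' @inheritParams ibd_decay
#' @return An `ibd_decay` object.
#' @export
identity_vs_distance <- function(panel, identity_mismatch_max = 0.015,
                                 bin_width_km = 1, floor = 0.01) {
  ibd_decay(
    panel_identity_pairs(panel, identity_mismatch_max),
    bin_width_km = bin_width_km, floor = floor
  )
}

#' Flag accessions as potential natives at nearby sites
#'
#' An accession originally collected within `cutoff_km` of a field site
#' (boundary inclusive) is flagged: wild individuals genetically identical to
#' it could plausibly occur inside the experimental plots there.
#'
#' @param accessions Tibble with `accession_id`, `lat`, `lon`.
#' @param sites Tibble with `site_id`, `lat`, `lon`.
#' @param cutoff_km Distance cutoff in km (default 5.6).
#' @return A tibble: `accession_id`, `site_id`, `distance_km`,
#'   `potential_native` (logical; `NA` with a note when coordinates are
#'   missing), `note`.
#' @export
flag_potential_natives <- function(accessions, sites, cutoff_km = 5.6) {
  if (!is.numeric(cutoff_km) || cutoff_km <= 0) {
    stop("`cutoff_km` must be positive", call. = FALSE)
  }
  out <- tidyr::expand_grid(
    accession_id = accessions$accession_id,
    site_id = sites$site_id
  ) |>
    dplyr::left_join(
      dplyr::select(accessions, "accession_id", acc_lat = "lat", acc_lon = "lon"),
      by = "accession_id"
    ) |>
    dplyr::left_join(
      dplyr::select(sites, "site_id", site_lat = "lat", site_lon = "lon"),
      by = "site_id"
    )
  has_coords <- stats::complete.cases(out[, c("acc_lat", "acc_lon", "site_lat", "site_lon")])
  dist <- rep(NA_real_, nrow(out))
  if (any(has_coords)) {
    dist[has_coords] <- geo_distance(
      out$acc_lat[has_coords], out$acc_lon[has_coords],
      out$site_lat[has_coords], out$site_lon[has_coords]
    )
  }
  tibble::tibble(
    accession_id = out$accession_id,
    site_id = out$site_id,
    distance_km = dist,
    potential_native = ifelse(has_coords, dist <= cutoff_km, NA),
    note = ifelse(has_coords, NA_character_, "missing coordinates: unflaggable")
  )
}

#' Exclude potential natives that are frequency outliers
#'
#' A potential-native accession whose sampled frequency at its nearby
#' ("home") site is suspiciously high is excluded from fitness estimation
#' there. Two modes:
#' \describe{
#'   \item{`"ratio"`}{excluded iff home frequency `>= min_home_freq` AND home
#'     frequency `>= home_away_ratio` times its maximum frequency at other
#'     sites.}
#'   \item{`"top_home"`}{excluded iff it is a potential native and has the
#'     single largest frequency at that site (judgment-style rule).}
#' }
#'
#' @param composition A [summarize_composition()] result (experimental-class
#'   counts define the frequencies).
#' @param flags Output of [flag_potential_natives()].
#' @param home_away_ratio,min_home_freq Thresholds for `"ratio"` mode.
#' @param mode `"ratio"` (default) or `"top_home"`.
#' @return A tibble: `accession_id`, `site_id`, `distance_km`,
#'   `potential_native`, `frequency`, `max_away_frequency`, `excluded`,
#'   `reason`.
#' @export
flag_frequency_outliers <- function(composition, flags, home_away_ratio = 3.0,
                                    min_home_freq = 0.10,
                                    mode = c("ratio", "top_home")) {
  mode <- match.arg(mode)
  stopifnot(inherits(composition, "site_composition"))
  freqs <- composition$accessions |>
    dplyr::left_join(composition$n_experimental |>
                       dplyr::rename(n_site = "n"), by = "site_id") |>
    dplyr::mutate(frequency = ifelse(.data$n_site > 0, .data$n / .data$n_site, 0))
  away_max <- freqs |>
    dplyr::group_by(.data$accession_id) |>
    dplyr::mutate(
      max_away_frequency = purrr::map_dbl(
        seq_along(.data$frequency),
        ~ if (dplyr::n() > 1) max(.data$frequency[-.x]) else 0
      )
    ) |>
    dplyr::ungroup()
  top_at_site <- freqs |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(is_top = .data$frequency == max(.data$frequency) &
                    sum(.data$frequency == max(.data$frequency)) == 1) |>
    dplyr::ungroup() |>
    dplyr::select("site_id", "accession_id", "is_top")

  out <- flags |>
    dplyr::inner_join(
      dplyr::select(away_max, "site_id", "accession_id", "frequency",
                    "max_away_frequency"),
      by = c("accession_id", "site_id")
    ) |>
    dplyr::left_join(top_at_site, by = c("site_id", "accession_id"))
  pn <- !is.na(out$potential_native) & out$potential_native
  if (mode == "ratio") {
    out$excluded <- pn & out$frequency >= min_home_freq &
      out$frequency >= home_away_ratio * out$max_away_frequency
    out$reason <- ifelse(
      out$excluded,
      sprintf("potential native; home freq %.3f >= %.2g and >= %.1f x away max %.3f",
              out$frequency, min_home_freq, home_away_ratio, out$max_away_frequency),
      NA_character_
    )
  } else {
    out$excluded <- pn & !is.na(out$is_top) & out$is_top
    out$reason <- ifelse(out$excluded,
                         "potential native with the single largest home-site frequency",
                         NA_character_)
  }
  dplyr::select(out, "accession_id", "site_id", "distance_km",
                "potential_native", "frequency", "max_away_frequency",
                "excluded", "reason")
}
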