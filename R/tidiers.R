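# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a liability-threshold fit
#'
#' @param x A `liability_fit` from [fit_liability()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy liability_fit
#' @export
tidy.liability_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = c(x$se_alpha, x$se_beta)
  )
}

#' @rdname tidy.liability_fit
#' @return For `glance()`: a one-row tibble with `n_accessions`, `rss`,
#'   `weighted`, `converged`.
#' @method glance liability_fit
#' @export
glance.liability_fit <- function(x, ...) {
  tibble::tibble(
    n_accessions = x$n_accessions, rss = x$rss,
    weighted = x$weighted, converged = x$converged
  )
}

#' Tidy an effective-population-size estimate
#'
#' @param x An `ne_estimate` from [estimate_ne()].
#' @param ... Unused.
#' @return A one-row tibble: `site_id`, `n_sample`, `slope`, `ne`, `valid`,
#'   `n_snps`, `maf_floor`.
#' @method tidy ne_estimate
#' @export
tidy.ne_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("site_id", "n_sample", "slope", "ne",
                                 "valid", "n_snps", "maf_floor")])
}
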