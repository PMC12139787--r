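# Liability-threshold model linking survival between two environments.
#
# Each accession i has a Gaussian latent liability N(mu_i, sigma_site); it
# survives iff liability falls below the site threshold tau_site (survival is
# the cumulative probability up to the threshold; the harsher site has the
# lower threshold). Writing survival in the milder site A as
# p_A = Phi((tau_A - mu)/sigma_A), survival in the harsher site B is
#   p_B = 1/2 erfc( alpha/sqrt(2) + beta * erfcinv(2 p_A) ),
# with alpha = (tau_A - tau_B)/sigma_B and beta = sigma_A/sigma_B. Only
# (alpha, beta) are identifiable; the per-site (tau, sigma) and the mu_i live
# only in the simulator.

#' Predict harsh-site survival from mild-site survival
#'
#' Evaluates the liability-threshold map
#' `p_harsh = 1/2 erfc(alpha/sqrt(2) + beta * erfcinv(2 p_mild))`.
#' Strictly increasing in `p_mild`, mapping (0,1) to (0,1);
#' `alpha = 0, beta = 1` is the identity.
#'
#' @param p_mild Survival probability in the milder environment; values of
#'   exactly 0 or 1 are handled by their limits (0/1) with a warning.
#' @param alpha Threshold shift in harsh-site liability SD units.
#' @param beta Ratio of mild-site to harsh-site liability SD (positive).
#' @return Predicted harsh-site survival probabilities.
#' @export
predict_harsh <- function(p_mild, alpha, beta) {
  check_proportion(p_mild, "p_mild")
  if (any(beta <= 0)) stop("`beta` must be positive", call. = FALSE)
  if (any(p_mild %in% c(0, 1))) {
    warning("p_mild of exactly 0 or 1 mapped to its limit", call. = FALSE)
  }
  0.5 * erfc(alpha / sqrt(2) + beta * erfcinv(2 * p_mild))
}

#' Fit the liability-threshold map between two environments
#'
#' Nonlinear least squares of observed harsh-site survival on
#' [predict_harsh()] of observed mild-site survival, across accessions.
#' Weighted by harsh-site trial counts by default (binomial precision).
#' Mild-site proportions of exactly 0 or 1 are shrunk by a half-count
#' correction `(k + 0.5)/(n + 1)` before the inverse-erfc transform. The
#' optimizer is started from a coarse grid over `alpha` in [-3, 3] and
#' `beta` in (0, 4] and the best converged fit is kept.
#'
#' @param data Tibble with columns `p_mild`, `p_harsh` and trial counts
#'   `n_mild`, `n_harsh` (counts may be omitted when `weighted = FALSE`).
#' @param weighted Weight residuals by `n_harsh`?
#' @param subset Optional logical or integer vector selecting accessions
#'   (e.g. a single ancestry group).
#' @return An object of class `liability_fit`: `alpha`, `beta`, `se_alpha`,
#'   `se_beta`, `converged`, `n_accessions`, `rss`, plus the underlying
#'   `nls` fit.
#' @export
fit_liability <- function(data, weighted = TRUE, subset = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("p_mild", "p_harsh") %in% names(data)))
  if (!is.null(subset)) data <- data[subset, ]
  if (weighted && !"n_harsh" %in% names(data)) {
    stop("`n_harsh` trial counts are required for a weighted fit", call. = FALSE)
  }
  n_mild <- if ("n_mild" %in% names(data)) data$n_mild else rep(1e6, nrow(data))
  p_mild <- ifelse(
    data$p_mild <= 0 | data$p_mild >= 1,
    (data$p_mild * n_mild + 0.5) / (n_mild + 1),
    data$p_mild
  )
  keep <- !is.na(p_mild) & !is.na(data$p_harsh)
  d <- tibble::tibble(
    u = erfcinv(2 * p_mild[keep]),
    p_harsh = data$p_harsh[keep],
    w = if (weighted) data$n_harsh[keep] else rep(1, sum(keep))
  )
  if (nrow(d) < 3) stop("need >= 3 accessions with interior p_mild", call. = FALSE)
  if (stats::sd(d$u) < 1e-10) {
    stop("all mild-site survival probabilities identical: (alpha, beta) not identifiable",
         call. = FALSE)
  }

  starts <- expand.grid(alpha = seq(-3, 3, by = 1), beta = c(0.25, 0.5, 1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        p_harsh ~ 0.5 * erfc(alpha / sqrt(2) + beta * u),
        data = d, weights = d$w,
        start = list(alpha = starts$alpha[i], beta = starts$beta[i]),
        lower = c(alpha = -Inf, beta = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(d$w * stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("liability fit failed from every start", call. = FALSE)

  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) c(NA, NA))
  structure(
    list(
      alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
      se_alpha = unname(se[1]), se_beta = unname(se[2]),
      converged = best$fit$convInfo$isConv %||% TRUE,
      n_accessions = nrow(d), rss = best$rss,
      weighted = weighted, fit = best$fit, data = d
    ),
    class = "liability_fit"
  )
}

#' @export
print.liability_fit <- function(x, ...) {
  cat(sprintf(
    "<liability_fit> alpha = %.4f (SE %.4f), beta = %.4f (SE %.4f); %d accessions, %s\n",
    x$alpha, x$se_alpha, x$beta, x$se_beta, x$n_accessions,
    ifelse(x$converged, "converged", "NOT converged")
  ))
  invisible(x)
}

#' Simulate per-accession survival under the liability model
#'
#' Each accession's survival probability is `P(N(mu_i, sigma) < tau)`;
#' observed survivor counts are binomial at `n_trials` replicates.
#'
#' @param mu_per_accession Genetic liability means.
#' @param tau Site threshold (lower = harsher).
#' @param sigma Liability SD at the site (positive).
#' @param n_trials Replicates per accession.
#' @param seed Integer seed.
#' @param accession_id Optional labels.
#' @return A tibble: `accession_id`, `p_true`, `survived`, `total`, `p_hat`.
#' @export
simulate_survival <- function(mu_per_accession, tau, sigma, n_trials, seed = 1L,
                              accession_id = NULL) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  check_count(n_trials, "n_trials")
  p <- stats::pnorm((tau - mu_per_accession) / sigma)
  k <- withr::with_seed(as.integer(seed),
                        stats::rbinom(length(p), n_trials, p))
  tibble::tibble(
    accession_id = accession_id %||%
      sprintf("acc%03d", seq_along(mu_per_accession)),
    p_true = p, survived = k, total = n_trials, p_hat = k / n_trials
  )
}

#' Simulate a paired mild/harsh survival study
#'
#' Shared accession liability means, two environments with their own
#' thresholds and SDs. The implied identifiable parameters are
#' `alpha = (tau_mild - tau_harsh)/sigma_harsh` and
#' `beta = sigma_mild/sigma_harsh` (attached as attributes).
#'
#' @param mu_per_accession Genetic liability means.
#' @param tau_mild,tau_harsh Site thresholds (`tau_mild > tau_harsh` for a
#'   genuinely harsher second site).
#' @param sigma_mild,sigma_harsh Site liability SDs.
#' @param n_trials Replicates per accession per site.
#' @param seed Integer seed.
#' @return A tibble ready for [fit_liability()]: `accession_id`, `p_mild`,
#'   `n_mild`, `p_harsh`, `n_harsh` (plus true probabilities); attributes
#'   `alpha`, `beta`.
#' @export
simulate_survival_pair <- function(mu_per_accession, tau_mild, tau_harsh,
                                   sigma_mild = 1, sigma_harsh = 1,
                                   n_trials = 24, seed = 1L) {
  mild <- simulate_survival(mu_per_accession, tau_mild, sigma_mild, n_trials,
                            seed = derive_seed(seed, "mild"))
  harsh <- simulate_survival(mu_per_accession, tau_harsh, sigma_harsh, n_trials,
                             seed = derive_seed(seed, "harsh"))
  out <- tibble::tibble(
    accession_id = mild$accession_id,
    p_mild = mild$p_hat, n_mild = mild$total, p_mild_true = mild$p_true,
    p_harsh = harsh$p_hat, n_harsh = harsh$total, p_harsh_true = harsh$p_true
  )
  attr(out, "alpha") <- (tau_mild - tau_harsh) / sigma_harsh
  attr(out, "beta") <- sigma_mild / sigma_harsh
  out
}
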