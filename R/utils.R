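# Internal helpers: seed streams, error-function utilities, input checks.

#' Derive a deterministic child seed for a named pipeline stage
#'
#' All randomness in the package flows from one root seed. Each stage draws
#' from its own substream, derived deterministically from the root seed and a
#' stage label, so adding or reordering stages never perturbs the others.
#'
#' @param seed Integer root seed.
#' @param stage Character stage label (e.g. `"panel"`, `"site:SR"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 30011) %% 2147483646 + 1)
}

# complementary error function and its inverse, in terms of the normal cdf
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
erfcinv <- function(y) -stats::qnorm(y / 2) / sqrt(2)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_proportion <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x != floor(x))) {
    stop(sprintf("`%s` must be an integer count >= %d", name, min), call. = FALSE)
  }
  invisible(x)
}

check_latlon <- function(lat, lon) {
  bad <- (!is.na(lat) & (lat < -90 | lat > 90)) | (!is.na(lon) & (lon < -180 | lon > 180))
  if (any(bad)) stop("latitude must lie in [-90, 90] and longitude in [-180, 180]", call. = FALSE)
  invisible(NULL)
}
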