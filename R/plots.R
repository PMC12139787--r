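# ggplot2 visualizations of the main result types.

#' Manhattan-style plot of a combined drift scan
#'
#' @param combined Output of [combine_experiments()].
#' @param top_quantile Highlight SNPs above this quantile of the combined
#'   score's `-log10` (default 0.999).
#' @return A ggplot object.
#' @export
plot_drift_scan <- function(combined, top_quantile = 0.999) {
  stopifnot(all(c("pos", "neg_log10_combined") %in% names(combined)))
  thr <- stats::quantile(combined$neg_log10_combined, top_quantile, names = FALSE)
  ggplot2::ggplot(combined, ggplot2::aes(x = .data$pos,
                                         y = .data$neg_log10_combined)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$neg_log10_combined >= thr),
                        size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red3")) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position", y = expression(-log[10] ~ "combined score")) +
    ggplot2::theme_minimal()
}

#' @method autoplot ibd_decay
#' @export
autoplot.ibd_decay <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$dist_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop_identical,
                                     size = .data$n_pairs), alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$prop_fit), colour = "red3") +
    ggplot2::geom_hline(yintercept = object$floor, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$cutoff_km, linetype = "dotted") +
    ggplot2::labs(x = "distance (km)", y = "proportion genotype-identical",
                  size = "pairs") +
    ggplot2::theme_minimal()
}

#' @method autoplot liability_fit
#' @export
autoplot.liability_fit <- function(object, ...) {
  grid <- tibble::tibble(
    p_mild = seq(0.001, 0.999, length.out = 200)
  )
  grid$p_harsh <- predict_harsh(grid$p_mild, object$alpha, object$beta)
  pts <- tibble::tibble(
    p_mild = 0.5 * erfc(object$data$u),
    p_harsh = object$data$p_harsh
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$p_mild, y = .data$p_harsh)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "red3") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "survival, milder site", y = "survival, harsher site") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
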