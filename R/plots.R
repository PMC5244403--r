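#' Forest plot of per-SNP and combined MR estimates
#'
#' Draws each instrument's Wald-ratio odds ratio with its 95% CI, plus the
#' combined estimates, on a log-scaled axis with a reference line at OR 1.
#'
#' @param per_snp A per-SNP table from [per_snp_estimates()].
#' @param estimates Optional estimates tibble (rows on the
#'   `per_unit_log_odds` scale are shown below the SNPs).
#' @return A ggplot object.
#' @export
plot_forest <- function(per_snp, estimates = NULL) {
  rows <- dplyr::transmute(per_snp, label = .data$snp_id, or = .data$or,
                           lo = .data$or_ci_low, hi = .data$or_ci_high,
                           kind = "SNP")
  if (!is.null(estimates)) {
    comb <- dplyr::filter(estimates, .data$scale == "per_unit_log_odds",
                          .data$method != "egger_intercept")
    rows <- dplyr::bind_rows(rows, dplyr::transmute(
      comb, label = .data$method, or = .data$or, lo = .data$or_ci_low,
      hi = .data$or_ci_high, kind = "combined"))
  }
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$or, y = .data$label,
                                     colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_forest Forest plot for a full analysis object.
#' @param object An `mr_analysis` object.
#' @param ... Unused.
#' @export
autoplot.mr_analysis <- function(object, ...) {
  plot_forest(object$per_snp, object$estimates) +
    ggplot2::ggtitle(object$config$direction_label)
}
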