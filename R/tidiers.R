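#' Tidy an MR analysis into one row per estimate
#'
#' @param x An `mr_analysis` object.
#' @param ... Unused.
#' @return The estimates tibble: one row per estimator and scale with
#'   log-scale and odds-ratio-scale columns.
#' @export
tidy.mr_analysis <- function(x, ...) {
  x$estimates
}

#' One-row summary of an MR analysis
#'
#' @param x An `mr_analysis` object.
#' @param ... Unused.
#' @return One-row tibble: instrument counts at each filtering stage, the
#'   primary (fixed-effects IVW, per-unit) estimate, and heterogeneity.
#' @export
glance.mr_analysis <- function(x, ...) {
  primary <- dplyr::filter(x$estimates, .data$method == "ivw_fixed",
                           .data$scale == "per_unit_log_odds")
  n_of <- function(stage) {
    n <- x$counts$n[x$counts$stage == stage]
    if (length(n) == 1) n else NA_integer_
  }
  tibble(
    direction = x$config$direction_label,
    n_read = n_of("read_exposure"),
    n_p_filtered = n_of("p_filtered"),
    n_pruned = n_of("pruned"),
    n_harmonized = n_of("harmonized"),
    beta_ivw = primary$beta[1], se_ivw = primary$se[1],
    or_ivw = primary$or[1], p_ivw = primary$p_value[1],
    q = if (!is.null(x$heterogeneity)) x$heterogeneity$q else NA_real_,
    q_p = if (!is.null(x$heterogeneity)) x$heterogeneity$p_value else NA_real_,
    i2 = if (!is.null(x$heterogeneity)) x$heterogeneity$i2 else NA_real_
  )
}
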