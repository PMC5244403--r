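#' Convert an estimate to the per-doubling-of-odds scale
#'
#' An effect per 1-unit increase in the log odds of a binary exposure is
#' hard to interpret; multiplying the log effect (and its SE and CI
#' endpoints) by the log of 2 re-expresses it per doubling of the exposure
#' odds. On the odds-ratio scale this is `OR_new = OR_old ^ factor`. The
#' default factor is the conventional rounded constant 0.693; set
#' `exact_ln2 = TRUE` for `log(2)`. P-values are unchanged: beta and se are
#' scaled identically, so the z statistic is untouched.
#'
#' @param est An estimate tibble on the `per_unit_log_odds` scale.
#' @param exact_ln2 Use `log(2)` instead of 0.693.
#' @return The estimate tibble with beta, se and CI scaled and
#'   `scale = "per_doubling"`.
#' @export
#' @examples
#' per_doubling(ivw_fixed(table1_fixture()))
per_doubling <- function(est, exact_ln2 = FALSE) {
  if (any(est$scale != "per_unit_log_odds")) {
    abort("estimate is already on the per-doubling scale (or unlabelled); refusing to convert twice")
  }
  f <- if (exact_ln2) log(2) else 0.693
  dplyr::mutate(est,
    beta = .data$beta * f, se = .data$se * f,
    ci_low = .data$ci_low * f, ci_high = .data$ci_high * f,
    scale = "per_doubling")
}

#' Express an estimate on the odds-ratio scale
#'
#' Exponentiates the log-scale effect and its confidence limits. The
#' p-value is carried over unchanged.
#'
#' @param est An estimate tibble.
#' @return The input with columns `or, or_ci_low, or_ci_high` appended.
#' @export
#' @examples
#' or_with_ci(ivw_fixed(table1_fixture()))
or_with_ci <- function(est) {
  dplyr::mutate(est,
    or = exp(.data$beta),
    or_ci_low = exp(.data$ci_low),
    or_ci_high = exp(.data$ci_high))
}

#' Approximate power for summary-data MR with a binary outcome
#'
#' Standard normal approximation: the expected association z statistic for
#' a causal odds ratio `or_alternative` is
#' `z = |ln OR| * sqrt(n * r2 * k * (1 - k))` with `n` the outcome sample
#' size, `k` the case fraction and `r2` the variance in the exposure
#' explained by the instruments; power for a two-sided test is
#' `Phi(z - z_(1-alpha/2))`. Monotone increasing in `n`, `r2` and `|ln OR|`.
#'
#' @param n_outcome Outcome-study sample size (cases + controls).
#' @param case_fraction Proportion of cases in the outcome study, in (0,1).
#' @param r2_exposure Variance in the exposure explained by the instruments,
#'   as a fraction in (0,1) (e.g. 0.0003 for 0.03%).
#' @param or_alternative Causal odds ratio under the alternative.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power as a single number in \[0, 1\].
#' @export
#' @examples
#' power_binary_outcome(150064, 0.2465, 0.0003, 1.1)
power_binary_outcome <- function(n_outcome, case_fraction, r2_exposure,
                                 or_alternative, alpha = 0.05) {
  stopifnot(n_outcome >= 1, case_fraction > 0, case_fraction < 1,
            r2_exposure > 0, r2_exposure < 1, or_alternative > 0,
            alpha > 0, alpha < 1)
  z <- abs(log(or_alternative)) *
    sqrt(n_outcome * r2_exposure * case_fraction * (1 - case_fraction))
  pnorm(z - qnorm(1 - alpha / 2))
}
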