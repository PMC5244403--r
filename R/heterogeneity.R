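#' Cochran's Q and I-squared heterogeneity across per-SNP ratio estimates
#'
#' With `ratio_j = by_j / bx_j` and weights `w_j = (bx_j / se_y_j)^2`,
#' `Q = sum w_j (ratio_j - beta_ivw)^2` around the fixed-effects IVW
#' estimate, referred to a chi-square on `n - 1` degrees of freedom.
#' `I2 = max(0, 100 (Q - df) / Q)` is the percentage of variation across
#' instruments beyond chance, with a test-based (Higgins-Thompson)
#' confidence interval from the log of `H = sqrt(Q/df)`, truncated to
#' \[0, 100\].
#'
#' @param set A harmonized set with at least two instruments.
#' @param conf_level Confidence level for the I-squared interval.
#' @return A one-row tibble: `q, df, p_value, i2, i2_ci_low, i2_ci_high`.
#' @export
#' @examples
#' cochran_q(table1_fixture())
cochran_q <- function(set, conf_level = 0.95) {
  check_harmonized(set, min_n = 2L)
  if (any(set$bx == 0)) abort("all SNP-exposure coefficients must be nonzero")
  ratio <- set$by / set$bx
  w <- (set$bx / set$se_y)^2
  beta_fe <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - beta_fe)^2)
  k <- nrow(set)
  df <- k - 1L
  p <- pchisq(q, df, lower.tail = FALSE)
  i2 <- max(0, 100 * (q - df) / q)
  if (q == 0) i2 <- 0

  # Higgins-Thompson test-based interval on ln H
  se_ln_h <- if (q > k) {
    0.5 * (log(q) - log(df)) / (sqrt(2 * q) - sqrt(2 * k - 3))
  } else if (k > 2) {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    NA_real_
  }
  zc <- qnorm(1 - (1 - conf_level) / 2)
  h <- max(1, sqrt(q / df))
  if (is.na(se_ln_h)) {
    ci <- c(0, 100)
  } else {
    h_ci <- exp(log(h) + c(-1, 1) * zc * se_ln_h)
    h_ci <- pmax(h_ci, 1)
    ci <- pmin(pmax(100 * (h_ci^2 - 1) / h_ci^2, 0), 100)
  }
  tibble(q = q, df = df, p_value = p, i2 = i2,
         i2_ci_low = ci[1], i2_ci_high = ci[2])
}
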