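#' @noRd
new_estimate <- function(method, n_snps, beta, se, conf_level = 0.95,
                         scale = "per_unit_log_odds", p_value = NULL,
                         ci = NULL) {
  # conventional 1.96 multiplier at the default level (reported intervals
  # in this literature use it verbatim)
  z <- if (conf_level == 0.95) 1.96 else qnorm(1 - (1 - conf_level) / 2)
  if (is.null(p_value)) {
    p_value <- if (se > 0) 2 * pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  }
  if (is.null(ci)) ci <- beta + c(-1, 1) * z * se
  tibble(method = method, n_snps = as.integer(n_snps), beta = beta, se = se,
         ci_low = ci[1], ci_high = ci[2], p_value = p_value, scale = scale)
}

#' Single-SNP Wald ratio estimate
#'
#' The causal effect implied by one instrument: the SNP-outcome coefficient
#' divided by the SNP-exposure coefficient. The first-order standard error
#' `se_y / |bx|` ignores uncertainty in the exposure coefficient; the
#' second-order delta-method error `sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4)`
#' propagates it.
#'
#' @param inst A one-row harmonized set (or any data frame with columns
#'   `bx, se_x, by, se_y`).
#' @param se_method `"first_order"` (default; matches the IVW weight
#'   construction) or `"second_order"`.
#' @return A one-row estimate tibble with columns
#'   `method, n_snps, beta, se, ci_low, ci_high, p_value, scale`.
#' @export
#' @examples
#' wald_ratio(table1_fixture()[1, ])
wald_ratio <- function(inst, se_method = c("first_order", "second_order")) {
  se_method <- match.arg(se_method)
  check_harmonized(inst, min_n = 1L)
  if (nrow(inst) != 1) abort("wald_ratio takes a single instrument; see per_snp_estimates()")
  if (inst$bx == 0) abort("undefined ratio: SNP-exposure coefficient is zero")
  beta <- inst$by / inst$bx
  se <- switch(se_method,
    first_order  = inst$se_y / abs(inst$bx),
    second_order = sqrt(inst$se_y^2 / inst$bx^2 + inst$by^2 * inst$se_x^2 / inst$bx^4)
  )
  new_estimate("wald", 1L, beta, se)
}

ivw_components <- function(set) {
  list(sxy = sum(set$bx * set$by / set$se_y^2),
       sxx = sum(set$bx^2 / set$se_y^2))
}

#' Fixed-effects inverse-variance-weighted estimate
#'
#' Combines per-SNP Wald ratios weighted by their inverse first-order
#' variances: `beta = sum(bx by / se_y^2) / sum(bx^2 / se_y^2)`,
#' `se = 1 / sqrt(sum(bx^2 / se_y^2))`. Identical to the slope of a
#' zero-intercept regression of the SNP-outcome on the SNP-exposure
#' coefficients with weights `1/se_y^2`.
#'
#' @param set A harmonized set (all `bx` nonzero).
#' @return A one-row estimate tibble (see [wald_ratio()]).
#' @export
#' @examples
#' ivw_fixed(table1_fixture())
ivw_fixed <- function(set) {
  check_harmonized(set, min_n = 1L)
  if (any(set$bx == 0)) abort("all SNP-exposure coefficients must be nonzero")
  cmp <- ivw_components(set)
  new_estimate("ivw_fixed", nrow(set), cmp$sxy / cmp$sxx, 1 / sqrt(cmp$sxx))
}

#' Random-effects (DerSimonian-Laird) inverse-variance-weighted estimate
#'
#' Additive random-effects meta-analysis of the per-SNP Wald ratios. The
#' between-SNP variance is the DerSimonian-Laird moment estimate
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` computed from the
#' fixed-effects Cochran's Q; ratios are then re-weighted by
#' `1 / (se_ratio^2 + tau2)`. When `tau2 = 0` the estimate equals
#' [ivw_fixed()] exactly.
#'
#' @param set A harmonized set with at least two instruments.
#' @return A one-row estimate tibble.
#' @export
ivw_random <- function(set) {
  check_harmonized(set, min_n = 2L)
  if (any(set$bx == 0)) abort("all SNP-exposure coefficients must be nonzero")
  ratio <- set$by / set$bx
  w <- (set$bx / set$se_y)^2
  beta_fe <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - beta_fe)^2)
  df <- nrow(set) - 1L
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (1 / w + tau2)
  new_estimate("ivw_random", nrow(set), sum(w_re * ratio) / sum(w_re),
               1 / sqrt(sum(w_re)))
}

build_omega <- function(set, ld) {
  r <- ld_submatrix(ld, set$snp_id)
  off <- r; diag(off) <- 0
  if (any(abs(off) >= 0.999)) {
    abort("near-singular outcome covariance: a pair of instruments has |r| >= 0.999; prune first")
  }
  outer(set$se_y, set$se_y) * r
}

#' IVW estimate for correlated instruments (generalized least squares)
#'
#' When instruments are in linkage disequilibrium their outcome coefficients
#' are correlated; the outcome covariance is
#' `Omega[j,k] = se_y[j] se_y[k] r[j,k]` with `r` the signed LD correlation.
#' The estimate is the GLS solution
#' `beta = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by` with
#' `se = sqrt((bx' Omega^-1 bx)^-1)`. With an identity correlation matrix
#' this reduces to [ivw_fixed()] exactly.
#'
#' @param set A harmonized set.
#' @param ld An [ld_matrix()] covering the instruments.
#' @return A one-row estimate tibble.
#' @export
ivw_correlated <- function(set, ld) {
  check_harmonized(set, min_n = 1L)
  omega <- build_omega(set, ld)
  oi_bx <- solve(omega, set$bx)
  prec <- sum(set$bx * oi_bx)
  new_estimate("ivw_correlated", nrow(set),
               sum(oi_bx * set$by) / prec, 1 / sqrt(prec))
}

profile_xi <- function(beta, bx, by, sx2, omega_inv) {
  # for fixed beta, the true SNP-exposure effects maximizing the likelihood
  a <- diag(1 / sx2, length(bx)) + beta^2 * omega_inv
  solve(a, bx / sx2 + beta * (omega_inv %*% by))
}

profile_loglik <- function(beta, bx, by, sx2, omega_inv) {
  xi <- profile_xi(beta, bx, by, sx2, omega_inv)
  rx <- bx - xi
  ry <- by - beta * xi
  -0.5 * (sum(rx^2 / sx2) + sum(ry * (omega_inv %*% ry)))
}

#' Maximum-likelihood estimate for correlated instruments
#'
#' Bivariate likelihood treating the true SNP-exposure effects as nuisance
#' parameters: `bx_j ~ N(xi_j, se_x_j^2)` independently, and
#' `by ~ N(beta * xi, Omega)` jointly with `Omega` as in
#' [ivw_correlated()]. The causal effect is found by maximizing the profile
#' log-likelihood over `beta` (the `xi` maximizer is available in closed
#' form), with the standard error from the observed profile information.
#' As `se_x -> 0` the estimate converges to the GLS solution.
#'
#' @param set A harmonized set with positive `se_x` for every instrument.
#' @param ld An [ld_matrix()] covering the instruments.
#' @param interval Search interval for the causal effect (default spans
#'   10 standard errors around the GLS estimate).
#' @return A one-row estimate tibble.
#' @export
ml_correlated <- function(set, ld, interval = NULL) {
  check_harmonized(set, min_n = 1L)
  if (any(set$se_x <= 0)) abort("ml_correlated needs positive se_x for every instrument")
  omega <- build_omega(set, ld)
  omega_inv <- solve(omega)
  sx2 <- set$se_x^2
  gls <- ivw_correlated(set, ld)
  if (is.null(interval)) {
    interval <- gls$beta + c(-10, 10) * max(gls$se, 1e-6)
  }
  ll <- function(b) profile_loglik(b, set$bx, set$by, sx2, omega_inv)
  opt <- optimize(ll, interval = interval, maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  beta_hat <- opt$maximum
  if (min(abs(beta_hat - interval)) < 1e-6 * diff(interval)) {
    abort("profile-likelihood maximization hit the search boundary; widen `interval`",
          class = "mrsum_convergence_error")
  }
  h <- 1e-4 * max(1, abs(beta_hat))
  info <- -(ll(beta_hat + h) - 2 * ll(beta_hat) + ll(beta_hat - h)) / h^2
  if (!is.finite(info) || info <= 0) {
    abort("observed information not positive at the optimum",
          class = "mrsum_convergence_error")
  }
  new_estimate("ml_correlated", nrow(set), beta_hat, 1 / sqrt(info))
}

#' MR-Egger regression
#'
#' Weighted regression of the SNP-outcome on the SNP-exposure coefficients
#' with a free intercept, weights `1/se_y^2`. Instruments are first oriented
#' so every exposure coefficient is non-negative (negating both coefficients
#' where needed), making the fit invariant to arbitrary allele coding. The
#' intercept estimates the average directional pleiotropic effect and its
#' test is the pleiotropy test; the slope is a pleiotropy-adjusted causal
#' estimate (consistent under the InSIDE assumption that pleiotropic effects
#' are independent of instrument strength).
#'
#' @param set A harmonized set with at least three instruments.
#' @param t_dist Use t(n-2) rather than normal reference for CIs and
#'   p-values (default `FALSE`; normal is the summary-data MR convention).
#' @return A two-row estimate tibble: methods `egger_slope` and
#'   `egger_intercept`.
#' @export
mr_egger <- function(set, t_dist = FALSE) {
  check_harmonized(set, min_n = 3L)
  flip <- sign(set$bx) < 0
  bx <- abs(set$bx)
  by <- ifelse(flip, -set$by, set$by)
  if (diff(range(bx)) == 0) {
    abort("all exposure coefficients equal after orientation: intercept and slope are collinear")
  }
  fit <- lm(by ~ bx, weights = 1 / set$se_y^2)
  cf <- summary(fit)$coefficients
  n <- nrow(set)
  mult <- if (t_dist) qt(0.975, n - 2) else 1.96
  pfun <- function(est, se) {
    if (se == 0) return(as.numeric(est == 0))
    z <- est / se
    if (t_dist) 2 * pt(-abs(z), n - 2) else 2 * pnorm(-abs(z))
  }
  mk <- function(method, row) {
    est <- cf[row, "Estimate"]; se <- cf[row, "Std. Error"]
    new_estimate(method, n, est, se, p_value = pfun(est, se),
                 ci = est + c(-1, 1) * mult * se)
  }
  dplyr::bind_rows(mk("egger_slope", "bx"), mk("egger_intercept", "(Intercept)"))
}
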