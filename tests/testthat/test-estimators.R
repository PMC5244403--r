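test_that("wald ratio matches hand division of the four-SNP fixture", {
  f <- table1_fixture()
  est <- wald_ratio(f[1, ])  # rs6265
  expect_equal(est$beta, -0.052 / -0.061)
  expect_equal(est$beta, 0.85246, tolerance = 1e-4)
  expect_equal(est$se, 0.013 / 0.061)
  expect_equal(est$se, 0.21311, tolerance = 1e-4)
  expect_equal(est$ci_low, est$beta - 1.96 * est$se)

  # second-order se propagates exposure uncertainty and reduces to
  # first-order when se_x = 0
  est2 <- wald_ratio(f[1, ], se_method = "second_order")
  expect_equal(est2$se,
               sqrt(0.013^2 / 0.061^2 + 0.052^2 * 0.011^2 / 0.061^4))
  nox <- tibble::tibble(snp_id = "rs1", bx = 1, se_x = 0, by = 0.5, se_y = 0.1)
  expect_equal(wald_ratio(nox, "second_order")$se, wald_ratio(nox, "first_order")$se)

  # null outcome effect
  null <- tibble::tibble(snp_id = "rs1", bx = 0.1, se_x = 0.01, by = 0, se_y = 0.1)
  est0 <- wald_ratio(null)
  expect_equal(est0$beta, 0)
  expect_equal(est0$p_value, 1)

  zero <- tibble::tibble(snp_id = "rs1", bx = 0, se_x = 0.01, by = 0.1, se_y = 0.1)
  expect_error(wald_ratio(zero), "undefined ratio")
  expect_error(wald_ratio(f), "single instrument")
})

test_that("fixed-effects IVW reproduces the four-SNP worked example", {
  f <- table1_fixture()
  est <- ivw_fixed(f)
  expect_equal(est$beta, 0.7727374804, tolerance = 1e-9)
  expect_equal(est$se, 0.1124750973, tolerance = 1e-9)
  expect_equal(round(exp(est$beta), 2), 2.17)
  expect_equal(est$n_snps, 4L)

  # a single instrument reduces to the first-order Wald ratio
  expect_equal(ivw_fixed(f[1, ])$beta, wald_ratio(f[1, ])$beta)
  expect_equal(ivw_fixed(f[1, ])$se, wald_ratio(f[1, ])$se)

  # duplicating an instrument doubles its weight: beta unchanged, se / sqrt(2)
  dup <- dplyr::bind_rows(f[1, ], dplyr::mutate(f[1, ], snp_id = "rs6265b"))
  expect_equal(ivw_fixed(dup)$beta, wald_ratio(f[1, ])$beta)
  expect_equal(ivw_fixed(dup)$se, wald_ratio(f[1, ])$se / sqrt(2))

  expect_error(ivw_fixed(f[0, ]), "at least 1")
})

test_that("IVW analytic formula equals zero-intercept weighted regression", {
  for (seed in 1:100) {
    set <- random_set(n = 3 + seed %% 10, seed = seed)
    analytic <- ivw_fixed(set)
    fit <- lm(by ~ 0 + bx, data = set, weights = 1 / set$se_y^2)
    expect_equal(analytic$beta, unname(coef(fit)["bx"]), tolerance = 1e-11)
  }
})

test_that("random-effects IVW is DerSimonian-Laird over the Wald ratios", {
  f <- table1_fixture()
  # Q = 0.266 < 3 df, so tau2 = 0 and the estimate equals fixed effects
  re <- ivw_random(f)
  fe <- ivw_fixed(f)
  expect_equal(re$beta, fe$beta)
  expect_equal(re$se, fe$se)

  # homogeneous ratios: exactly fixed effects
  hom <- tibble::tibble(snp_id = c("rs1", "rs2"), bx = c(0.1, 0.2),
                        se_x = 0.01, by = c(0.05, 0.10), se_y = c(0.01, 0.02))
  expect_equal(ivw_random(hom)$beta, ivw_fixed(hom)$beta)

  # two instruments with ratios 0 and 1 and equal ratio precision
  sym <- tibble::tibble(snp_id = c("rs1", "rs2"), bx = c(0.1, 0.1),
                        se_x = 0.01, by = c(0, 0.1), se_y = 0.013)
  expect_equal(ivw_random(sym)$beta, 0.5)

  expect_error(ivw_random(f[1, ]), "at least 2")

  # independent cross-check against metafor's DL implementation
  set <- random_set(30, seed = 202)
  set$by <- set$by + withr::with_seed(9, rnorm(30, 0, 0.05))  # real heterogeneity
  ours <- ivw_random(set)
  ref <- metafor::rma(yi = set$by / set$bx, sei = set$se_y / abs(set$bx),
                      method = "DL")
  expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se, ref$se, tolerance = 1e-8)
})

test_that("correlated-instrument GLS handles LD correctly", {
  f <- table1_fixture()
  identity_ld <- ld_matrix(diag(4), snp_ids = f$snp_id)
  gls <- ivw_correlated(f, identity_ld)
  fe <- ivw_fixed(f)
  expect_equal(gls$beta, fe$beta, tolerance = 1e-14)
  expect_equal(gls$se, fe$se, tolerance = 1e-14)

  # two near-copies of one instrument carry the information of one:
  # brute-force 2x2 inverse oracle, se within 0.5% of the single-SNP Wald se
  two <- dplyr::bind_rows(f[1, ], dplyr::mutate(f[1, ], snp_id = "rs6265b"))
  r <- 0.99
  ld2 <- ld_matrix(matrix(c(1, r, r, 1), 2), snp_ids = two$snp_id)
  est2 <- ivw_correlated(two, ld2)
  se_oracle <- two$se_y[1] * sqrt((1 + r) / 2) / abs(two$bx[1])
  expect_equal(est2$se, se_oracle, tolerance = 1e-10)
  expect_lt(abs(est2$se - wald_ratio(f[1, ])$se) / wald_ratio(f[1, ])$se, 0.005)

  # negatively correlated errors are mutually informative: smaller se
  ldneg <- ld_matrix(matrix(c(1, -0.5, -0.5, 1), 2), snp_ids = two$snp_id)
  ld0 <- ld_matrix(diag(2), snp_ids = two$snp_id)
  expect_lt(ivw_correlated(two, ldneg)$se, ivw_correlated(two, ld0)$se)

  # numerically singular correlation is refused with advice
  ld_sing <- ld_matrix(matrix(c(1, 0.9995, 0.9995, 1), 2), snp_ids = two$snp_id)
  expect_error(ivw_correlated(two, ld_sing), "prune")
})

test_that("profile-ML agrees with GLS in the small-measurement-error limit", {
  f <- table1_fixture()
  identity_ld <- ld_matrix(diag(4), snp_ids = f$snp_id)
  tiny <- dplyr::mutate(f, se_x = 1e-8)
  ml <- ml_correlated(tiny, identity_ld)
  expect_equal(ml$beta, 0.7727374804, tolerance = 1e-4)
  expect_lt(abs(ml$se - ivw_fixed(f)$se) / ivw_fixed(f)$se, 0.01)

  # the same limit under real correlation
  ld <- exchangeable_ld(f$snp_id, 0.3)
  pos <- orient_positive(tiny)
  expect_equal(ml_correlated(pos, ld)$beta, ivw_correlated(pos, ld)$beta,
               tolerance = 1e-5)

  # single SNP: saturated model, exact ratio
  one <- ml_correlated(f[1, ], ld_matrix(diag(1), snp_ids = f$snp_id[1]))
  expect_equal(one$beta, f$by[1] / f$bx[1], tolerance = 1e-6)

  # with real exposure noise the ML se exceeds the GLS se
  expect_gt(ml_correlated(f, identity_ld)$se, ivw_correlated(f, identity_ld)$se)
})

test_that("profile-ML recovers the causal effect on simulated instruments", {
  reps <- 200
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- simulate_two_sample(n_snps = 10, true_beta = 0.3, se_x = 0.002,
                               se_y = 0.005, seed = 5000 + i)
    set <- sim_to_set(sim)
    est[i] <- ml_correlated(set, ld_matrix(diag(10), snp_ids = set$snp_id))$beta
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.3), 3 * mc_se)
})

test_that("MR-Egger recovers slope and intercept on constructed data", {
  # exact proportionality: slope = causal effect, intercept = 0
  lin <- tibble::tibble(snp_id = paste0("rs", 1:5), bx = seq(0.1, 0.5, 0.1),
                        se_x = 0.01, by = 0.4 * seq(0.1, 0.5, 0.1), se_y = 0.01)
  est <- mr_egger(lin)
  expect_equal(est$beta[est$method == "egger_slope"], 0.4)
  expect_equal(est$beta[est$method == "egger_intercept"], 0, tolerance = 1e-12)

  # exact affine data: intercept is the common pleiotropic effect
  aff <- dplyr::mutate(lin, by = 0.1 + 0.4 * bx)
  est_aff <- mr_egger(aff)
  expect_equal(est_aff$beta[est_aff$method == "egger_slope"], 0.4)
  expect_equal(est_aff$beta[est_aff$method == "egger_intercept"], 0.1)

  # three points, equal weights: ordinary least squares by hand
  three <- tibble::tibble(snp_id = paste0("rs", 1:3), bx = c(0.1, 0.2, 0.3),
                          se_x = 0.01, by = c(0.25, 0.40, 0.55), se_y = 0.02)
  est3 <- mr_egger(three)
  expect_equal(est3$beta[est3$method == "egger_slope"], 1.5)
  expect_equal(est3$beta[est3$method == "egger_intercept"], 0.1)

  # weighted-regression se cross-check against the closed form
  set <- random_set(15, seed = 31)
  w <- 1 / set$se_y^2
  xb <- sum(w * set$bx) / sum(w); yb <- sum(w * set$by) / sum(w)
  sxx <- sum(w * (set$bx - xb)^2)
  slope <- sum(w * (set$bx - xb) * (set$by - yb)) / sxx
  resid <- set$by - (yb - slope * xb) - slope * set$bx
  sigma2 <- sum(w * resid^2) / (15 - 2)
  oracle <- mr_egger(set)
  expect_equal(oracle$beta[1], slope, tolerance = 1e-10)
  expect_equal(oracle$se[1], sqrt(sigma2 / sxx), tolerance = 1e-10)

  expect_error(mr_egger(lin[1:2, ]), "at least 3")
  coll <- dplyr::mutate(lin, bx = 0.2)
  expect_error(mr_egger(coll), "collinear")

  # t-reference CIs are wider than normal ones at small n
  expect_gt(mr_egger(three, t_dist = TRUE)$ci_high[1], est3$ci_high[1])
})

test_that("Egger regression is invariant to allele orientation", {
  for (seed in 1:5) {
    set <- random_set(12, seed = 100 + seed)
    base <- mr_egger(set)
    flipped <- set
    pick <- withr::with_seed(seed, sample(12, 5))
    flipped$bx[pick] <- -flipped$bx[pick]
    flipped$by[pick] <- -flipped$by[pick]
    re <- mr_egger(flipped)
    expect_equal(re$beta, base$beta)
    expect_equal(re$se, base$se)
  }
})

test_that("estimators are scale- and sign-equivariant", {
  set <- random_set(10, seed = 77)
  ld <- exchangeable_ld(set$snp_id, 0.25)
  ests <- list(
    function(s) ivw_fixed(s),
    function(s) ivw_random(s),
    function(s) ivw_correlated(s, ld),
    function(s) mr_egger(s)[1, ]   # slope
  )
  for (fn in ests) {
    base <- fn(set)
    # multiplying all outcome coefficients and ses by c scales beta and se by c
    scaled <- dplyr::mutate(set, by = by * 3.7, se_y = se_y * 3.7)
    got <- fn(scaled)
    expect_equal(got$beta, 3.7 * base$beta, tolerance = 1e-10)
    expect_equal(got$se, 3.7 * base$se, tolerance = 1e-10)
    # negating all exposure coefficients negates beta
    neg <- dplyr::mutate(set, bx = -bx)
    expect_equal(fn(neg)$beta, -base$beta, tolerance = 1e-10)
    expect_equal(fn(neg)$se, base$se, tolerance = 1e-10)
  }
})
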