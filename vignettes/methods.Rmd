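---
title: "Methods: two-sample MR from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsum)
```

## The model

Two-sample Mendelian randomization estimates the causal effect of an
exposure on an outcome from two independent GWAS. For instrument $j$ the
exposure study reports $\hat{b}_{Xj} \sim N(\xi_j, \sigma_{Xj}^2)$ and the
outcome study reports $\hat{b}_{Yj} \sim N(\beta\,\xi_j + \alpha_j,
\sigma_{Yj}^2)$, where $\xi_j$ is the true SNP–exposure effect, $\beta$ the
causal effect of interest, and $\alpha_j$ a direct (pleiotropic) effect of
the variant on the outcome. For binary traits all coefficients are log odds
ratios. The core MR assumptions are that instruments are associated with
the exposure, unconfounded, and affect the outcome only through the
exposure ($\alpha_j = 0$); the sensitivity machinery in this package exists
because the last assumption is untestable directly.

Three complications are handled explicitly:

1. **Allele coding.** The two studies need not report effects on the same
   allele, or even the same strand. `harmonize()` re-expresses the outcome
   effect on the exposure's effect allele, trying a direct label match,
   then a strand complement, before declaring a SNP irreconcilable.
   Palindromic variants (A/T, C/G) are aligned by comparing each study's
   effect-allele frequency with 0.5, and dropped when either frequency
   falls within `eaf_tolerance` of 0.5 (default 0.08, the conventional
   ambiguity zone: at minor-allele frequencies this close to 0.5, sampling
   noise in reported frequencies can silently point the wrong way).
2. **Linkage disequilibrium.** Instruments from one gene region are
   correlated, which leaves the point estimate roughly unchanged but makes
   independence-based intervals too narrow. `prune_ld()` removes one member
   of every pair with $r^2 \ge 0.9$ (stepwise, seeded random choice within
   each pair), and the correlated estimators below consume the residual
   correlation. `find_proxies()` substitutes a variant in high LD
   (strictly $r^2 > 0.9$) when an instrument is missing from the outcome
   study. The thresholds differ in strictness deliberately — pruning treats
   the boundary as redundant, proxy lookup requires the surrogate to exceed
   it.
3. **Pleiotropy.** MR-Egger regression frees the intercept of the weighted
   regression of $\hat{b}_{Yj}$ on $\hat{b}_{Xj}$; the intercept estimates
   the average direct effect and the slope remains consistent for $\beta$
   under the InSIDE condition (direct effects independent of instrument
   strength).

## Estimators

With weights $w_j = \hat{b}_{Xj}^2/\sigma_{Yj}^2$ (inverse first-order
variances of the per-SNP ratio estimates):

* `wald_ratio()` — $\hat\beta_j = \hat{b}_{Yj}/\hat{b}_{Xj}$; the
  first-order SE $\sigma_{Yj}/|\hat{b}_{Xj}|$ is the default because it is
  the same approximation the IVW weights use; a second-order delta-method
  SE that adds $\hat{b}_{Yj}^2\sigma_{Xj}^2/\hat{b}_{Xj}^4$ is available.
* `ivw_fixed()` — the $w_j$-weighted mean of the ratios, algebraically
  identical to a zero-intercept weighted regression (the test suite checks
  the two routes agree to 10+ significant figures).
* `ivw_random()` — additive DerSimonian–Laird. The multiplicative
  (overdispersed-regression) variant would be a natural extension; the
  additive moment estimator is the standard meta-analysis default and is
  cross-checked against `metafor` in the tests.
* `ivw_correlated()` — generalized least squares with outcome covariance
  $\Omega_{jk} = \sigma_{Yj}\sigma_{Yk} r_{jk}$, where $r$ is the signed LD
  correlation. Signs matter: a supplied $r^2$ matrix is accepted only with
  an explicit warning that positive signs are assumed.
* `ml_correlated()` — maximizes the bivariate likelihood over
  $(\beta, \xi)$. The $\xi$ maximizer is available in closed form for fixed
  $\beta$, so the implementation optimizes the one-dimensional profile
  log-likelihood (`stats::optimize` over the GLS estimate $\pm 10$ SEs) and
  takes the SE from the numerically differentiated profile information
  (central differences, step $10^{-4}\max(1,|\hat\beta|)$). As
  $\sigma_{Xj} \to 0$ this converges to the GLS solution; with real
  exposure-side noise its SE is larger, which is the point of having it.
* `mr_egger()` — weighted least squares with a free intercept after
  orienting every instrument to $\hat{b}_{Xj} \ge 0$ (the fit is invariant
  to arbitrary pre-flipping; orientation makes that explicit). SEs are the
  plain WLS ones, i.e. the residual variance is estimated, so balanced
  pleiotropy inflates the intervals as it should. No floor is placed on the
  residual SD.

`cochran_q()` computes $Q$ around the fixed-effects estimate, $I^2 =
\max(0, 100(Q-\mathrm{df})/Q)$ (so $I^2$ is exactly 0 whenever $Q \le
\mathrm{df}$), and the Higgins–Thompson test-based interval on
$\ln H = \tfrac12\ln(Q/\mathrm{df})$, truncated to $[0, 100]$. With two
instruments and $Q \le k$ the log-$H$ SE formula is undefined and the
interval is reported as the full $[0, 100]$.

## Numerical and interface choices

* **Confidence intervals** use the literal multiplier 1.96 at the 95%
  level, matching how intervals in this literature are printed; other
  levels use exact normal quantiles. MR-Egger can use $t(n-2)$ via
  `t_dist = TRUE` for small instrument sets.
* **Per-doubling conversion** multiplies log-scale estimates by 0.693 by
  default — the rounded constant used when such conversions are reported —
  with `exact_ln2 = TRUE` switching to $\ln 2$. P-values are never
  recomputed after conversion: scaling the estimate and its SE together
  leaves the z statistic unchanged.
* **Power** uses the normal approximation
  $z = |\ln \mathrm{OR}|\sqrt{n\,r^2 k(1-k)}$, power
  $= \Phi(z - z_{1-\alpha/2})$, for a binary outcome with case fraction
  $k$ and instrument $r^2$ on the exposure. Worth knowing: with $r^2$ of
  order $3\times10^{-4}$ this formula yields power barely above the type-I
  rate at OR 1.1 for any case-control study of realistic size, so
  materially higher figures sometimes quoted for such designs must rest on
  different inputs or approximations than these.
* **Degenerate inputs.** A zero exposure coefficient is an error for
  `wald_ratio()` and is flagged (not dropped) in the per-SNP forest table;
  a pair with $|r| \ge 0.999$ makes $\Omega$ numerically singular and is
  refused with advice to prune; an exact-fit Egger regression has SE 0 and
  reports $p = 0$ for a nonzero coefficient; `prune_ld()` scans pairs in
  lexicographic rsID order and returns a sorted set, so its output is
  independent of input order, and the random within-pair choice is seeded.
  Proxy ties are broken by the lexicographically smallest rsID, and the
  strict proxy threshold is enforced with a $10^{-9}$ guard so boundary
  values do not pass by round-off.
* **Pipeline.** `run_analysis()` degrades gracefully: an estimator whose
  prerequisites the instrument set cannot meet (e.g. Egger with fewer than
  three SNPs) is skipped with a logged reason rather than aborting the run
  — instrument counts at every stage, the harmonization log, the seed and
  the package version all land in the report, and reports are byte-stable
  across reruns.

## The synthetic-data generator

`simulate_two_sample()` draws directly from the model above: it emulates
the *summary-statistic* layer (coefficients with Gaussian sampling error at
stated SEs, optional LD-correlated errors via the Cholesky factor of
$\Omega$, optional balanced/directional pleiotropy, InSIDE holding by
construction unless deliberately violated with `pleiotropy_inside_cor`).
Defaults — 50-SNP scale analyses with $\xi_j \sim N(0.1, 0.03^2)$,
$\sigma_X = 0.005$, $\sigma_Y = 0.013$ — represent strong, well-powered
instruments of the kind consortium-scale GWAS provide; $\sigma_Y$ matches
the outcome-side SE of the built-in four-SNP fixture. What it does *not*
emulate: individual-level genotypes, case-control ascertainment, sample
overlap between the two studies, weak-instrument regimes, allele-frequency
mismatches between studies, or non-Gaussian effect-size distributions.
Passing tests therefore demonstrate correctness of the estimators under
the model they assume, not robustness to those real-data pathologies.

Validation uses it at desk scale: unbiasedness of IVW at true effects 0
and 0.3 (50 SNPs, 1000 replicates, three Monte-Carlo-SE tolerance),
Egger-intercept recovery of a mean directional effect of 0.01, and 5%-size
calibration of the Egger-intercept test (under balanced pleiotropy, its
null) and of the Q test (under no pleiotropy, *its* null — balanced
pleiotropy is real heterogeneity, which Q is supposed to detect). The
pleiotropy-recovery and calibration simulations set the true causal effect
to zero: with a nonzero effect, exposure-side measurement error attenuates
the Egger slope and leaks a small systematic term into the intercept (the
NOME violation quantified elsewhere by $I^2_{GX}$), which would confound a
test of whether the intercept recovers the mean pleiotropic effect.

## Limitations

* The harmonization rules are standard practice; when reproducing a
  published analysis, the original authors' (usually undocumented) allele
  alignment may differ, particularly for palindromic SNPs.
* Correlated-instrument estimation is only as good as the supplied LD
  matrix, which must come from a panel matched to the study ancestry; the
  package deliberately has no remote LD lookup.
* No weighted-median, mode-based or multivariable estimators; no
  individual-level data; no genome-build liftover.
* Egger regression with a handful of highly correlated instruments is not
  meaningful (its prerequisites gate it out of such runs); the correlated
  GLS/ML estimators address the interval, not pleiotropy.
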