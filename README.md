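# mrsum

Two-sample Mendelian randomization (MR) from GWAS summary statistics.

Observational associations between two traits — the motivating case is
smoking initiation and schizophrenia — cannot distinguish causation from
confounding or reverse causation. MR uses genetic variants associated with
an exposure as unconfounded instruments: if a variant affects the outcome
only through the exposure, the ratio of its outcome and exposure
associations estimates the causal effect. Two-sample MR takes the
SNP–exposure coefficients from one GWAS and the SNP–outcome coefficients
from another, so the analysis needs nothing beyond published summary
tables. `mrsum` is for analysts who have two such tables (and optionally a
local LD correlation matrix) and want the full workflow: harmonization,
instrument selection, estimation, sensitivity analysis, and reporting —
with a synthetic-data generator so every stage can be validated against a
known truth.

## The estimators

For harmonized instruments with exposure coefficients `bx_j` (SE `se_x_j`)
and outcome coefficients `by_j` (SE `se_y_j`), all on the log-odds scale
for binary traits:

- **Wald ratio** (one SNP): `beta = by/bx`, first-order
  `se = se_y/|bx|` (second-order delta-method option).
- **IVW fixed effects**: `beta = Σ(bx·by/se_y²) / Σ(bx²/se_y²)`,
  `se = 1/√Σ(bx²/se_y²)` — equivalently the zero-intercept weighted
  regression of `by` on `bx` with weights `1/se_y²`.
- **IVW random effects**: DerSimonian–Laird, with
  `τ² = max(0, (Q − df)/(Σw − Σw²/Σw))` added to each ratio variance.
- **Correlated instruments**: with LD correlation `r_jk`, the outcome
  covariance is `Ω_jk = se_y_j·se_y_k·r_jk`; GLS gives
  `beta = (bxᵀΩ⁻¹bx)⁻¹ bxᵀΩ⁻¹by`. A profile maximum-likelihood variant
  (`bx_j ~ N(ξ_j, se_x_j²)`, `by ~ N(β·ξ, Ω)`) also propagates
  exposure-side uncertainty.
- **MR-Egger**: weighted regression `by = α + β·bx` after orienting all
  `bx ≥ 0`; the intercept `α` estimates average directional pleiotropy and
  its test is the pleiotropy test.
- **Heterogeneity**: Cochran's `Q = Σ w_j (ratio_j − β_IVW)²`,
  `I² = max(0, 100(Q − df)/Q)` with a Higgins–Thompson test-based CI.
- **Scales**: log-odds estimates are re-expressed per doubling of exposure
  odds by multiplying by 0.693 (`OR_dbl = OR^0.693`), and a normal
  approximation gives power for binary outcomes.

## Worked example

The package ships the four BDNF-region SNPs associated with smoking
initiation (exposure) together with their schizophrenia associations
(outcome) as a built-in fixture:

```r
library(mrsum)

dir <- tempfile()
paths <- write_table1_files(dir)   # exposure/outcome summary-stat files

cfg <- analysis_config(
  exposure = paths[["exposure"]],
  outcome  = paths[["outcome"]],
  direction_label = "smoking_initiation -> schizophrenia",
  p_threshold = 5e-8,
  estimators = c("ivw_fixed", "ivw_random")
)
res <- run_analysis(cfg)
res
#> Two-sample MR analysis: smoking_initiation -> schizophrenia
#> Instruments analysed: 4
#>
#>      method             scale n_snps    or           ci         p
#>   ivw_fixed per_unit_log_odds      4 2.166 (1.74, 2.70) 6.407e-12
#>  ivw_random per_unit_log_odds      4 2.166 (1.74, 2.70) 6.407e-12
#>   ivw_fixed      per_doubling      4 1.708 (1.47, 1.99) 6.407e-12
#>  ivw_random      per_doubling      4 1.708 (1.47, 1.99) 6.407e-12
#>
#> Heterogeneity: Q = 0.266 on 3 df (p = 0.966), I2 = 0.0% (0-85%)
```

Reading the output: the odds of schizophrenia are estimated to be 2.17
times higher per unit increase in the log odds of being an ever-smoker
(equivalently 1.71 times higher per doubling of smoking odds). The
random-effects estimate coincides with the fixed-effects one because the
four per-SNP ratios are mutually consistent (Q = 0.27 on 3 df, I² = 0).
Note these four instruments sit in one gene region; an interval that
accounts for their LD (supply `ld =` an `ld_matrix()`) is wider.

`tidy(res)` returns every estimate as a tibble, `glance(res)` a one-row
summary, `autoplot(res)` a forest plot of per-SNP and combined odds
ratios. `simulate_two_sample()` generates paired summary statistics with
known causal effect and pleiotropy for validation, and
`inst/scripts/mrsum-cli.R` wraps the pipeline for shell use.

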