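#' Simulate paired two-sample MR summary statistics with known truth
#'
#' Generates exposure- and outcome-study association records under the
#' standard two-sample model. True SNP-exposure effects `xi_j` are drawn
#' from `N(bx_mean, bx_sd^2)`; per-SNP pleiotropic effects `alpha_j` are 0
#' (`none`), `N(0, pleiotropy_sd^2)` (`balanced`) or
#' `N(pleiotropy_mean, pleiotropy_sd^2)` (`directional`). Observed
#' coefficients are `bx_j = xi_j + ex_j` and
#' `by_j = true_beta * xi_j + alpha_j + ey_j`, with exposure- and
#' outcome-side noise independent of each other (the two-sample
#' assumption). When `ld` is supplied the noise on each side is drawn
#' jointly with covariance `se_j se_k r_jk`. Pleiotropy is generated
#' independently of instrument strength (the InSIDE condition) unless
#' `pleiotropy_inside_cor` is nonzero, which correlates `alpha_j` with
#' `xi_j` for stress-testing Egger regression where its assumption fails.
#'
#' Defaults emulate consortium-scale GWAS instruments for a binary exposure
#' and binary outcome: strong instruments (per-SNP z around 20 on the
#' exposure) and outcome standard errors of 0.013 log-odds units.
#'
#' @param n_snps Number of instruments.
#' @param true_beta Causal effect (log-OR of outcome per unit exposure
#'   log-odds).
#' @param bx_mean,bx_sd Mean and SD of the true SNP-exposure effects.
#' @param se_x,se_y Standard errors (scalar or per-SNP vectors).
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`.
#' @param pleiotropy_sd SD of pleiotropic effects.
#' @param pleiotropy_mean Mean pleiotropic effect (directional mode).
#' @param pleiotropy_inside_cor Correlation between pleiotropic effect and
#'   instrument strength; 0 (default) satisfies InSIDE.
#' @param ld Optional [ld_matrix()] with `n_snps` rows inducing correlated
#'   sampling noise; its rsIDs are used for the records.
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical output. The caller's RNG state is left untouched.
#'
#' @return List with `exposure` and `outcome` (association-record tibbles in
#'   the format read by [read_summary_stats()]) and `truth` (list of
#'   `true_beta`, per-SNP `xi` and `alpha`, and the `seed`).
#' @export
#' @examples
#' sim <- simulate_two_sample(n_snps = 10, true_beta = 0.3, seed = 7)
#' ivw_fixed(harmonize(sim$exposure, sim$outcome))
simulate_two_sample <- function(n_snps, true_beta, bx_mean = 0.1, bx_sd = 0.03,
                                se_x = 0.005, se_y = 0.013,
                                pleiotropy_mode = c("none", "balanced", "directional"),
                                pleiotropy_sd = 0, pleiotropy_mean = 0,
                                pleiotropy_inside_cor = 0,
                                ld = NULL, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, bx_sd >= 0, all(se_x >= 0), all(se_y >= 0),
            pleiotropy_sd >= 0, abs(pleiotropy_inside_cor) <= 1)
  se_x <- rep_len(se_x, n_snps)
  se_y <- rep_len(se_y, n_snps)
  if (!is.null(ld) && nrow(ld) != n_snps) {
    abort(sprintf("ld matrix dimension (%d) does not match n_snps (%d)",
                  nrow(ld), n_snps))
  }
  ids <- if (!is.null(ld)) rownames(ld) else sprintf("rs%06d", seq_len(n_snps))

  withr::with_seed(seed, {
    xi <- rnorm(n_snps, bx_mean, bx_sd)
    alpha <- switch(pleiotropy_mode,
      none = rep(0, n_snps),
      balanced = rnorm(n_snps, 0, pleiotropy_sd),
      directional = rnorm(n_snps, pleiotropy_mean, pleiotropy_sd)
    )
    if (pleiotropy_inside_cor != 0 && pleiotropy_sd > 0 && bx_sd > 0) {
      mu <- if (pleiotropy_mode == "directional") pleiotropy_mean else 0
      z <- (alpha - mu) / pleiotropy_sd
      zx <- (xi - bx_mean) / bx_sd
      alpha <- mu + pleiotropy_sd * (pleiotropy_inside_cor * zx +
                                     sqrt(1 - pleiotropy_inside_cor^2) * z)
    }
    draw_noise <- function(se) {
      if (is.null(ld)) {
        rnorm(n_snps, 0, se)
      } else {
        omega <- outer(se, se) * unclass(ld)
        # jitter guards chol against semidefinite (e.g. duplicated-SNP) matrices
        u <- chol(omega + diag(1e-12, n_snps))
        as.numeric(crossprod(u, rnorm(n_snps)))
      }
    }
    bx <- xi + draw_noise(se_x)
    by <- true_beta * xi + alpha + draw_noise(se_y)
    eaf <- runif(n_snps, 0.1, 0.9)

    mk_records <- function(beta, se, trait) {
      tibble(
        snp_id = ids,
        chromosome = "1",
        position = 1000L * seq_len(n_snps),
        effect_allele = "A", other_allele = "G",
        eaf = eaf, beta = beta, se = se,
        p_value = pmax(2 * pnorm(-abs(beta / pmax(se, 1e-300))), 1e-300),
        trait_label = trait
      )
    }
    list(
      exposure = mk_records(bx, se_x, "simulated_exposure"),
      outcome = mk_records(by, se_y, "simulated_outcome"),
      truth = list(true_beta = true_beta, xi = xi, alpha = alpha, seed = seed)
    )
  })
}

#' Write association records to a tab-delimited summary-statistics file
#'
#' Emits the same format [read_summary_stats()] reads (round-trippable).
#'
#' @param records Tibble of association records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  readr::write_tsv(dplyr::select(records, -dplyr::any_of("trait_label")),
                   path, progress = FALSE)
  invisible(path)
}

table1_data <- function() {
  tibble(
    snp_id = c("rs6265", "rs4923460", "rs1304100", "rs6484320"),
    chromosome = "11",
    position = c(27636492L, 27613365L, 27528179L, 27659764L),
    effect_allele = c("T", "T", "A", "A"),
    # partner alleles are not part of the published table; non-palindromic
    # synthetic partners are assigned so the rows harmonize cleanly
    other_allele = c("C", "C", "G", "G"),
    eaf = c(0.21, 0.23, 0.74, 0.76),
    bx = c(-0.061, -0.058, 0.055, 0.057),
    se_x = c(0.011, 0.011, 0.01, 0.01),
    px = c(1.8e-8, 4.1e-8, 4.4e-8, 4.9e-8),
    by = c(-0.052, -0.045, 0.038, 0.043),
    se_y = c(0.013, 0.013, 0.013, 0.013),
    py = c(8e-5, 4.2e-4, 2.7e-3, 7.5e-4)
  )
}

#' The four-SNP smoking-initiation instrument set
#'
#' The published BDNF-region instruments for smoking initiation (exposure)
#' with their schizophrenia (outcome) coefficients, already on a common
#' effect allele: rs6265, rs4923460, rs1304100 and rs6484320.
#'
#' @return A harmonized set of 4 instruments.
#' @export
#' @examples
#' or_with_ci(ivw_fixed(table1_fixture()))
table1_fixture <- function() {
  d <- table1_data()
  new_harmonized_set(
    tibble(snp_id = d$snp_id, effect_allele = d$effect_allele,
           bx = d$bx, se_x = d$se_x, by = d$by, se_y = d$se_y,
           flipped = FALSE, palindromic = FALSE),
    exposure_label = "smoking_initiation",
    outcome_label = "schizophrenia",
    report = tibble(snp_id = d$snp_id, action = "kept",
                    reason = "built-in fixture")
  )
}

#' Write the four-SNP instrument set as exposure/outcome input files
#'
#' Emits `exposure_smoking_initiation.tsv` and `outcome_schizophrenia.tsv`
#' in the canonical summary-statistics format, suitable as pipeline inputs.
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_table1_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- table1_data()
  base <- dplyr::select(d, "snp_id", "chromosome", "position",
                        "effect_allele", "other_allele", "eaf")
  exposure <- dplyr::bind_cols(base, tibble(beta = d$bx, se = d$se_x, p_value = d$px))
  outcome <- dplyr::bind_cols(base, tibble(beta = d$by, se = d$se_y, p_value = d$py))
  paths <- c(exposure = file.path(dir, "exposure_smoking_initiation.tsv"),
             outcome = file.path(dir, "outcome_schizophrenia.tsv"))
  readr::write_tsv(exposure, paths[["exposure"]], progress = FALSE)
  readr::write_tsv(outcome, paths[["outcome"]], progress = FALSE)
  invisible(paths)
}
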