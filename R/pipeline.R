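#' Build an analysis configuration
#'
#' Collects everything one direction of a bidirectional two-sample MR
#' analysis needs: input files, instrument-selection thresholds, the
#' estimators to run, and output settings. `read_analysis_config()` loads
#' the same fields from a YAML file (paths resolved relative to the file).
#'
#' @param exposure,outcome Paths to exposure and outcome summary-statistics
#'   files ([read_summary_stats()] format).
#' @param direction_label Free-text label for the report (e.g.
#'   "smoking_initiation -> schizophrenia").
#' @param ld Optional [ld_matrix()] or path to one ([read_ld_matrix()]
#'   format). Enables pruning and the correlated-instrument estimators.
#' @param p_threshold Exposure p-value below which a SNP qualifies as an
#'   instrument; default genomewide significance `5e-8` (a relaxed `1e-6`
#'   is conventional for secondary analyses).
#' @param r2_prune r-squared threshold for stepwise pruning (default 0.9;
#'   only applied when `ld` is given).
#' @param estimators Character vector among `ivw_fixed, ivw_random,
#'   mr_egger, ivw_correlated, ml_correlated`; `ivw_fixed` always runs.
#' @param seed Integer seed driving every random choice.
#' @param output_dir Directory for report files, or `NULL` to skip writing.
#' @param exposure_columns,outcome_columns Optional column maps (see
#'   [read_summary_stats()]).
#' @param drop_ambiguous_palindromes,eaf_tolerance Passed to [harmonize()].
#' @param exact_ln2 Passed to [per_doubling()].
#' @return A named list of class `mr_config`.
#' @export
analysis_config <- function(exposure, outcome,
                            direction_label = "exposure -> outcome",
                            ld = NULL, p_threshold = 5e-8, r2_prune = 0.9,
                            estimators = c("ivw_fixed", "ivw_random", "mr_egger",
                                           "ivw_correlated", "ml_correlated"),
                            seed = 1L, output_dir = NULL,
                            exposure_columns = NULL, outcome_columns = NULL,
                            drop_ambiguous_palindromes = TRUE,
                            eaf_tolerance = 0.08, exact_ln2 = FALSE) {
  stopifnot(file.exists(exposure), file.exists(outcome),
            p_threshold > 0, p_threshold <= 1,
            r2_prune > 0, r2_prune <= 1)
  estimators <- unlist(estimators)
  known <- c("ivw_fixed", "ivw_random", "mr_egger", "ivw_correlated", "ml_correlated")
  bad <- setdiff(estimators, known)
  if (length(bad) > 0) abort(paste0("unknown estimator(s): ", paste(bad, collapse = ", ")))
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  structure(list(
    exposure = exposure, outcome = outcome, direction_label = direction_label,
    ld = ld, p_threshold = p_threshold, r2_prune = r2_prune,
    estimators = union("ivw_fixed", estimators), seed = as.integer(seed),
    output_dir = output_dir, exposure_columns = exposure_columns,
    outcome_columns = outcome_columns,
    drop_ambiguous_palindromes = drop_ambiguous_palindromes,
    eaf_tolerance = eaf_tolerance, exact_ln2 = exact_ln2
  ), class = "mr_config")
}

#' @rdname analysis_config
#' @param path Path to a YAML configuration file.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (!is.null(p) && !file.exists(p)) file.path(base, p) else p
  cfg$exposure <- rel(cfg$exposure)
  cfg$outcome <- rel(cfg$outcome)
  if (is.character(cfg$ld)) cfg$ld <- rel(cfg$ld)
  do.call(analysis_config, cfg)
}

#' Per-SNP Wald-ratio forest table
#'
#' One row per instrument with its exposure/outcome coefficients and the
#' single-SNP causal estimate on the odds-ratio scale with 95% CI — the
#' content of a per-SNP forest plot. Rows keep the input order. Instruments
#' with a zero exposure coefficient are flagged, not dropped.
#'
#' @param set A harmonized set.
#' @param se_method Passed to [wald_ratio()].
#' @return Tibble with columns `snp_id, bx, se_x, by, se_y, beta, se, or,
#'   or_ci_low, or_ci_high, p_value, note`.
#' @export
per_snp_estimates <- function(set, se_method = "first_order") {
  check_harmonized(set, min_n = 1L)
  purrr::map_dfr(seq_len(nrow(set)), function(i) {
    row <- set[i, ]
    base <- tibble(snp_id = row$snp_id, bx = row$bx, se_x = row$se_x,
                   by = row$by, se_y = row$se_y)
    if (row$bx == 0) {
      return(dplyr::bind_cols(base, tibble(
        beta = NA_real_, se = NA_real_, or = NA_real_, or_ci_low = NA_real_,
        or_ci_high = NA_real_, p_value = NA_real_,
        note = "undefined ratio: bx = 0")))
    }
    est <- or_with_ci(wald_ratio(row, se_method))
    dplyr::bind_cols(base, tibble(
      beta = est$beta, se = est$se, or = est$or, or_ci_low = est$or_ci_low,
      or_ci_high = est$or_ci_high, p_value = est$p_value, note = ""))
  })
}

#' Run one direction of a two-sample MR analysis
#'
#' Filters exposure records at the instrument p-value threshold, prunes
#' correlated instruments when an LD matrix is supplied, harmonizes the two
#' datasets onto common effect alleles, runs the requested estimators
#' (skipping, with a logged reason, any whose prerequisites the instrument
#' set cannot meet), computes heterogeneity statistics, converts every
#' estimate to the per-doubling-of-odds scale alongside the per-unit scale,
#' and assembles a per-SNP forest table. Fully deterministic given the
#' config and seed. If `output_dir` is set, writes `estimates.tsv`,
#' `per_snp.tsv`, `heterogeneity.tsv`, `harmonization.tsv`, `log.tsv` and a
#' machine-readable `report.json`.
#'
#' @param config An [analysis_config()] (or path to a YAML config file).
#' @return An object of class `mr_analysis`: list with elements
#'   `estimates` (all estimators, both scales, OR columns appended),
#'   `per_snp`, `heterogeneity`, `harmonized`, `counts`, `log`, `config`.
#'   Has [tidy()], [glance()], [autoplot()] and print methods.
#' @export
#' @examples
#' dir <- tempfile(); write_table1_files(dir)
#' cfg <- analysis_config(
#'   exposure = file.path(dir, "exposure_smoking_initiation.tsv"),
#'   outcome = file.path(dir, "outcome_schizophrenia.tsv"),
#'   estimators = "ivw_fixed")
#' run_analysis(cfg)
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "mr_config"))
  log <- tibble(event = character(), detail = character())
  note <- function(event, detail = "") {
    log <<- dplyr::bind_rows(log, tibble(event = event, detail = detail))
  }

  exposure <- read_summary_stats(config$exposure, config$exposure_columns,
                                 trait_label = "exposure")
  outcome <- read_summary_stats(config$outcome, config$outcome_columns,
                                trait_label = "outcome")
  counts <- tibble(stage = "read_exposure", n = nrow(exposure)) |>
    dplyr::add_row(stage = "read_outcome", n = nrow(outcome))

  keep <- !is.na(exposure$p_value) & exposure$p_value < config$p_threshold
  exposure <- exposure[keep, , drop = FALSE]
  counts <- dplyr::add_row(counts, stage = "p_filtered", n = nrow(exposure))
  if (nrow(exposure) == 0) {
    abort(sprintf("no instruments: no exposure SNP has p < %g", config$p_threshold))
  }

  if (!is.null(config$ld)) {
    retained <- prune_ld(exposure$snp_id, config$ld,
                         r2_threshold = config$r2_prune, seed = config$seed)
    dropped <- setdiff(exposure$snp_id, retained)
    if (length(dropped) > 0) {
      note("pruned", paste(dropped, collapse = ","))
    }
    exposure <- exposure[exposure$snp_id %in% retained, , drop = FALSE]
  }
  counts <- dplyr::add_row(counts, stage = "pruned", n = nrow(exposure))

  set <- harmonize(exposure, outcome,
                   drop_ambiguous_palindromes = config$drop_ambiguous_palindromes,
                   eaf_tolerance = config$eaf_tolerance)
  counts <- dplyr::add_row(counts, stage = "harmonized", n = nrow(set))
  if (nrow(set) == 0) abort("no instruments remain after harmonization")

  run_est <- function(name, fn) {
    if (!name %in% config$estimators && name != "ivw_fixed") return(NULL)
    tryCatch(fn(), error = function(e) {
      note(paste0("estimator_skipped:", name), conditionMessage(e))
      NULL
    })
  }
  estimates <- dplyr::bind_rows(
    run_est("ivw_fixed", function() ivw_fixed(set)),
    run_est("ivw_random", function() ivw_random(set)),
    run_est("mr_egger", function() mr_egger(set)),
    if (!is.null(config$ld)) run_est("ivw_correlated", function() ivw_correlated(set, config$ld)),
    if (!is.null(config$ld)) run_est("ml_correlated", function() ml_correlated(set, config$ld))
  )
  estimates <- dplyr::bind_rows(
    estimates,
    per_doubling(dplyr::filter(estimates, .data$method != "egger_intercept"),
                 exact_ln2 = config$exact_ln2)
  ) |> or_with_ci()

  heterogeneity <- if (nrow(set) >= 2) cochran_q(set) else {
    note("heterogeneity_skipped", "fewer than 2 instruments")
    NULL
  }

  result <- structure(list(
    estimates = estimates,
    per_snp = per_snp_estimates(set),
    heterogeneity = heterogeneity,
    harmonized = set,
    counts = counts,
    log = dplyr::bind_rows(log,
      dplyr::mutate(harmonization_report(set),
                    event = paste0("harmonize:", .data$action),
                    detail = paste0(.data$snp_id, ": ", .data$reason),
                    .keep = "none")),
    config = config
  ), class = "mr_analysis")

  if (!is.null(config$output_dir)) write_analysis_report(result, config$output_dir)
  result
}

#' Write an analysis report to disk
#'
#' @param result An `mr_analysis` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$estimates, file.path(dir, "estimates.tsv"), progress = FALSE)
  readr::write_tsv(result$per_snp, file.path(dir, "per_snp.tsv"), progress = FALSE)
  if (!is.null(result$heterogeneity)) {
    readr::write_tsv(result$heterogeneity, file.path(dir, "heterogeneity.tsv"),
                     progress = FALSE)
  }
  write_harmonization_report(result$harmonized, file.path(dir, "harmonization.tsv"))
  readr::write_tsv(result$log, file.path(dir, "log.tsv"), progress = FALSE)
  report <- list(
    package = "mrsum",
    version = as.character(utils::packageVersion("mrsum")),
    direction = result$config$direction_label,
    seed = result$config$seed,
    counts = result$counts,
    estimates = result$estimates,
    heterogeneity = result$heterogeneity,
    per_snp = result$per_snp
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("Two-sample MR analysis:", x$config$direction_label, "\n")
  cat("Instruments analysed:", nrow(x$harmonized), "\n\n")
  show <- or_pretty(dplyr::filter(x$estimates, .data$method != "egger_intercept"))
  print(as.data.frame(show), row.names = FALSE, digits = 4)
  eint <- dplyr::filter(x$estimates, .data$method == "egger_intercept")
  if (nrow(eint) > 0) {
    cat(sprintf("\nEgger intercept (pleiotropy test): %.4f (p = %.3g)\n",
                eint$beta[1], eint$p_value[1]))
  }
  if (!is.null(x$heterogeneity)) {
    h <- x$heterogeneity
    cat(sprintf("Heterogeneity: Q = %.3f on %d df (p = %.3g), I2 = %.1f%% (%.0f-%.0f%%)\n",
                h$q, h$df, h$p_value, h$i2, h$i2_ci_low, h$i2_ci_high))
  }
  invisible(x)
}

or_pretty <- function(est) {
  dplyr::transmute(est, method = .data$method, scale = .data$scale,
                   n_snps = .data$n_snps, or = .data$or,
                   ci = sprintf("(%.2f, %.2f)", .data$or_ci_low, .data$or_ci_high),
                   p = .data$p_value)
}
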