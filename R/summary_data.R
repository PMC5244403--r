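#' Canonical summary-statistics column names
#'
#' A GWAS association record holds, for one SNP and one trait, the estimated
#' per-allele effect on the trait (log odds ratio for binary traits) together
#' with its standard error and p-value. These are the canonical column names
#' used throughout the package.
#'
#' @return Character vector of canonical column names.
#' @export
summary_stat_columns <- function() {
  c("snp_id", "chromosome", "position", "effect_allele", "other_allele",
    "eaf", "beta", "se", "p_value")
}

required_stat_columns <- function() {
  setdiff(summary_stat_columns(), c("eaf", "chromosome", "position"))
}

valid_alleles <- c("A", "C", "G", "T")

allele_complement <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}

is_palindromic_pair <- function(a1, a2) {
  a2 == allele_complement(a1)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or whitespace-delimited association table with a header row
#' and returns one record per SNP as a tibble in canonical column order.
#' Rows whose beta or standard error cannot be parsed, or whose standard
#' error is not strictly positive, are rejected; the number of rejected rows
#' is reported via a message and attached as the `n_rejected` attribute.
#'
#' @param path Path to the delimited text file.
#' @param column_map Named character vector or list mapping canonical names
#'   (see [summary_stat_columns()]) to the column names used in the file.
#'   Canonical names absent from the map are assumed to be used verbatim.
#'   May also be a path to a YAML file of `canonical: file_column` pairs.
#' @param trait_label Label recorded in the `trait_label` column.
#'
#' @return A tibble of association records with columns
#'   `snp_id, chromosome, position, effect_allele, other_allele, eaf, beta,
#'   se, p_value, trait_label`. Alleles are upper-cased.
#' @export
#' @examples
#' dir <- tempfile(); write_table1_files(dir)
#' read_summary_stats(file.path(dir, "exposure_smoking_initiation.tsv"))
read_summary_stats <- function(path, column_map = NULL, trait_label = basename(path)) {
  if (is.character(column_map) && length(column_map) == 1 && file.exists(column_map)) {
    column_map <- yaml::read_yaml(column_map)
  }
  column_map <- as.list(column_map %||% list())

  first_line <- readLines(path, n = 1L)
  raw <- if (grepl("\t", first_line)) {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
  }

  resolve <- function(canonical) {
    nm <- column_map[[canonical]] %||% canonical
    if (!nm %in% names(raw)) {
      if (canonical %in% required_stat_columns()) {
        abort(sprintf("required column '%s' (mapped to '%s') not found in %s",
                      canonical, nm, path),
              class = "mrsum_config_error")
      }
      return(NULL)
    }
    raw[[nm]]
  }

  n <- nrow(raw)
  out <- tibble(
    snp_id        = as.character(resolve("snp_id")),
    chromosome    = as.character(resolve("chromosome") %||% rep(NA_character_, n)),
    position      = suppressWarnings(as.integer(resolve("position") %||% rep(NA, n))),
    effect_allele = toupper(as.character(resolve("effect_allele"))),
    other_allele  = toupper(as.character(resolve("other_allele"))),
    eaf           = suppressWarnings(as.numeric(resolve("eaf") %||% rep(NA, n))),
    beta          = suppressWarnings(as.numeric(resolve("beta"))),
    se            = suppressWarnings(as.numeric(resolve("se"))),
    p_value       = suppressWarnings(as.numeric(resolve("p_value"))),
    trait_label   = trait_label
  )

  bad <- is.na(out$beta) | is.na(out$se) | out$se <= 0 |
    !out$effect_allele %in% valid_alleles | !out$other_allele %in% valid_alleles |
    out$effect_allele == out$other_allele
  if (any(bad)) {
    inform(sprintf("read_summary_stats: rejected %d of %d rows (unparseable beta/SE, se <= 0, or invalid alleles)",
                   sum(bad), n))
  }
  out <- out[!bad, , drop = FALSE]
  attr(out, "n_rejected") <- sum(bad)
  out
}

new_harmonized_set <- function(tbl, exposure_label = NA_character_,
                               outcome_label = NA_character_, report = NULL) {
  stopifnot(!anyDuplicated(tbl$snp_id))
  structure(
    as_tibble(tbl),
    exposure_label = exposure_label,
    outcome_label = outcome_label,
    report = report,
    class = c("harmonized_set", class(as_tibble(tbl)))
  )
}

#' Harmonization report
#'
#' @param set A harmonized set produced by [harmonize()].
#' @return Tibble with columns `snp_id, action, reason` recording, for every
#'   SNP shared by the two inputs, whether it was kept (and whether its
#'   outcome beta was sign-flipped) or dropped and why.
#' @export
harmonization_report <- function(set) {
  attr(set, "report") %||% tibble(snp_id = character(), action = character(),
                                  reason = character())
}

#' Align exposure and outcome summary statistics onto a common effect allele
#'
#' For every SNP present in both datasets, expresses the outcome effect on
#' the exposure's effect allele. If the outcome's effect allele matches the
#' exposure's other allele (directly or after strand complementing), the
#' outcome beta is negated and the instrument flagged `flipped`. Palindromic
#' SNPs (A/T or C/G) carry no strand information in their allele labels, so
#' they are resolved by comparing each study's effect-allele frequency with
#' 0.5: frequencies on the same side imply the same allele. When either
#' frequency is missing or falls inside the ambiguity zone
#' `0.5 +/- eaf_tolerance`, the SNP is dropped if
#' `drop_ambiguous_palindromes` is set, otherwise aligned by allele label.
#'
#' @param exposure,outcome Tibbles of association records as returned by
#'   [read_summary_stats()].
#' @param drop_ambiguous_palindromes Drop palindromic SNPs whose frequencies
#'   cannot resolve strand (default `TRUE`).
#' @param eaf_tolerance Half-width of the frequency ambiguity zone around
#'   0.5 (default 0.08, conventional harmonization practice).
#'
#' @return A `harmonized_set`: a tibble with one row per retained SNP and
#'   columns `snp_id, effect_allele, bx, se_x, by, se_y, flipped,
#'   palindromic` (`bx`/`se_x` exposure, `by`/`se_y` outcome), plus a
#'   drop/flip report retrievable with [harmonization_report()].
#' @export
#' @examples
#' dir <- tempfile(); write_table1_files(dir)
#' exp <- read_summary_stats(file.path(dir, "exposure_smoking_initiation.tsv"))
#' out <- read_summary_stats(file.path(dir, "outcome_schizophrenia.tsv"))
#' harmonize(exp, out)
harmonize <- function(exposure, outcome, drop_ambiguous_palindromes = TRUE,
                      eaf_tolerance = 0.08) {
  stopifnot(!anyDuplicated(exposure$snp_id), !anyDuplicated(outcome$snp_id))
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]

  rows <- purrr::map(seq_along(shared), function(i) {
    e <- ex[i, ]; o <- ou[i, ]
    palin <- is_palindromic_pair(e$effect_allele, e$other_allele)

    # label-based alignment, trying strand complement before giving up
    flip <- NA
    if (setequal(c(o$effect_allele, o$other_allele),
                 c(e$effect_allele, e$other_allele))) {
      flip <- o$effect_allele == e$other_allele
    } else {
      oc_ea <- allele_complement(o$effect_allele)
      oc_oa <- allele_complement(o$other_allele)
      if (setequal(c(oc_ea, oc_oa), c(e$effect_allele, e$other_allele))) {
        flip <- oc_ea == e$other_allele
      }
    }
    if (is.na(flip)) {
      return(list(row = NULL,
                  log = tibble(snp_id = e$snp_id, action = "dropped",
                               reason = "allele mismatch")))
    }

    reason <- if (flip) "outcome beta sign-flipped" else "alleles already aligned"
    if (palin) {
      eafs_usable <- !is.na(e$eaf) && !is.na(o$eaf) &&
        abs(e$eaf - 0.5) > eaf_tolerance && abs(o$eaf - 0.5) > eaf_tolerance
      if (eafs_usable) {
        flip <- (e$eaf < 0.5) != (o$eaf < 0.5)
        reason <- if (flip) "palindromic, aligned by frequency (flipped)"
                  else "palindromic, aligned by frequency"
      } else if (drop_ambiguous_palindromes) {
        return(list(row = NULL,
                    log = tibble(snp_id = e$snp_id, action = "dropped",
                                 reason = "ambiguous palindrome")))
      } else {
        reason <- "palindromic, kept on allele labels (frequencies uninformative)"
      }
    }

    list(
      row = tibble(
        snp_id = e$snp_id,
        effect_allele = e$effect_allele,
        bx = e$beta, se_x = e$se,
        by = if (flip) -o$beta else o$beta, se_y = o$se,
        flipped = flip, palindromic = palin
      ),
      log = tibble(snp_id = e$snp_id, action = "kept", reason = reason)
    )
  })

  instruments <- dplyr::bind_rows(purrr::map(rows, "row"))
  if (nrow(instruments) == 0) {
    instruments <- tibble(snp_id = character(), effect_allele = character(),
                          bx = numeric(), se_x = numeric(), by = numeric(),
                          se_y = numeric(), flipped = logical(),
                          palindromic = logical())
  }
  new_harmonized_set(
    instruments,
    exposure_label = exposure$trait_label[1] %||% NA_character_,
    outcome_label = outcome$trait_label[1] %||% NA_character_,
    report = dplyr::bind_rows(purrr::map(rows, "log"))
  )
}

#' Write a harmonization report to delimited text
#'
#' @param set A harmonized set.
#' @param path Output file path (tab-delimited, columns snp, action, reason).
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(set, path) {
  readr::write_tsv(harmonization_report(set), path, progress = FALSE)
  invisible(path)
}

# keep harmonized_set attributes through dplyr-style row subsetting
#' @export
`[.harmonized_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("bx", "by") %in% names(out))) {
    attributes(out)[c("exposure_label", "outcome_label")] <-
      attributes(x)[c("exposure_label", "outcome_label")]
    class(out) <- unique(c("harmonized_set", class(out)))
  }
  out
}

check_harmonized <- function(set, min_n = 1L, call = rlang::caller_env()) {
  need <- c("snp_id", "bx", "se_x", "by", "se_y")
  missing <- setdiff(need, names(set))
  if (length(missing) > 0) {
    abort(paste0("not a harmonized set: missing column(s) ",
                 paste(missing, collapse = ", ")), call = call)
  }
  if (nrow(set) < min_n) {
    abort(sprintf("at least %d instrument(s) required, got %d", min_n, nrow(set)),
          call = call)
  }
  if (any(set$se_y <= 0) || any(set$se_x < 0)) {
    abort("outcome standard errors must be strictly positive and exposure standard errors non-negative",
          call = call)
  }
  invisible(set)
}
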