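#' Construct a validated LD correlation matrix
#'
#' Pairwise signed correlations (r, not r squared) among instrument SNPs,
#' as estimated from a reference panel. The matrix must be symmetric with a
#' unit diagonal and positive semidefinite within a small tolerance.
#'
#' @param r Square numeric matrix of signed correlations in \[-1, 1\], with
#'   rsIDs as row/column names, or both dimnames missing and `snp_ids` given.
#' @param snp_ids Optional character vector of rsIDs (overrides dimnames).
#' @return The matrix with class `ld_matrix`.
#' @export
ld_matrix <- function(r, snp_ids = NULL) {
  r <- as.matrix(r)
  if (!is.null(snp_ids)) dimnames(r) <- list(snp_ids, snp_ids)
  ids <- rownames(r)
  if (is.null(ids) || nrow(r) != ncol(r) || !identical(ids, colnames(r))) {
    abort("ld matrix must be square with matching rsID row/column names")
  }
  if (anyDuplicated(ids)) abort("duplicated rsIDs in ld matrix")
  if (max(abs(r - t(r))) > 1e-8) abort("ld matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) abort("ld matrix must have unit diagonal")
  if (any(abs(r) > 1 + 1e-8)) abort("correlations must lie in [-1, 1]")
  ev <- eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf("ld matrix is not positive semidefinite (min eigenvalue %.3g)",
                  min(ev)))
  }
  structure(r, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from a delimited square-matrix file
#'
#' The file must be tab-delimited with a header row of rsIDs; the first
#' column holds the row rsIDs. If all off-diagonal entries are non-negative
#' the values may be r-squared rather than signed r; in that case signs are
#' assumed positive and a warning is issued, because the correlated-
#' instrument estimators need signed correlations.
#'
#' @param path File path.
#' @param squared Set `TRUE` if the file stores r-squared values; they are
#'   square-rooted with positive sign (with a warning).
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path, squared = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  dimnames(m) <- list(ids, colnames(tab)[-1])
  if (squared) {
    warn("r-squared input: signs assumed positive; correlated-instrument estimators need signed r")
    m <- sqrt(pmax(m, 0))
    diag(m) <- 1
  }
  ld_matrix(m)
}

#' Write an LD matrix to a delimited square-matrix file
#'
#' @param ld An [ld_matrix()].
#' @param path Output path (tab-delimited; first column `snp_id`).
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  tab <- dplyr::bind_cols(tibble(snp_id = rownames(ld)),
                          as_tibble(unclass(ld)[, , drop = FALSE]))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

ld_submatrix <- function(ld, ids, call = rlang::caller_env()) {
  missing <- setdiff(ids, rownames(ld))
  if (length(missing) > 0) {
    abort(paste0("SNP(s) absent from LD matrix: ", paste(missing, collapse = ", ")),
          call = call)
  }
  unclass(ld)[ids, ids, drop = FALSE]
}

#' Stepwise LD pruning of correlated instruments
#'
#' Repeatedly finds a pair of SNPs correlated at `r2 >= r2_threshold`, keeps
#' one member of the pair chosen uniformly at random, and drops the other,
#' until no such pair remains. Pairs are scanned in lexicographic rsID order
#' and the random choice is driven by `seed`, so the result is deterministic
#' and independent of input order.
#'
#' @param snps Character vector of rsIDs to prune.
#' @param ld An [ld_matrix()] covering all of `snps`.
#' @param r2_threshold Squared-correlation threshold at or above which a pair
#'   is considered redundant (default 0.9).
#' @param seed Integer seed for the random keep/drop choice.
#' @return Character vector of retained rsIDs, sorted lexicographically.
#'   Among them no pair has `r2 >= r2_threshold`.
#' @export
prune_ld <- function(snps, ld, r2_threshold = 0.9, seed = 1L) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  snps <- sort(unique(as.character(snps)))
  r <- ld_submatrix(ld, snps)
  withr::with_seed(seed, {
    keep <- snps
    repeat {
      r2 <- r[keep, keep, drop = FALSE]^2
      diag(r2) <- 0
      hit <- which(r2 >= r2_threshold, arr.ind = TRUE)
      if (nrow(hit) == 0) break
      # first offending pair in lexicographic scan order (ids are sorted)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      pair <- keep[hit[1, ]]
      drop <- sample(pair, 1L)
      keep <- setdiff(keep, drop)
    }
    keep
  })
}

#' Find proxy SNPs in high LD for instruments missing from a dataset
#'
#' Each wanted SNP already present in `available` maps to itself. Each
#' missing one maps to the available SNP with the largest r-squared,
#' provided it exceeds `r2_min` (strict); ties are broken by the
#' lexicographically smallest rsID. SNPs with no qualifying proxy are
#' reported as unresolved.
#'
#' @param wanted Character vector of rsIDs needed.
#' @param available Character vector of rsIDs present in the other dataset.
#' @param ld An [ld_matrix()] covering the union of the two sets.
#' @param r2_min Minimum (exclusive) r-squared for a proxy (default 0.9).
#' @return Tibble with columns `snp_id, proxy, r2, status` where status is
#'   one of `present`, `proxy`, `unresolved` (`proxy` is `NA` when
#'   unresolved; `r2` is 1 for present SNPs).
#' @export
find_proxies <- function(wanted, available, ld, r2_min = 0.9) {
  wanted <- unique(as.character(wanted))
  available <- unique(as.character(available))
  ld_submatrix(ld, union(wanted, available))  # coverage check
  r <- unclass(ld)
  purrr::map_dfr(wanted, function(s) {
    if (s %in% available) {
      return(tibble(snp_id = s, proxy = s, r2 = 1, status = "present"))
    }
    cand <- sort(setdiff(available, s))
    if (length(cand) == 0) {
      return(tibble(snp_id = s, proxy = NA_character_, r2 = NA_real_,
                    status = "unresolved"))
    }
    r2 <- r[s, cand]^2
    best <- max(r2)
    # strict threshold, with a guard so values equal to r2_min up to
    # floating-point round-off do not sneak through
    if (best > r2_min + 1e-9) {
      tibble(snp_id = s, proxy = cand[which(r2 == best)[1]], r2 = best,
             status = "proxy")
    } else {
      tibble(snp_id = s, proxy = NA_character_, r2 = NA_real_,
             status = "unresolved")
    }
  })
}
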