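# shared test utilities: fast set construction and random instances

# simulate_two_sample output is already allele-aligned (same effect allele on
# both sides), so a harmonized set can be assembled directly without paying
# the per-SNP harmonization cost inside Monte-Carlo loops
sim_to_set <- function(sim) {
  tibble::tibble(
    snp_id = sim$exposure$snp_id,
    bx = sim$exposure$beta, se_x = sim$exposure$se,
    by = sim$outcome$beta, se_y = sim$outcome$se
  )
}

# random harmonized instances for oracle-equivalence and property checks;
# exposure coefficients bounded away from zero
random_set <- function(n, seed) {
  withr::with_seed(seed, {
    bx <- rnorm(n, 0.1, 0.05)
    bx <- sign(bx + (bx == 0)) * pmax(abs(bx), 0.02)
    tibble::tibble(
      snp_id = sprintf("rs%04d", seq_len(n)),
      bx = bx,
      se_x = runif(n, 0.003, 0.01),
      by = 0.4 * bx + rnorm(n, 0, 0.02),
      se_y = runif(n, 0.008, 0.02)
    )
  })
}

exchangeable_ld <- function(ids, rho) {
  n <- length(ids)
  r <- matrix(rho, n, n)
  diag(r) <- 1
  ld_matrix(r, snp_ids = ids)
}

# orient a harmonized set so every exposure coefficient is positive
orient_positive <- function(set) {
  flip <- set$bx < 0
  set$bx[flip] <- -set$bx[flip]
  set$by[flip] <- -set$by[flip]
  set
}

table1_association_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_table1_files(dir)
}
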