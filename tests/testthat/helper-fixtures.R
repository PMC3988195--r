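# shared fixtures and independent oracles

# small panel with prescribed per-site minor-allele column sums, built so
# every subject count is in {0,1,2}
panel_with_colsums <- function(col_sums, n_subjects, positions = NULL) {
  K <- length(col_sums)
  counts <- matrix(0L, n_subjects, K)
  for (j in seq_len(K)) {
    s <- col_sums[j]
    stopifnot(s <= 2 * n_subjects)
    n2 <- s %/% 2L
    if (n2 > 0L) counts[seq_len(n2), j] <- 2L
    if (s %% 2L == 1L) counts[n2 + 1L, j] <- 1L
  }
  if (is.null(positions)) positions <- seq_len(K) * 100L
  genotype_panel(counts, positions)
}

# random null panel: genotypes independent of any phenotype
random_panel <- function(n, K, maf_range = c(0.005, 0.05), spacing = 300L) {
  f <- runif(K, maf_range[1], maf_range[2])
  counts <- matrix(rbinom(n * K, 2L, rep(f, each = n)), n, K)
  genotype_panel(counts, positions = cumsum(rep(spacing, K)))
}

balanced_phenotype <- function(n) {
  phenotype_vector(rep(c(1L, 0L), each = n %/% 2L))
}

# independent mid-P oracle: explicit combinatorics over the 2x2 support,
# deliberately avoiding dhyper (the implementation's route)
oracle_mid_p <- function(a, b, nA, nU) {
  m <- a + b
  if (m == 0 || m == nA + nU) return(1)
  support <- max(0, m - nU):min(m, nA)
  pr <- choose(nA, support) * choose(nU, m - support) / choose(nA + nU, m)
  p_obs <- pr[support == a]
  tol <- p_obs * 1e-7
  sum(pr[pr < p_obs - tol]) + 0.5 * sum(pr[abs(pr - p_obs) <= tol])
}

# vectorised oracle over a full margin: mid-P for every attainable a
oracle_mid_p_row <- function(m, nA, nU) {
  if (m == 0 || m == nA + nU) return(1)
  support <- max(0, m - nU):min(m, nA)
  pr <- choose(nA, support) * choose(nU, m - support) / choose(nA + nU, m)
  vapply(seq_along(pr), function(i) {
    tol <- pr[i] * 1e-7
    sum(pr[pr < pr[i] - tol]) + 0.5 * sum(pr[abs(pr - pr[i]) <= tol])
  }, numeric(1))
}

# largest |implementation - oracle| over every 2x2 allele table with
# total allele count <= maxN
midp_sweep_max_err <- function(maxN) {
  worst <- 0
  for (N in 2:maxN) {
    for (nA in 1:(N - 1)) {
      nU <- N - nA
      for (m in 0:N) {
        support <- max(0, m - nU):min(m, nA)
        impl <- rvcluster:::mid_p_table(m, nA, nU)[support + 1L]
        worst <- max(worst, abs(impl - oracle_mid_p_row(m, nA, nU)))
      }
    }
  }
  worst
}

# tiny simulated dataset for equivalence checks
tiny_sim_dataset <- function() {
  cfg <- sim_config(H = 300, region_length = 20000, n_sites = 20,
                    common_frac = 0.1, n_causal = 4, clustered = FALSE,
                    n_protective = 2, n_deleterious = 2, par = 0,
                    f0 = 0.05, n_cases = 40, n_controls = 40)
  dat <- simulate_case_control(cfg)
  list(panel = maf_filter(dat$panel, dat$pheno), pheno = dat$pheno)
}
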