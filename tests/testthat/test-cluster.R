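test_that("signal vectors apply truncation, direction split, and weights", {
  sm <- data.frame(
    site_id = c("a", "b", "c"), position = c(1L, 2L, 3L),
    p_value = c(0.05, 0.15, 0.5),
    direction = c("deleterious_inclined", "protective_inclined",
                  "deleterious_inclined"),
    weight = c(2, 1, 3), maf_combined = c(0.01, 0.02, 0.03))
  u <- signal_vectors(sm, tau = 0.12)
  expect_equal(u$u_del, c(2, 0, 0))
  expect_equal(u$u_pro, c(0, 0, 0))

  # all p >= tau -> both vectors vanish
  u0 <- signal_vectors(sm, tau = 0.01)
  expect_equal(u0$u_del, rep(0, 3))
  expect_equal(u0$u_pro, rep(0, 3))

  # neglog10 magnitude scales each entry by -log10(p)
  un <- signal_vectors(sm, tau = 0.2, transform = "neglog10")
  expect_equal(un$u_del, c(2 * -log10(0.05), 0, 0))
  expect_equal(un$u_pro, c(0, 1 * -log10(0.15), 0))
})

test_that("quadratic-form statistic expands correctly and never crosses direction classes", {
  C <- matrix(c(1, 0.8, 0, 0.8, 1, 0, 0, 0, 1), 3)
  expect_equal(threshold_statistic(c(1, 0.5, 0), rep(0, 3), C),
               1 + 0.25 + 2 * 0.8 * 0.5)  # = 2.05
  expect_equal(threshold_statistic(rep(0, 3), rep(0, 3), C), 0)
  # with one vector per class, cross terms only arise within a class
  s_split <- threshold_statistic(c(1, 0, 0), c(0, 1, 0), C, variant = "split")
  expect_equal(s_split, 2)  # no 0.8 cross term between classes
  s_pool <- threshold_statistic(c(1, 0, 0), c(0, 1, 0), C, variant = "pooled")
  expect_equal(s_pool, 2 + 2 * 0.8)
  expect_error(threshold_statistic(c(1, 0), rep(0, 3), C), "length")
})

test_that("min-P adjustment reproduces a hand-enumerated 4-permutation example", {
  S <- rbind(c(5, 3, 6, 5, 1),
             c(2, 4, 0, 2, 2))  # col 1 observed, cols 2..5 permuted
  adj <- rvcluster:::minp_adjust(S)
  expect_equal(adj$per_threshold_pvalues, c(2 / 4, 3 / 4))
  expect_equal(adj$min_p_observed, 0.5)
  expect_equal(adj$min_p_permuted, c(0.25, 0.25, 0.5, 0.75))
  expect_equal(adj$adjusted_p, (1 + 3) / 5)
})

test_that("adjusted P-value depends on the statistics only through ranks", {
  set.seed(5)
  S <- matrix(rexp(11 * 201), 11, 201)
  base <- rvcluster:::minp_adjust(S)
  # strictly increasing per-row transforms leave everything unchanged
  S2 <- exp(S * 2)
  S3 <- sweep(S, 1, seq_len(11), "*") + 100
  expect_equal(rvcluster:::minp_adjust(S2)$adjusted_p, base$adjusted_p)
  expect_equal(rvcluster:::minp_adjust(S3)$adjusted_p, base$adjusted_p)
})

test_that("a permutation weaker than the observed minimum never raises the numerator", {
  set.seed(6)
  for (r in 1:20) {
    S <- matrix(rexp(5 * 41), 5, 41)
    base <- rvcluster:::minp_adjust(S)
    # a replicate with the smallest statistics everywhere has minP = 1
    S_aug <- cbind(S, rep(-1, 5))
    aug <- rvcluster:::minp_adjust(S_aug)
    expect_lte(aug$numerator, base$numerator)
  }
})

test_that("boundary of the estimator: observed minP below all permutations", {
  # observed stats dominate every permutation at every threshold
  S <- rbind(c(10, 1, 2, 3, 4), c(9, 0, 1, 2, 3))
  adj <- rvcluster:::minp_adjust(S)
  expect_equal(adj$min_p_observed, 0)
  expect_equal(adj$adjusted_p, 1 / 5)
})

test_that("ADA equals the identity-kernel spatial test bit-exactly", {
  set.seed(21)
  dat <- tiny_sim_dataset()
  r1 <- cluster_test(dat$panel, dat$pheno, kernel = "identity", B = 80, seed = 99)
  r2 <- ada_test(dat$panel, dat$pheno, B = 80, seed = 99)
  expect_identical(r1$adjusted_p, r2$adjusted_p)
  expect_identical(r1$per_threshold_stats, r2$per_threshold_stats)
  expect_equal(r2$method, "ADA")

  # d_max below the smallest inter-site gap degenerates CLUSTER to ADA
  gap <- min(diff(dat$panel$positions))
  r3 <- cluster_test(dat$panel, dat$pheno, d_max = gap - 1, B = 80, seed = 99)
  expect_identical(r3$adjusted_p, r2$adjusted_p)

  # single-site panel: CLUSTER and ADA coincide for any d_max
  one <- genotype_panel(dat$panel$counts[, 1, drop = FALSE],
                        dat$panel$positions[1])
  r4 <- cluster_test(one, dat$pheno, d_max = 20000, B = 50, seed = 3)
  r5 <- ada_test(one, dat$pheno, B = 50, seed = 3)
  expect_identical(r4$adjusted_p, r5$adjusted_p)
})

test_that("Monte-Carlo permutations converge to the full label enumeration", {
  set.seed(77)
  n <- 8L; n_case <- 4L
  counts <- matrix(rbinom(n * 3, 2L, 0.25), n, 3)
  counts[1, ] <- pmax(counts[1, ], 1L)
  panel <- genotype_panel(counts, c(100L, 2000L, 15000L))
  y <- c(rep(1L, n_case), rep(0L, n - n_case))
  pheno <- phenotype_vector(y)
  C <- triweight_kernel(pairwise_distances(panel$positions), 20000)
  thresholds <- seq(0.10, 0.20, by = 0.01)

  # exhaustive: every case assignment once
  combos <- utils::combn(n, n_case)
  Y_exh <- matrix(0, n, ncol(combos) + 1L)
  Y_exh[, 1L] <- y
  for (b in seq_len(ncol(combos))) Y_exh[combos[, b], b + 1L] <- 1
  S_exh <- rvcluster:::cluster_engine(panel$counts, Y_exh, C, thresholds)
  p_exh <- rvcluster:::minp_adjust(S_exh)$adjusted_p

  mc <- cluster_test(panel, pheno, B = 4000, seed = 12)
  expect_lt(abs(mc$adjusted_p - p_exh), 0.05)
})

test_that("degenerate panels warn and report no evidence", {
  # every site has identical case and control minor-allele counts -> all tied
  counts <- rbind(matrix(c(1L, 0L), 4, 2), matrix(c(1L, 0L), 4, 2))
  panel <- genotype_panel(counts, c(100L, 300L))
  pheno <- phenotype_vector(rep(c(1L, 0L), each = 4))
  expect_warning(res <- cluster_test(panel, pheno, B = 30, seed = 1),
                 "tied or monomorphic")
  expect_equal(res$adjusted_p, 1)
})

test_that("threshold grids and permutation counts are validated", {
  dat <- tiny_sim_dataset()
  expect_error(cluster_test(dat$panel, dat$pheno, thresholds = c(0.2, 0.1), B = 10),
               "ascending")
  expect_error(cluster_test(dat$panel, dat$pheno, thresholds = numeric(0), B = 10),
               "thresholds")
  expect_error(cluster_test(dat$panel, dat$pheno, B = 0), "B must be")
})
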