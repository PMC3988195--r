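test_that("simulation configs validate their invariants", {
  expect_error(sim_config(n_causal = 5, n_protective = 3, n_deleterious = 3),
               "n_causal")
  expect_error(sim_config(par = 1), "par")
  expect_error(sim_config(f0 = 0), "f0")
  expect_error(sim_config(n_sites = 30000, region_length = 20000), "sites")
  expect_error(sim_config(cluster_span = 30000, region_length = 20000),
               "cluster_span")
})

test_that("haplotype pools have the requested shape and are fully polymorphic", {
  set.seed(101)
  cfg <- sim_config(H = 100, n_sites = 10, region_length = 5000,
                    cluster_span = 2000,
                    n_causal = 2, n_protective = 1, n_deleterious = 1)
  pool <- build_haplotype_pool(cfg)
  expect_equal(dim(pool$haplotypes), c(100L, 10L))
  expect_true(all(pool$haplotypes %in% c(0L, 1L)))
  cs <- colSums(pool$haplotypes)
  expect_true(all(cs > 0 & cs < 100))
  expect_true(all(diff(pool$positions) > 0))
  expect_true(all(pool$positions >= 1 & pool$positions <= 5000))

  # common fraction 0 -> every drawn frequency rare
  cfg0 <- sim_config(H = 500, n_sites = 50, region_length = 20000,
                     common_frac = 0, n_causal = 2, n_protective = 1,
                     n_deleterious = 1)
  pool0 <- build_haplotype_pool(cfg0)
  expect_true(all(pool0$freqs <= 0.05))
})

test_that("the rare-site frequency spectrum follows a 1/x power law", {
  set.seed(55)
  cfg <- sim_config(H = 1000, n_sites = 10000, region_length = 1000000,
                    common_frac = 0, n_causal = 2, n_protective = 1,
                    n_deleterious = 1)
  pool <- build_haplotype_pool(cfg)
  f <- pool$freqs
  # histogram of log-frequency: for density ~ 1/x, log-bins have equal mass;
  # fitted slope of log-density against log-midpoint is the exponent
  br <- exp(seq(log(1 / cfg$H), log(0.05), length.out = 11))
  h <- hist(f, breaks = br, plot = FALSE)
  fit <- lm(log(h$density) ~ log(h$mids))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.12)
})

test_that("clustered and equally-spaced causal placement meet their geometry", {
  set.seed(77)
  cfg <- sim_config(H = 500, n_sites = 200, region_length = 20000,
                    common_frac = 0, n_causal = 10, clustered = TRUE,
                    cluster_span = 6000, n_protective = 10, n_deleterious = 0)
  pool <- build_haplotype_pool(cfg)
  causal <- select_causal_sites(pool, cfg)
  span <- diff(range(pool$positions[causal$indices]))
  expect_lte(span, 6000)
  expect_equal(causal$directions, rep("protective", 10))

  cfg2 <- sim_config(H = 500, n_sites = 200, region_length = 20000,
                     common_frac = 0, n_causal = 10, clustered = FALSE,
                     n_protective = 0, n_deleterious = 10)
  causal2 <- select_causal_sites(pool, cfg2)
  gaps <- diff(pool$positions[causal2$indices])
  expect_true(all(gaps <= 2 * 20000 / 10))
  expect_equal(causal2$directions, rep("deleterious", 10))

  # an impossible clustered placement errors after retries
  cfg3 <- sim_config(H = 500, n_sites = 200, region_length = 20000,
                     common_frac = 0, n_causal = 150, clustered = TRUE,
                     cluster_span = 100, n_protective = 0, n_deleterious = 150)
  expect_error(select_causal_sites(pool, cfg3), "rare sites")
})

test_that("PAR converts to GRR by the closed form, protective as reciprocal", {
  expect_equal(par_to_grr(0, 0.01, protective = FALSE), 1)
  expect_equal(par_to_grr(0, 0.01, protective = TRUE), 1)
  expect_equal(par_to_grr(0.01, 0.01, protective = FALSE),
               0.01 / (0.01 * 0.99) + 1)
  expect_equal(par_to_grr(0.01, 0.01, protective = FALSE), 2.010101,
               tolerance = 1e-6)
  expect_equal(par_to_grr(0.01, 0.01, protective = TRUE), 0.497487,
               tolerance = 1e-6)
  expect_error(par_to_grr(-0.1, 0.01), "par")
  expect_error(par_to_grr(0.01, 0), "maf")

  # asymmetry: although the relative risks are exact reciprocals, the
  # odds-ratio magnitude of the deleterious variant exceeds the protective
  # variant's reciprocal magnitude at equal PAR, MAF and baseline penetrance
  odds_ratio <- function(grr, f0) (grr * f0 / (1 - grr * f0)) / (f0 / (1 - f0))
  f0 <- 0.01
  for (par in c(0.002, 0.01)) {
    for (maf in c(0.005, 0.02)) {
      or_del <- odds_ratio(par_to_grr(par, maf, FALSE), f0)
      or_pro <- odds_ratio(par_to_grr(par, maf, TRUE), f0)
      expect_gt(or_del, 1 / or_pro)
    }
  }
})

test_that("the penetrance model multiplies per-allele relative risks on f0", {
  expect_equal(penetrance(c(0, 0), c(2, 0.5), 0.01), 0.01)
  expect_equal(penetrance(1, 2, 0.01), 0.02)
  expect_equal(penetrance(c(2, 1), c(2.0101, 0.4975), 0.01),
               0.01 * 2.0101^2 * 0.4975)
  expect_equal(penetrance(c(2, 1), c(2.0101, 0.4975), 0.01), 0.020102,
               tolerance = 1e-4)
  # capped at 1
  expect_equal(penetrance(2, 100, 0.5), 1)
  # matrix form agrees with the scalar form
  g <- rbind(c(0, 0), c(2, 1))
  expect_equal(penetrance(g, c(2, 0.5), 0.01),
               c(0.01, penetrance(c(2, 1), c(2, 0.5), 0.01)))
})

test_that("case-control sampling fills its quotas exactly and records truth", {
  set.seed(13)
  cfg <- sim_config(H = 300, n_sites = 30, region_length = 20000,
                    n_causal = 4, clustered = FALSE, n_protective = 2,
                    n_deleterious = 2, par = 0, f0 = 0.05,
                    n_cases = 50, n_controls = 60)
  dat <- simulate_case_control(cfg)
  expect_equal(sum(unclass(dat$pheno) == 1L), 50L)
  expect_equal(sum(unclass(dat$pheno) == 0L), 60L)
  expect_equal(dim(dat$panel$counts), c(110L, 30L))
  expect_equal(length(dat$truth$causal_indices), 4L)
  expect_equal(dat$truth$grrs, rep(1, 4))  # par = 0 is the null

  # an unfillable quota hits the draw budget
  cfg2 <- sim_config(H = 300, n_sites = 30, region_length = 20000,
                     n_causal = 2, n_protective = 1, n_deleterious = 1,
                     clustered = FALSE, par = 0, f0 = 0.001,
                     n_cases = 500, n_controls = 10, draw_budget = 5000)
  pool <- build_haplotype_pool(cfg2)
  causal <- select_causal_sites(pool, cfg2)
  expect_error(sample_case_control(pool, causal, cfg2), "draw budget")
})

test_that("a deleterious causal variant enriches cases for its minor allele", {
  set.seed(23)
  cfg <- sim_config(H = 2000, n_sites = 20, region_length = 20000,
                    common_frac = 0, n_causal = 1, clustered = FALSE,
                    n_protective = 0, n_deleterious = 1, par = 0.01,
                    f0 = 0.05, n_cases = 100, n_controls = 100)
  pool <- build_haplotype_pool(cfg)
  # pin the causal site to one with pool frequency near 1%
  j <- which.min(abs(colMeans(pool$haplotypes) - 0.01))
  causal <- list(indices = j, directions = "deleterious")
  diffs <- replicate(200, {
    dat <- sample_case_control(pool, causal, cfg)
    y <- unclass(dat$pheno)
    mean(dat$panel$counts[y == 1L, j]) - mean(dat$panel$counts[y == 0L, j])
  })
  expect_gt(mean(diffs), 0)
})
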