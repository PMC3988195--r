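#' Default reduced-scale study design for calibration runs
#'
#' The design used by [run_type1()] when no configuration is supplied:
#' 200 cases + 200 controls drawn from a pool of 2,000 haplotypes over a
#' 20 kb region with 70 segregating sites (about 60 rare after the 5% MAF
#' filter), 10 clustered causal sites within 6 kb, PAR 0.  The causal count
#' is scaled with the site density: a 6 kb window of this sparser map holds
#' about 18 rare sites, which accommodates 10 causal placements reliably
#' but not the full design's 20.  This keeps a 2,000-replicate calibration
#' run on a single CPU in minutes while preserving the shape of the full
#' design (500+500 subjects, ~330 sites, 20 causal).
#'
#' @param par per-causal-variant PAR (default 0, the null).
#' @param ... overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
reduced_scale_config <- function(par = 0, ...) {
  args <- list(H = 2000, region_length = 20000, n_sites = 70,
               n_causal = 10, clustered = TRUE, cluster_span = 6000,
               n_protective = 5, n_deleterious = 5,
               par = par, f0 = 0.01, n_cases = 200, n_controls = 200)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

run_methods_once <- function(dat, methods, B, thresholds, d_max, max_maf) {
  panel <- maf_filter(dat$panel, dat$pheno, max_maf = max_maf)
  out <- numeric(length(methods))
  names(out) <- methods
  for (m in methods) {
    out[m] <- switch(m,
      CLUSTER = cluster_test(panel, dat$pheno, thresholds = thresholds,
                             kernel = "triweight", d_max = d_max,
                             B = B)$adjusted_p,
      ADA = ada_test(panel, dat$pheno, thresholds = thresholds,
                     B = B)$adjusted_p,
      WS = ws_test(panel, dat$pheno, B = B)$p_value,
      stop("unknown method: ", m))
  }
  out
}

make_report <- function(pvals, methods, alphas, replicates, B, seed, config,
                        failed) {
  rates <- expand.grid(method = methods, alpha = alphas,
                       stringsAsFactors = FALSE)
  rates$rejections <- mapply(function(m, a) sum(pvals[, m] < a, na.rm = TRUE),
                             rates$method, rates$alpha)
  n_ok <- replicates - failed
  rates$rate <- rates$rejections / n_ok
  rates$se <- sqrt(rates$rate * (1 - rates$rate) / n_ok)
  structure(
    list(scenario = list(par = config$par, clustered = config$clustered,
                         n_causal = config$n_causal,
                         n_protective = config$n_protective,
                         n_deleterious = config$n_deleterious,
                         n_cases = config$n_cases,
                         n_controls = config$n_controls),
         rates = rates, p_values = pvals,
         replicates = replicates, failed = failed, B = B,
         alphas = alphas, seed = seed),
    class = "experiment_report"
  )
}

#' Empirical type-I error of the region tests on null simulations
#'
#' Simulates `replicates` independent null datasets (PAR must be 0): each
#' replicate draws a fresh haplotype pool, places causal sites (inert at
#' PAR 0), samples cases and controls, applies the MAF filter, and runs the
#' requested tests with `B` permutations.  The report gives the rejection
#' rate at each nominal level with its binomial standard error.  The run is
#' deterministic given `seed`.
#'
#' @param config a [sim_config()] with `par = 0`; default
#'   [reduced_scale_config()].
#' @param methods subset of `c("CLUSTER", "ADA", "WS")`.
#' @param replicates number of simulated datasets (>= 100 unless
#'   `force = TRUE`; fewer is too noisy to interpret).
#' @param B permutations per test.
#' @param alphas nominal significance levels.
#' @param seed integer seed for the whole run.
#' @param thresholds,d_max,max_maf test configuration forwarded to
#'   [cluster_test()] / [maf_filter()].
#' @param force allow `replicates < 100`.
#' @return An `experiment_report`: rejection `rates` (with SEs), the matrix
#'   of per-replicate adjusted P-values, and run metadata.
#' @export
run_type1 <- function(config = reduced_scale_config(),
                      methods = c("CLUSTER", "WS"),
                      replicates = 2000, B = 500,
                      alphas = c(0.01, 0.03, 0.05), seed = NULL,
                      thresholds = seq(0.10, 0.20, by = 0.01),
                      d_max = 20000, max_maf = 0.05, force = FALSE) {
  if (config$par != 0) stop("type-I error runs require par = 0")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (replicates < 100L && !force)
    stop("replicates < 100 is too noisy to interpret; use force = TRUE to override")
  methods <- match.arg(methods, c("CLUSTER", "ADA", "WS"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  config$seed <- NULL  # the driver owns the RNG stream; a per-config seed
                       # would make every replicate identical

  pvals <- matrix(NA_real_, replicates, length(methods),
                  dimnames = list(NULL, methods))
  failed <- 0L
  for (r in seq_len(replicates)) {
    res <- tryCatch({
      dat <- simulate_case_control(config)
      run_methods_once(dat, methods, B, thresholds, d_max, max_maf)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else pvals[r, ] <- res
  }
  if (failed > 0L)
    warning(sprintf("%d replicate(s) failed (e.g. no testable sites) and were excluded",
                    failed))
  make_report(pvals, methods, alphas, replicates, B, seed, config, failed)
}

#' Empirical power across simulation scenarios
#'
#' Runs the same simulate-filter-test pipeline as [run_type1()] for each
#' scenario configuration (at least one must have nonzero PAR) and reports
#' the rejection rate at `alpha` per method.  With PAR = 0 in the grid the
#' "power" of that cell is its type-I error rate.
#'
#' @param configs a single [sim_config()] or a list of them.
#' @param methods subset of `c("CLUSTER", "ADA", "WS")`.
#' @param replicates replicates per scenario.
#' @param B permutations per test (power runs conventionally use a smaller
#'   B than type-I runs).
#' @param alpha nominal level at which power is measured.
#' @param seed integer seed.
#' @param thresholds,d_max,max_maf forwarded test configuration.
#' @param force allow `replicates < 100`.
#' @return A list of `experiment_report`s, one per scenario.
#' @export
run_power <- function(configs, methods = c("CLUSTER", "WS"),
                      replicates = 300, B = 200, alpha = 0.05, seed = NULL,
                      thresholds = seq(0.10, 0.20, by = 0.01),
                      d_max = 20000, max_maf = 0.05, force = FALSE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  if (!any(vapply(configs, function(cf) cf$par > 0, logical(1))))
    stop("at least one scenario must have nonzero PAR")
  if (replicates < 100L && !force)
    stop("replicates < 100 is too noisy to interpret; use force = TRUE to override")
  methods <- match.arg(methods, c("CLUSTER", "ADA", "WS"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)

  lapply(configs, function(cf) {
    cf$seed <- NULL  # driver-owned stream, as in run_type1
    pvals <- matrix(NA_real_, replicates, length(methods),
                    dimnames = list(NULL, methods))
    failed <- 0L
    for (r in seq_len(replicates)) {
      res <- tryCatch({
        dat <- simulate_case_control(cf)
        run_methods_once(dat, methods, B, thresholds, d_max, max_maf)
      }, error = function(e) NULL)
      if (is.null(res)) failed <- failed + 1L else pvals[r, ] <- res
    }
    make_report(pvals, methods, alpha, replicates, B, seed, cf, failed)
  })
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report: PAR=%g, %s, %d+%d causal (prot+del), %d replicates, B=%d\n",
              x$scenario$par,
              if (x$scenario$clustered) "clustered" else "non-clustered",
              x$scenario$n_protective, x$scenario$n_deleterious,
              x$replicates, x$B))
  df <- x$rates
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-8s alpha=%.3g  rate=%.4f (se %.4f)\n",
                df$method[i], df$alpha[i], df$rate[i], df$se[i]))
  invisible(x)
}

#' Rejection rate lookup from an experiment report
#'
#' @param report an `experiment_report`.
#' @param method method name.
#' @param alpha nominal level.
#' @return The rejection rate (a proportion).
#' @export
rejection_rate <- function(report, method, alpha) {
  df <- report$rates
  i <- which(df$method == method & abs(df$alpha - alpha) < 1e-12)
  if (length(i) != 1L) stop("no unique rate for that method/alpha")
  df$rate[i]
}
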