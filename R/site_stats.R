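#' Two-sided mid-P value of Fisher's exact test on a 2x2 allele table
#'
#' Per-site association evidence for a rare variant is measured on the 2x2
#' table of minor/major allele counts by case/control status (allele
#' counting: each diploid subject contributes two alleles).  Conditioning on
#' the margins, the minor-allele count in cases follows a hypergeometric
#' distribution; the two-sided mid-P sums the probabilities of all outcomes
#' strictly less probable than the observed one plus half the probability of
#' outcomes exactly as probable (the probability-based two-sided rule).
#' The mid-P correction removes half the point mass of the observed outcome
#' and makes the discrete test markedly less conservative than the ordinary
#' Fisher P-value.
#'
#' A monomorphic table (`a + b == 0`, or all alleles minor) is defined to
#' have mid-P 1: it carries no information and should normally have been
#' removed by [maf_filter()].
#'
#' @param a minor-allele count in cases.
#' @param b minor-allele count in controls.
#' @param n_case_alleles total case alleles (2 x number of cases).
#' @param n_ctrl_alleles total control alleles (2 x number of controls).
#' @return The mid-P value, clipped to (0, 1].
#' @export
fisher_mid_p <- function(a, b, n_case_alleles, n_ctrl_alleles) {
  if (a < 0 || b < 0 || a > n_case_alleles || b > n_ctrl_alleles)
    stop("allele counts must be non-negative and within their margins")
  m <- a + b
  tab <- mid_p_table(m, n_case_alleles, n_ctrl_alleles)
  tab[a + 1L]
}

# Mid-P values for every possible case minor-allele count a = 0..m given
# fixed margins (m minor alleles among nA case + nU control alleles).
# Returns a vector of length m+1 indexed by a+1; impossible a get NA.
# Under label permutation the margins are fixed, so this table is the
# hypergeometric lookup that makes permutation testing cheap.
mid_p_table <- function(m, nA, nU) {
  out <- rep(NA_real_, m + 1L)
  lo <- max(0L, m - nU)
  hi <- min(m, nA)
  if (m == 0L || m == nA + nU) {  # degenerate table: no information
    out[(lo:hi) + 1L] <- 1
    return(out)
  }
  support <- lo:hi
  pr <- stats::dhyper(support, nA, nU, m)
  # probability-based two-sided rule with a relative tie tolerance
  # (mirrors the 1 + 1e-7 guard used by fisher.test for float equality)
  for (idx in seq_along(support)) {
    p0 <- pr[idx] * (1 + 1e-7)
    less <- pr < pr[idx] / (1 + 1e-7)
    tied <- !less & pr <= p0
    out[support[idx] + 1L] <- sum(pr[less]) + 0.5 * sum(pr[tied])
  }
  pmin(pmax(out, .Machine$double.xmin), 1)
}

#' Madsen-Browning variant weight
#'
#' The weight given to a variant site upweights alleles that are rare in the
#' unaffected subjects: with `m_U` minor alleles among `n_U` genotyped
#' controls, the smoothed control frequency is
#' \eqn{q = (m_U + 1) / (2 n_U + 2)} and the weight is
#' \eqn{w = 1 / \sqrt{n \, q (1 - q)}} where `n` is the total number of
#' subjects genotyped at the site.  For fixed sample sizes the weight is
#' strictly decreasing in `m_U` while `q < 0.5`.
#'
#' @param m_U minor-allele count in controls.
#' @param n_U number of control subjects genotyped.
#' @param n_total total number of subjects genotyped.
#' @return Positive weight(s); vectorised over `m_U`.
#' @export
madsen_browning_weight <- function(m_U, n_U, n_total) {
  if (any(n_U < 1L) || any(n_total < n_U))
    stop("need n_U >= 1 and n_total >= n_U")
  if (any(m_U < 0) || any(m_U > 2 * n_U))
    stop("m_U must lie in [0, 2*n_U]")
  q <- (m_U + 1) / (2 * n_U + 2)
  1 / sqrt(n_total * q * (1 - q))
}

#' Per-site association P-values by logistic regression
#'
#' Alternative per-site engine for designs needing covariate adjustment:
#' for each site, the two-sided Wald P-value of the minor-allele-count term
#' in `glm(status ~ count + covariates, family = binomial)`.  Sites where
#' the fit does not converge or the dosage term is inestimable (e.g. under
#' complete separation) are assigned P = 1 with a warning rather than a
#' spuriously small value.
#'
#' @param panel a [genotype_panel()].
#' @param pheno a [phenotype_vector()] aligned to the panel.
#' @param covariates optional numeric subjects-by-c matrix.
#' @return Numeric vector of P-values in (0, 1], one per site.
#' @export
per_site_pvalues_logistic <- function(panel, pheno, covariates = NULL) {
  y <- align_phenotype(panel, pheno)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(y))
      stop("covariate row count does not match the number of subjects")
  }
  K <- ncol(panel$counts)
  pv <- rep(1, K)
  n_fail <- 0L
  for (i in seq_len(K)) {
    g <- panel$counts[, i]
    dat <- if (is.null(covariates)) data.frame(y = y, g = g)
           else data.frame(y = y, g = g, covariates)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial())),
      error = function(e) NULL
    )
    ok <- !is.null(fit) && fit$converged
    if (ok) {
      cf <- summary(fit)$coefficients
      ok <- "g" %in% rownames(cf) && is.finite(cf["g", "Std. Error"]) &&
        cf["g", "Std. Error"] < 1e3
    }
    if (ok) pv[i] <- cf["g", "Pr(>|z|)"] else n_fail <- n_fail + 1L
  }
  if (n_fail > 0L)
    warning(sprintf("%d site(s) failed to fit (separation/non-convergence); P set to 1",
                    n_fail))
  pmin(pmax(pv, .Machine$double.xmin), 1)
}

#' Per-site summaries: P-value, direction class, weight, MAF
#'
#' Assembles the ingredients of the truncation-test signal vectors for every
#' site of a (filtered) panel: the per-site association P-value, the
#' direction class -- `deleterious_inclined` if the case minor-allele
#' frequency strictly exceeds the control frequency, `protective_inclined`
#' if strictly less, `tied` if equal -- the Madsen-Browning weight computed
#' from the current control labels, and the pooled MAF.  Tied sites belong
#' to neither direction class and contribute to neither signal vector.
#'
#' @param panel a [genotype_panel()], normally after [maf_filter()].
#' @param pheno a [phenotype_vector()] aligned to the panel.
#' @param engine `"fisher_mid_p"` (default) or `"logistic"`.
#' @param covariates optional covariate matrix for the logistic engine.
#' @return A data.frame with one row per site: `site_id`, `position`,
#'   `p_value`, `direction`, `weight`, `maf_combined`.
#' @export
per_site_summaries <- function(panel, pheno,
                               engine = c("fisher_mid_p", "logistic"),
                               covariates = NULL) {
  engine <- match.arg(engine)
  y <- align_phenotype(panel, pheno)
  X <- panel$counts
  n <- nrow(X)
  n_case <- sum(y == 1L)
  n_ctrl <- n - n_case
  a <- as.integer(colSums(X[y == 1L, , drop = FALSE]))  # case minor alleles
  m <- as.integer(colSums(X))
  b <- m - a

  if (engine == "fisher_mid_p") {
    pv <- vapply(seq_along(a), function(i)
      fisher_mid_p(a[i], b[i], 2L * n_case, 2L * n_ctrl), numeric(1))
  } else {
    pv <- per_site_pvalues_logistic(panel, pheno, covariates)
  }

  # strict frequency comparison in integer arithmetic: a/(2nA) vs b/(2nU)
  lhs <- as.numeric(a) * n_ctrl
  rhs <- as.numeric(b) * n_case
  direction <- ifelse(lhs > rhs, "deleterious_inclined",
                      ifelse(lhs < rhs, "protective_inclined", "tied"))

  data.frame(
    site_id = panel$site_ids,
    position = panel$positions,
    p_value = pv,
    direction = direction,
    weight = madsen_browning_weight(b, n_ctrl, n),
    maf_combined = m / (2 * n),
    stringsAsFactors = FALSE
  )
}
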