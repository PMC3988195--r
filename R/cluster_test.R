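#' Direction-split signal vectors at a truncation threshold
#'
#' Converts per-site summaries into the two K-vectors that accumulate
#' association evidence at truncation threshold `tau`: the deleterious
#' vector has entry \eqn{w_i \, g(p_i)} at sites that are
#' deleterious-inclined with \eqn{p_i < \tau} and 0 elsewhere; the
#' protective vector is built the same way from protective-inclined sites.
#' Tied sites contribute to neither.  The per-site magnitude `g` is 1 by
#' default (pure truncation indicator) or `-log10(p)`.
#'
#' @param summaries data.frame from [per_site_summaries()].
#' @param tau truncation threshold in (0, 1); strict comparison `p < tau`.
#' @param transform `"indicator"` (default) or `"neglog10"`.
#' @return List with numeric vectors `u_del` and `u_pro`.
#' @export
signal_vectors <- function(summaries, tau,
                           transform = c("indicator", "neglog10")) {
  transform <- match.arg(transform)
  if (nrow(summaries) == 0L) stop("summaries must be nonempty")
  g <- if (transform == "indicator") rep(1, nrow(summaries))
       else -log10(summaries$p_value)
  sel <- summaries$p_value < tau
  base <- summaries$weight * g * sel
  list(u_del = base * (summaries$direction == "deleterious_inclined"),
       u_pro = base * (summaries$direction == "protective_inclined"))
}

#' Quadratic-form statistic at one truncation threshold
#'
#' The default (`"split"`) statistic evaluates the spatial quadratic form on
#' each direction class separately and sums them:
#' \eqn{S = u_{del}' C \, u_{del} + u_{pro}' C \, u_{pro}}.  The two classes
#' are never cross-multiplied, under the view that deleterious and
#' protective variants form their own spatial clusters.  The `"pooled"`
#' alternative mixes the classes into a single vector before the quadratic
#' form; it can be more powerful when roughly half the causal variants act
#' in each direction, but less so when effects share one direction.
#'
#' @param u_del,u_pro signal vectors from [signal_vectors()].
#' @param C a `kernel_matrix` (or plain K x K matrix).
#' @param variant `"split"` (default) or `"pooled"`.
#' @return The scalar statistic.
#' @export
threshold_statistic <- function(u_del, u_pro, C,
                                variant = c("split", "pooled")) {
  variant <- match.arg(variant)
  M <- if (inherits(C, "kernel_matrix")) C$values else as.matrix(C)
  if (length(u_del) != nrow(M) || length(u_pro) != nrow(M))
    stop("signal vector length does not match kernel dimension")
  if (variant == "split") {
    drop(crossprod(u_del, M %*% u_del) + crossprod(u_pro, M %*% u_pro))
  } else {
    u <- u_del + u_pro
    drop(crossprod(u, M %*% u))
  }
}

# --- internal permutation engine ------------------------------------------

# case-indicator matrix: column 1 is the observed labeling, columns
# 2..B+1 are uniform label shuffles preserving the case/control totals
perm_indicators <- function(y, B) {
  n <- length(y)
  n_case <- sum(y == 1L)
  Y <- matrix(0, n, B + 1L)
  Y[, 1L] <- y
  for (b in seq_len(B)) Y[sample.int(n, n_case), b + 1L] <- 1
  Y
}

# Threshold statistics for the observed and every permuted labeling.
# X: n x K dosage matrix; Y: n x (B+1) case indicators (col 1 observed).
# Per-site P-values come from the hypergeometric mid-P lookup: under label
# permutation each site's total minor-allele count is fixed, so the mid-P
# is a function of the case minor-allele count alone and is tabulated once
# per distinct total.  Weights and direction classes are recomputed from
# each permuted labeling, reproducing the observed statistic's construction
# exactly.  Returns a J x (B+1) matrix of statistics.
cluster_engine <- function(X, Y, C, thresholds,
                           transform = "indicator", variant = "split") {
  n <- nrow(X)
  n_case <- sum(Y[, 1L])
  n_ctrl <- n - n_case
  K <- ncol(X)
  Xd <- X
  storage.mode(Xd) <- "double"

  a_mat <- crossprod(Xd, Y)             # K x (B+1) case minor alleles
  m <- colSums(Xd)                      # per-site totals, permutation-invariant
  b_mat <- m - a_mat                    # control minor alleles

  um <- sort(unique(m))
  max_m <- max(um)
  tab <- matrix(NA_real_, max_m + 1L, length(um))
  for (j in seq_along(um)) {
    mm <- um[j]
    tab[seq_len(mm + 1L), j] <-
      if (mm == 0) 1 else mid_p_table(mm, 2L * n_case, 2L * n_ctrl)
  }
  idx_m <- match(m, um)
  ncols <- ncol(a_mat)
  p_mat <- matrix(tab[cbind(as.vector(a_mat) + 1L, rep(idx_m, ncols))],
                  K, ncols)

  del <- (a_mat * n_ctrl) > (b_mat * n_case)
  pro <- (a_mat * n_ctrl) < (b_mat * n_case)
  q <- (b_mat + 1) / (2 * n_ctrl + 2)
  w <- 1 / sqrt(n * q * (1 - q))
  WG <- if (transform == "indicator") w else w * -log10(p_mat)

  M <- if (inherits(C, "kernel_matrix")) C$values else as.matrix(C)
  J <- length(thresholds)
  S <- matrix(0, J, ncols)
  for (j in seq_len(J)) {
    sel <- p_mat < thresholds[j]
    if (variant == "split") {
      U <- WG * (del & sel)
      S[j, ] <- colSums(U * (M %*% U))
      U <- WG * (pro & sel)
      S[j, ] <- S[j, ] + colSums(U * (M %*% U))
    } else {
      U <- WG * ((del | pro) & sel)
      S[j, ] <- colSums(U * (M %*% U))
    }
  }
  S
}

# slow generic engine used for the logistic per-site option: rebuilds the
# full per-site summary table under every labeling
cluster_engine_generic <- function(panel, Y, C, thresholds, transform,
                                   variant, engine, covariates) {
  J <- length(thresholds)
  S <- matrix(0, J, ncol(Y))
  for (b in seq_len(ncol(Y))) {
    ph <- phenotype_vector(Y[, b], subject_ids = panel$subject_ids)
    sm <- suppressWarnings(
      per_site_summaries(panel, ph, engine = engine, covariates = covariates))
    for (j in seq_len(J)) {
      u <- signal_vectors(sm, thresholds[j], transform)
      S[j, b] <- threshold_statistic(u$u_del, u$u_pro, C, variant)
    }
  }
  S
}

# Min-P adjustment over the threshold grid.  S is J x (B+1) with column 1
# the observed sample.  Per-threshold P-values are plain proportions over
# the B permuted statistics (self-inclusive for permuted samples); the
# final adjusted P-value uses the add-one estimator so it can never be 0.
minp_adjust <- function(S) {
  B <- ncol(S) - 1L
  J <- nrow(S)
  Sp <- S[, -1L, drop = FALSE]
  p_obs <- numeric(J)
  p_perm <- matrix(0, J, B)
  for (j in seq_len(J)) {
    p_obs[j] <- sum(Sp[j, ] >= S[j, 1L]) / B
    # count of permuted statistics >= each permuted statistic, self included
    p_perm[j, ] <- (B - rank(Sp[j, ], ties.method = "min") + 1L) / B
  }
  minp_obs <- min(p_obs)
  minp_perm <- apply(p_perm, 2L, min)
  numerator <- 1L + sum(minp_perm <= minp_obs)
  list(per_threshold_pvalues = p_obs,
       min_p_observed = minp_obs,
       min_p_permuted = minp_perm,
       numerator = numerator,
       adjusted_p = numerator / (B + 1L))
}

# --- user-facing tests -----------------------------------------------------

#' Spatial-kernel adaptive P-value truncation test (CLUSTER)
#'
#' Region-based rare-variant association test for case-control data.  For
#' each candidate truncation threshold \eqn{\tau_j}, per-site P-values below
#' \eqn{\tau_j} are accumulated into direction-split, Madsen-Browning
#' weighted signal vectors and combined through a spatial proximity kernel
#' as \eqn{S_j = u_{del}' C u_{del} + u_{pro}' C u_{pro}}, so that nearby
#' significant sites reinforce each other.  Significance is assessed by a
#' permutation minimum-P procedure: case/control labels are shuffled `B`
#' times, the full statistic (per-site P-values, direction classes and
#' weights included) is recomputed under each shuffle, each threshold's
#' statistic is converted to a permutation P-value, and the minimum over
#' thresholds of the observed sample is ranked against the same minimum in
#' every permuted sample.  The reported adjusted P-value is therefore valid
#' despite the data-driven choice of threshold.
#'
#' With the identity kernel the statistic ignores positions entirely and
#' the procedure reduces to the adaptive combination of P-values (ADA)
#' test; see [ada_test()].
#'
#' @param panel a [genotype_panel()], already restricted to rare sites
#'   (see [maf_filter()]).
#' @param pheno a [phenotype_vector()] aligned to the panel.
#' @param thresholds strictly ascending truncation grid in (0, 1); default
#'   0.10, 0.11, ..., 0.20.
#' @param kernel `"triweight"` (default) or `"identity"`; ignored when `C`
#'   is supplied.
#' @param d_max tri-weight maximum interaction distance in bp (default
#'   20000).
#' @param C optional precomputed `kernel_matrix`.
#' @param B number of permutations (>= 1; default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @param engine per-site P-value engine, `"fisher_mid_p"` (default) or
#'   `"logistic"` (slower; refits every permutation).
#' @param covariates optional covariate matrix for the logistic engine.
#' @param transform per-site magnitude, `"indicator"` or `"neglog10"`.
#' @param variant `"split"` (default) or `"pooled"` statistic; see
#'   [threshold_statistic()].
#' @return A `cluster_result` list: `adjusted_p`, `min_p_observed`,
#'   `per_threshold_stats`, `per_threshold_pvalues`, `thresholds`, `B`,
#'   `seed`, `method` ("CLUSTER" or "ADA"), `statistic_variant`,
#'   `transform`, `site_summaries` (observed per-site table), and sample
#'   sizes.
#' @export
cluster_test <- function(panel, pheno,
                         thresholds = seq(0.10, 0.20, by = 0.01),
                         kernel = c("triweight", "identity"),
                         d_max = 20000, C = NULL,
                         B = 1000, seed = NULL,
                         engine = c("fisher_mid_p", "logistic"),
                         covariates = NULL,
                         transform = c("indicator", "neglog10"),
                         variant = c("split", "pooled")) {
  kernel <- match.arg(kernel)
  engine <- match.arg(engine)
  transform <- match.arg(transform)
  variant <- match.arg(variant)
  y <- align_phenotype(panel, pheno)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0))
    stop("thresholds must be strictly ascending and inside (0, 1)")
  if (!is.numeric(B) || B < 1L) stop("B must be >= 1")
  B <- as.integer(B)

  if (is.null(C)) {
    C <- switch(kernel,
                triweight = triweight_kernel(pairwise_distances(panel$positions),
                                             d_max),
                identity = identity_kernel(ncol(panel$counts)))
  }
  if (!inherits(C, "kernel_matrix")) C <- new_kernel_matrix(as.matrix(C), "custom")
  if (nrow(C$values) != ncol(panel$counts))
    stop("kernel dimension does not match the number of sites")
  method <- if (C$measure == "identity") "ADA" else "CLUSTER"

  if (!is.null(seed)) set.seed(seed)
  obs_summaries <- per_site_summaries(panel, pheno, engine = engine,
                                      covariates = covariates)
  if (all(obs_summaries$direction == "tied"))
    warning("all sites are tied or monomorphic; adjusted P-value is 1")

  Y <- perm_indicators(y, B)
  S <- if (engine == "fisher_mid_p") {
    cluster_engine(panel$counts, Y, C, thresholds, transform, variant)
  } else {
    cluster_engine_generic(panel, Y, C, thresholds, transform, variant,
                           engine, covariates)
  }
  adj <- minp_adjust(S)

  structure(
    list(adjusted_p = adj$adjusted_p,
         min_p_observed = adj$min_p_observed,
         per_threshold_stats = S[, 1L],
         per_threshold_pvalues = adj$per_threshold_pvalues,
         thresholds = thresholds,
         B = B, seed = seed,
         method = method, statistic_variant = variant,
         transform = transform, engine = engine,
         d_max = if (C$measure == "triweight") C$d_max else NA_real_,
         site_summaries = obs_summaries,
         n_cases = sum(y == 1L), n_controls = sum(y == 0L)),
    class = "cluster_result"
  )
}

#' Adaptive combination of P-values test (ADA)
#'
#' The identity-kernel special case of [cluster_test()]: spatial positions
#' are ignored and the per-threshold statistic is the weighted sum of
#' squared signals over the selected sites.  Identical arguments and
#' identical seed give bit-identical results to
#' `cluster_test(kernel = "identity")`.
#'
#' @inheritParams cluster_test
#' @return A `cluster_result` with `method = "ADA"`.
#' @export
ada_test <- function(panel, pheno,
                     thresholds = seq(0.10, 0.20, by = 0.01),
                     B = 1000, seed = NULL,
                     engine = c("fisher_mid_p", "logistic"),
                     covariates = NULL,
                     transform = c("indicator", "neglog10"),
                     variant = c("split", "pooled")) {
  cluster_test(panel, pheno, thresholds = thresholds, kernel = "identity",
               B = B, seed = seed, engine = match.arg(engine),
               covariates = covariates, transform = match.arg(transform),
               variant = match.arg(variant))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%s test: adjusted P = %.4g (B = %d permutations)\n",
              x$method, x$adjusted_p, x$B))
  cat(sprintf("  min per-threshold P = %.4g over %d thresholds [%g..%g]\n",
              x$min_p_observed, length(x$thresholds),
              min(x$thresholds), max(x$thresholds)))
  cat(sprintf("  %d cases / %d controls, %d sites, statistic=%s, g(p)=%s\n",
              x$n_cases, x$n_controls, nrow(x$site_summaries),
              x$statistic_variant, x$transform))
  invisible(x)
}

#' Serialise a test result to JSON
#'
#' @param x a `cluster_result` or `ws_result`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
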