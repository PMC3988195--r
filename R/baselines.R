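#' Madsen-Browning weighted-sum (WS) burden test
#'
#' Rank-sum burden test for an excess of rare minor alleles in cases.
#' Each site is weighted by the reciprocal of
#' \eqn{w'_i = \sqrt{n \, q_i (1 - q_i)}} with \eqn{q_i} the smoothed
#' control minor-allele frequency (see [madsen_browning_weight()]); the
#' genetic score of a subject is \eqn{\sum_i x_{i} / w'_i}, and the test
#' statistic is the sum of the cases' ranks of this score (midranks for
#' ties).  The test is one-sided -- sensitive to an excess burden in cases,
#' the direction the weighting scheme targets.  Significance comes from the
#' same permutation machinery as [cluster_test()]: labels are shuffled `B`
#' times, weights and scores are recomputed from each shuffled labeling,
#' and the add-one permutation estimator is reported.
#'
#' @param panel a [genotype_panel()], already restricted to rare sites.
#' @param pheno a [phenotype_vector()] aligned to the panel.
#' @param B number of permutations (>= 1; default 1000).
#' @param seed optional integer seed.
#' @return A `ws_result` list: `observed_score` (case rank-sum), `p_value`,
#'   `B`, `seed`, sample sizes.
#' @export
ws_test <- function(panel, pheno, B = 1000, seed = NULL) {
  y <- align_phenotype(panel, pheno)
  if (!is.numeric(B) || B < 1L) stop("B must be >= 1")
  B <- as.integer(B)
  if (!is.null(seed)) set.seed(seed)

  X <- panel$counts
  storage.mode(X) <- "double"
  n <- nrow(X)
  n_case <- sum(y == 1L)
  n_ctrl <- n - n_case

  Y <- perm_indicators(y, B)                  # n x (B+1), col 1 observed
  a_mat <- crossprod(X, Y)                    # case minor alleles per site
  m <- colSums(X)
  b_mat <- m - a_mat                          # control minor alleles
  q <- (b_mat + 1) / (2 * n_ctrl + 2)
  inv_w <- 1 / sqrt(n * q * (1 - q))          # K x (B+1) reciprocal weights

  scores <- X %*% inv_w                       # n x (B+1) genetic scores
  stats <- numeric(ncol(Y))
  for (b in seq_len(ncol(Y)))
    stats[b] <- sum(rank(scores[, b])[Y[, b] == 1])

  obs <- stats[1L]
  perm <- stats[-1L]
  p <- (1 + sum(perm >= obs)) / (B + 1L)

  structure(
    list(observed_score = obs, p_value = p, B = B, seed = seed,
         n_cases = n_case, n_controls = n_ctrl,
         n_sites = ncol(X)),
    class = "ws_result"
  )
}

#' @export
print.ws_result <- function(x, ...) {
  cat(sprintf("WS burden test: rank-sum = %.2f, P = %.4g (B = %d)\n",
              x$observed_score, x$p_value, x$B))
  cat(sprintf("  %d cases / %d controls, %d sites\n",
              x$n_cases, x$n_controls, x$n_sites))
  invisible(x)
}
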