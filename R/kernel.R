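#' Pairwise physical distances between variant sites
#'
#' @param positions per-site base-pair coordinates (finite, sorted).
#' @return K x K matrix with `D[i, j] = |pos_i - pos_j|`.
#' @export
pairwise_distances <- function(positions) {
  positions <- as.numeric(positions)
  if (any(!is.finite(positions))) stop("positions must be finite")
  abs(outer(positions, positions, "-"))
}

new_kernel_matrix <- function(values, measure, d_max = NA_real_) {
  structure(list(values = values, measure = measure, d_max = d_max),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %dx%d, measure=%s%s\n",
              nrow(x$values), ncol(x$values), x$measure,
              if (is.na(x$d_max)) "" else sprintf(", d_max=%g bp", x$d_max)))
  invisible(x)
}

#' Tri-weight spatial proximity kernel
#'
#' Builds the K x K matrix of proximity scores that lets nearby variant
#' sites reinforce each other's association signal.  The tri-weight measure
#' is compactly supported: \eqn{c(d) = (1 - (d/d_{max})^2)^3} for
#' \eqn{d < d_{max}} and 0 beyond, so two sites further apart than `d_max`
#' never interact.  The diagonal is 1 and entries decrease with distance.
#' With `d_max` below the smallest inter-site gap the kernel degenerates to
#' the identity matrix and the spatial test reduces to its
#' no-spatial-information special case (ADA).
#'
#' The kernel is not required to be positive semi-definite; the test uses
#' the statistic only through permutation ranks, so indefiniteness is
#' harmless.
#'
#' @param D distance matrix from [pairwise_distances()].
#' @param d_max maximum interaction distance in bp (default 20000).
#' @return A `kernel_matrix` object with fields `values`, `measure`,
#'   `d_max`.
#' @export
triweight_kernel <- function(D, d_max = 20000) {
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0)
    stop("d_max must be a single positive number")
  r <- D / d_max
  C <- ifelse(r < 1, (1 - r^2)^3, 0)
  diag(C) <- 1
  new_kernel_matrix(C, "triweight", d_max)
}

#' Identity kernel (no spatial information)
#'
#' The exact K x K identity matrix.  Using it in [cluster_test()] discards
#' all positional information and yields the adaptive combination of
#' P-values (ADA) test; results computed with it are tagged `method = "ADA"`.
#'
#' @param K number of sites (>= 1).
#' @return A `kernel_matrix` with `measure = "identity"`.
#' @export
identity_kernel <- function(K) {
  if (K < 1L) stop("K must be >= 1")
  new_kernel_matrix(diag(K), "identity")
}

#' Export a kernel matrix as TSV (debugging aid)
#'
#' @param kernel a `kernel_matrix`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  utils::write.table(kernel$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
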