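BASES <- c("A", "C", "G", "T")

#' Replicated per-position read counts
#'
#' Container for the observed data: for each genomic position `j` (J in
#' total) and sequencing replicate `i` (N in total), the number of reads of
#' each nucleotide. The model works with the derived quantities `r` (reads
#' carrying a non-reference base) and `n` (total reads).
#'
#' @param base_counts integer array of dimension `J x N x 4`, the last
#'   dimension ordered A, C, G, T.
#' @param positions integer vector of 1-based genomic coordinates, length J,
#'   strictly increasing.
#' @param ref character vector of reference bases (one of A/C/G/T), length J.
#' @param chrom single sequence (chromosome) name shared by all positions.
#'
#' @return An object of class `read_count_matrix` with elements `chrom`,
#'   `positions`, `ref`, `base_counts`, `r` (J x N), `n` (J x N), `J`, `N`.
#' @export
read_count_matrix <- function(base_counts, positions, ref, chrom = "seq1") {
  if (length(dim(base_counts)) != 3L || dim(base_counts)[3] != 4L) {
    stop_input("base_counts must be a J x N x 4 array")
  }
  J <- dim(base_counts)[1]
  N <- dim(base_counts)[2]
  if (J < 1L || N < 1L) stop_input("need J >= 1 positions and N >= 1 replicates")
  if (length(positions) != J) stop_input("positions must have length J = %d", J)
  if (length(ref) != J) stop_input("ref must have length J = %d", J)
  if (!all(ref %in% BASES)) stop_input("ref bases must be one of A,C,G,T")
  if (any(positions < 1) || any(positions != round(positions))) {
    stop_input("positions must be positive 1-based integers")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop_input("positions must be strictly increasing")
  }
  if (any(!is.finite(base_counts)) || any(base_counts < 0) ||
      any(base_counts != round(base_counts))) {
    stop_input("base_counts must be non-negative integers")
  }
  dimnames(base_counts) <- list(NULL, NULL, BASES)
  n <- base_counts[, , 1] + base_counts[, , 2] +
       base_counts[, , 3] + base_counts[, , 4]
  ref_idx <- match(ref, BASES)
  refc <- base_counts[cbind(rep(seq_len(J), N),
                            rep(seq_len(N), each = J),
                            rep(ref_idx, N))]
  r <- n - matrix(refc, J, N)
  dim(n) <- dim(r) <- c(J, N)
  structure(list(chrom = chrom, positions = as.integer(positions),
                 ref = ref, base_counts = base_counts,
                 r = r, n = n, J = J, N = N),
            class = "read_count_matrix")
}

#' @export
print.read_count_matrix <- function(x, ...) {
  cat(sprintf("read_count_matrix: %d positions x %d replicates on %s\n",
              x$J, x$N, x$chrom))
  cat(sprintf("  positions %d..%d; median depth %.0f; pooled non-ref rate %.4g\n",
              min(x$positions), max(x$positions),
              stats::median(x$n), sum(x$r) / max(1, sum(x$n))))
  invisible(x)
}

#' Model parameters of the hierarchical Beta-Binomial model
#'
#' `mu0` is the global non-reference read rate (the shared error level),
#' `M0` the global precision tying position-level rates together, and `M`
#' the per-position precision governing replicate-to-replicate variation.
#'
#' @param mu0 scalar in (0,1).
#' @param M0 positive scalar.
#' @param M positive vector, one entry per position.
#' @return Object of class `model_params`.
#' @export
model_params <- function(mu0, M0, M) {
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0) ||
      mu0 <= 0 || mu0 >= 1) {
    stop_input("mu0 must be a single number in (0,1)")
  }
  if (!is.numeric(M0) || length(M0) != 1L || !is.finite(M0) || M0 <= 0) {
    stop_input("M0 must be a single positive number")
  }
  if (!is.numeric(M) || length(M) < 1L || any(!is.finite(M)) || any(M <= 0)) {
    stop_input("M must be a positive vector")
  }
  structure(list(mu0 = mu0, M0 = M0, M = as.numeric(M)),
            class = "model_params")
}

#' Variational parameters
#'
#' Beta shape parameters of the factorized variational posterior:
#' `gamma[j, ]` parameterizes q(mu_j) and `delta[j, i, ]` parameterizes
#' q(theta_ji).
#'
#' @param gamma J x 2 matrix of positive Beta shapes.
#' @param delta J x N x 2 array of positive Beta shapes.
#' @return Object of class `variational_params`.
#' @export
variational_params <- function(gamma, delta) {
  gamma <- as.matrix(gamma)
  if (ncol(gamma) != 2L) stop_input("gamma must be a J x 2 matrix")
  if (length(dim(delta)) != 3L || dim(delta)[3] != 2L) {
    stop_input("delta must be a J x N x 2 array")
  }
  if (dim(delta)[1] != nrow(gamma)) {
    stop_input("gamma and delta disagree on the number of positions")
  }
  if (any(!is.finite(gamma)) || any(gamma <= 0) ||
      any(!is.finite(delta)) || any(delta <= 0)) {
    stop_input("all variational shape parameters must be positive and finite")
  }
  structure(list(gamma = gamma, delta = delta), class = "variational_params")
}

model_estimate <- function(params, vparams, elbo_trace, converged,
                           chrom = NULL, positions = NULL, ref = NULL) {
  nraf <- vparams$gamma[, 1] / (vparams$gamma[, 1] + vparams$gamma[, 2])
  structure(list(params = params, vparams = vparams,
                 elbo_trace = elbo_trace, converged = converged,
                 nraf = nraf, chrom = chrom, positions = positions,
                 ref = ref),
            class = "model_estimate")
}

#' @export
print.model_estimate <- function(x, ...) {
  cat(sprintf("model_estimate: %d positions, %d EM iterations (%s)\n",
              nrow(x$vparams$gamma), length(x$elbo_trace),
              if (isTRUE(x$converged)) "converged" else "not converged"))
  cat(sprintf("  mu0 = %.4g, M0 = %.4g, final ELBO = %.6g\n",
              x$params$mu0, x$params$M0,
              x$elbo_trace[length(x$elbo_trace)]))
  invisible(x)
}

#' Convert a Beta distribution from mean-precision to shape form
#'
#' The mean-precision convention Beta(mean, precision) used throughout the
#' model maps to shapes `(mean * precision, (1 - mean) * precision)`; the
#' convention is fixed by the conjugate posterior update
#' Beta(r + M mu, n - r + M (1 - mu)).
#'
#' @param mean rate(s) in (0,1).
#' @param precision positive precision(s) (the sum of the two shapes).
#' @return For scalar input, a numeric vector `c(shape1, shape2)`; for
#'   vector input a matrix with columns `shape1`, `shape2`.
#' @export
beta_shapes_from_mean_precision <- function(mean, precision) {
  if (any(!is.finite(mean)) || any(mean <= 0) || any(mean >= 1)) {
    stop_input("mean must lie strictly inside (0,1)")
  }
  if (any(!is.finite(precision)) || any(precision <= 0)) {
    stop_input("precision must be positive")
  }
  a <- mean * precision
  b <- (1 - mean) * precision
  if (length(a) == 1L && length(b) == 1L) {
    c(shape1 = a, shape2 = b)
  } else {
    cbind(shape1 = a, shape2 = b)
  }
}
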