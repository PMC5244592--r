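# ELBO mathematics: expected log Beta normalizer under q(mu), Beta
# entropies, and the full evidence lower bound.
#
# The expected log normalizer E_q[log(Gamma(M)/(Gamma(mu M) Gamma((1-mu)M)))]
# has no closed form, but its endpoint log-singularities can be removed
# exactly: log Gamma(x) = log Gamma(1 + x) - log x, so
#   log(Gamma(M)/(Gamma(mu M) Gamma((1-mu) M)))
#     = log Gamma(M) + 2 log M + log mu + log(1-mu)
#       - log Gamma(1 + mu M) - log Gamma(1 + (1-mu) M).
# E_q[log mu] and E_q[log(1-mu)] are exact digamma identities; only the
# smooth log Gamma(1 + .) part is integrated numerically, by Gauss-Legendre
# in the CDF-transformed variable u with mu = qbeta(u; gamma), which keeps
# the rule accurate even when q(mu) is extremely concentrated.

#' Expected log Beta normalizer under a Beta variational distribution
#'
#' Computes `E_q[log(Gamma(M) / (Gamma(mu M) Gamma((1 - mu) M)))]` where
#' `q(mu) = Beta(gamma[1], gamma[2])`, the one non-analytic ingredient of
#' the evidence lower bound and of the precision updates.
#'
#' @param gamma positive Beta shape pair (length 2).
#' @param M positive precision scalar.
#' @param quad_order order of the Gauss-Legendre rule (default 50).
#' @return A finite scalar.
#' @export
expected_log_beta_norm <- function(gamma, M, quad_order = 50) {
  if (length(gamma) != 2L || any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop_input("gamma must be a pair of positive finite Beta shapes")
  }
  if (length(M) != 1L || !is.finite(M) || M <= 0) {
    stop_input("M must be a single positive number")
  }
  rule <- gauss_legendre_01(quad_order)
  # Composite rule over a symmetric graded mesh in the CDF variable: the
  # map u -> qbeta(u) has endpoint-derivative singularities like u^(1/g)
  # for large shapes, which a single panel resolves only slowly. The mesh
  # is symmetric about 1/2 so the shape-swap identity holds exactly.
  edges <- c(0, 1e-3, 1e-2, 0.1, 0.5, 0.9, 0.99, 0.999, 1)
  g1 <- unname(gamma[1]); g2 <- unname(gamma[2])
  quad <- 0
  for (p in seq_len(length(edges) - 1L)) {
    a <- edges[p]; b <- edges[p + 1L]
    u <- a + (b - a) * rule$x
    mu <- stats::qbeta(u, g1, g2)
    quad <- quad + (b - a) *
      sum(rule$w * (lgamma(1 + mu * M) + lgamma(1 + (1 - mu) * M)))
  }
  g0 <- g1 + g2
  val <- lgamma(M) + 2 * log(M) +
    (digamma(g1) - digamma(g0)) + (digamma(g2) - digamma(g0)) - quad
  if (!is.finite(val)) {
    stop_numeric("expected_log_beta_norm is non-finite for gamma=(%g,%g), M=%g",
                 gamma[1], gamma[2], M)
  }
  val
}

# Vectorized over positions: mu_nodes is J x K (quadrature nodes per
# position), w length K, g1/g2/M length J (or scalars). Returns length-J.
elbn_given_nodes <- function(mu_nodes, w, g1, g2, M) {
  g0 <- g1 + g2
  smooth <- lgamma(1 + mu_nodes * M) + lgamma(1 + (1 - mu_nodes) * M)
  if (is.matrix(mu_nodes)) {
    quad <- drop(smooth %*% w)
  } else {
    quad <- sum(w * smooth)
  }
  lgamma(M) + 2 * log(M) +
    (digamma(g1) - digamma(g0)) + (digamma(g2) - digamma(g0)) - quad
}

# qbeta nodes for each position (rows of gamma), as a J x K matrix.
beta_quantile_nodes <- function(gamma, u) {
  J <- nrow(gamma)
  K <- length(u)
  matrix(stats::qbeta(rep(u, each = J), gamma[, 1], gamma[, 2]), J, K)
}

#' Entropy of a Beta distribution
#'
#' @param a,b positive shape parameters (vectorized).
#' @return Differential entropy in nats.
#' @export
beta_entropy <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    stop_input("Beta shapes must be positive and finite")
  }
  lbeta(a, b) - (a - 1) * digamma(a) - (b - 1) * digamma(b) +
    (a + b - 2) * digamma(a + b)
}

# Shared digamma moments of q(theta): E[log theta] and E[log(1-theta)].
delta_log_moments <- function(delta) {
  d1 <- delta[, , 1, drop = FALSE]; dim(d1) <- dim(delta)[1:2]
  d2 <- delta[, , 2, drop = FALSE]; dim(d2) <- dim(delta)[1:2]
  dg0 <- digamma(d1 + d2)
  list(d1 = d1, d2 = d2,
       elog = digamma(d1) - dg0, elog1m = digamma(d2) - dg0)
}

#' Evidence lower bound of the hierarchical Beta-Binomial model
#'
#' Evaluates the variational objective
#' `L(q, phi) = E_q[log p(r, mu, theta | n; phi)] - E_q[log q(mu, theta)]`,
#' which is always a lower bound on the log evidence `log p(r | n; phi)`.
#' Positions are conditionally independent given (mu0, M0), so the bound is
#' a sum of per-position terms; the only numerically integrated piece is the
#' expected log Beta normalizer of the replicate-level prior.
#'
#' @param counts a [read_count_matrix()].
#' @param vparams a [variational_params()].
#' @param params a [model_params()].
#' @param quad_order Gauss-Legendre order for the integrated term.
#' @return A finite scalar.
#' @export
elbo <- function(counts, vparams, params, quad_order = 50) {
  stopifnot(inherits(counts, "read_count_matrix"),
            inherits(vparams, "variational_params"),
            inherits(params, "model_params"))
  J <- counts$J; N <- counts$N
  if (nrow(vparams$gamma) != J || dim(vparams$delta)[2] != N) {
    stop_input("variational parameter dimensions do not match the counts")
  }
  if (length(params$M) != J) stop_input("params$M must have one entry per position")
  g1 <- vparams$gamma[, 1]; g2 <- vparams$gamma[, 2]
  mom <- delta_log_moments(vparams$delta)
  r <- counts$r; n <- counts$n
  M <- params$M; mu0 <- params$mu0; M0 <- params$M0

  # (i) E_q[log Binomial(r | n, theta)]; identically 0 where n = 0.
  ll_binom <- sum(lchoose(n, r) + r * mom$elog + (n - r) * mom$elog1m)

  # (ii) E_q[log Beta(theta | mu, M)]: integrated normalizer (once per
  # replicate) plus cross terms, which factor since q(mu) and q(theta) are
  # independent and the exponent is linear in mu.
  rule <- gauss_legendre_01(quad_order)
  mu_nodes <- beta_quantile_nodes(vparams$gamma, rule$x)
  Q <- elbn_given_nodes(mu_nodes, rule$w, g1, g2, M)
  emu <- g1 / (g1 + g2)
  ll_theta <- sum(N * Q +
                  (M * emu - 1) * rowSums(mom$elog) +
                  (M * (1 - emu) - 1) * rowSums(mom$elog1m))

  # (iii) E_q[log Beta(mu | mu0, M0)] -- fully analytic.
  dg0 <- digamma(g1 + g2)
  elog_mu <- digamma(g1) - dg0
  elog_1mmu <- digamma(g2) - dg0
  ll_mu <- J * (lgamma(M0) - lgamma(mu0 * M0) - lgamma((1 - mu0) * M0)) +
    (mu0 * M0 - 1) * sum(elog_mu) + ((1 - mu0) * M0 - 1) * sum(elog_1mmu)

  # (iv) entropies of q.
  ent <- sum(beta_entropy(g1, g2)) + sum(beta_entropy(mom$d1, mom$d2))

  out <- ll_binom + ll_theta + ll_mu + ent
  if (!is.finite(out)) stop_numeric("ELBO evaluated non-finite")
  out
}
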