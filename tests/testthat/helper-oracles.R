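# Independent oracles used to validate the variational machinery.
# Everything here is built from scratch on quadrature / closed forms and
# never calls the package's ELBO internals.

# log Beta-Binomial pmf with mean-precision Beta(mu, M) mixing
lbetabinom <- function(r, n, mu, M) {
  lchoose(n, r) + lbeta(r + mu * M, n - r + (1 - mu) * M) -
    lbeta(mu * M, (1 - mu) * M)
}

# Marginal log evidence log p(r | n; mu0, M0, M) for a single position:
# the theta integrals are Beta-Binomial in closed form, leaving a 1-D
# integral over mu, done by high-order Gauss-Legendre in the prior CDF.
log_evidence_oracle <- function(r, n, mu0, M0, M, order = 400) {
  gl <- pracma::gaussLegendre(order, 0, 1)
  mu <- qbeta(gl$x, mu0 * M0, (1 - mu0) * M0)
  mu <- pmin(pmax(mu, 1e-14), 1 - 1e-14)
  ll <- vapply(mu, function(m) sum(lbetabinom(r, n, m, M)), numeric(1))
  mx <- max(ll)
  mx + log(sum(gl$w * exp(ll - mx)))
}

# Posterior mean of mu for a single position, same construction.
posterior_mean_mu_oracle <- function(r, n, mu0, M0, M, order = 400) {
  gl <- pracma::gaussLegendre(order, 0, 1)
  mu <- qbeta(gl$x, mu0 * M0, (1 - mu0) * M0)
  mu <- pmin(pmax(mu, 1e-14), 1 - 1e-14)
  ll <- vapply(mu, function(m) sum(lbetabinom(r, n, m, M)), numeric(1))
  w <- gl$w * exp(ll - max(ll))
  sum(w * mu) / sum(w)
}

# Posterior mean of theta_i: E[(r_i + mu M) / (n_i + M)] over p(mu | r).
posterior_mean_theta_oracle <- function(i, r, n, mu0, M0, M, order = 400) {
  gl <- pracma::gaussLegendre(order, 0, 1)
  mu <- qbeta(gl$x, mu0 * M0, (1 - mu0) * M0)
  mu <- pmin(pmax(mu, 1e-14), 1 - 1e-14)
  ll <- vapply(mu, function(m) sum(lbetabinom(r, n, m, M)), numeric(1))
  w <- gl$w * exp(ll - max(ll))
  sum(w * (r[i] + mu * M) / (n[i] + M)) / sum(w)
}

# E_q[log(Gamma(M) / (Gamma(mu M) Gamma((1-mu) M)))] by adaptive
# quadrature on the raw integrand (independent of the package's
# singularity-extracted scheme).
elbn_oracle <- function(g1, g2, M) {
  f <- function(m) {
    dbeta(m, g1, g2) * (lgamma(M) - lgamma(m * M) - lgamma((1 - m) * M))
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}

# Beta entropy by quadrature of -q log q.
beta_entropy_oracle <- function(a, b) {
  f <- function(m) {
    d <- dbeta(m, a, b)
    ifelse(d > 0, -d * dbeta(m, a, b, log = TRUE), 0)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}

# Tiny count-matrix builder: non-reference reads all on one alternative
# base unless given per-base counts directly.
make_counts <- function(r, n, ref = NULL, positions = NULL, chrom = "t") {
  r <- as.matrix(r); n <- as.matrix(n)
  J <- nrow(r); N <- ncol(r)
  if (is.null(ref)) ref <- rep("A", J)
  if (is.null(positions)) positions <- seq_len(J)
  bc <- array(0L, dim = c(J, N, 4))
  ref_idx <- match(ref, c("A", "C", "G", "T"))
  for (j in seq_len(J)) {
    alt <- setdiff(1:4, ref_idx[j])[1]
    bc[j, , ref_idx[j]] <- n[j, ] - r[j, ]
    bc[j, , alt] <- r[j, ]
  }
  read_count_matrix(bc, positions, ref, chrom)
}

# Random small valid instance for the evidence-bound checks.
random_small_instance <- function() {
  J <- 1L
  N <- sample(1:2, 1)
  n <- matrix(sample(5:50, N, replace = TRUE), J, N)
  mu_true <- runif(1, 0.02, 0.5)
  r <- matrix(rbinom(N, n, mu_true), J, N)
  params <- model_params(mu0 = runif(1, 0.05, 0.5),
                         M0 = runif(1, 1, 50),
                         M = runif(1, 1, 100))
  gamma <- matrix(runif(2, 0.5, 20), 1, 2)
  delta <- array(runif(2 * N, 0.5, 30), dim = c(1, N, 2))
  list(counts = make_counts(r, n), params = params,
       vparams = variational_params(gamma, delta))
}
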