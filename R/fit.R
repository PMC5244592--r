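# Coordinate-ascent variational EM.
#
# One iteration updates, in order: delta (exact conjugate coordinate
# maximizer given E_q[mu]), gamma (batched damped-Newton ascent of the
# per-position ELBO block), then mu0/M0 (joint bounded quasi-Newton on the
# analytic block) and M_j (batched 1-D Newton). Every block update is
# accepted per position only if its objective does not decrease, so the
# ELBO is monotone by construction up to the quadrature tolerance.

#' Fit configuration
#'
#' @param max_iterations maximum number of EM iterations.
#' @param elbo_rel_tol stop when the relative ELBO change drops below this.
#' @param quad_order Gauss-Legendre order for integrated ELBO terms.
#' @param seed integer seed for any randomized restarts (none are used by
#'   the default deterministic optimizer; kept for interface stability).
#' @param fix_M0 optional positive scalar; when set, the global precision
#'   M0 is pinned at this value and excluded from the M-step (used for
#'   sensitivity analysis of the shrinkage strength).
#' @param bounds box bounds for the optimized quantities. The lower bound
#'   on the local precisions M_j (default 100) encodes that technical
#'   replicates share a position's error rate to within a few percent
#'   absolute; letting M_j fall further opens a degenerate explanation in
#'   which replicate-level overdispersion absorbs all position-level
#'   signal and the global prior collapses (see the methods vignette).
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(max_iterations = 100, elbo_rel_tol = 1e-5,
                       quad_order = 50, seed = NULL, fix_M0 = NULL,
                       bounds = list(mu0 = c(1e-6, 1 - 1e-6),
                                     M0 = c(1e-3, 1e3),
                                     M = c(100, 1e8),
                                     shape = c(1e-3, 1e10))) {
  if (max_iterations < 1) stop_input("max_iterations must be >= 1")
  if (elbo_rel_tol <= 0) stop_input("elbo_rel_tol must be > 0")
  if (!is.null(fix_M0) && (!is.finite(fix_M0) || fix_M0 <= 0)) {
    stop_input("fix_M0 must be a positive number")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 elbo_rel_tol = elbo_rel_tol,
                 quad_order = as.integer(quad_order),
                 seed = seed, fix_M0 = fix_M0, bounds = bounds),
            class = "fit_config")
}

#' Initialize model and variational parameters from the data
#'
#' Prior-smoothed empirical rates seed the variational posteriors:
#' `delta_ji = (r_ji + 1, n_ji - r_ji + 1)`, `gamma_j` by method of moments
#' on the smoothed per-replicate rates (variance floored at 1e-10 so N = 1
#' works), `mu0` as the median pooled non-reference rate, and the
#' precisions by method-of-moments estimates; everything is clipped into
#' its valid box so the output always satisfies the type invariants.
#'
#' @param counts a [read_count_matrix()].
#' @return list with elements `params` and `vparams`.
#' @export
vb_initialize <- function(counts) {
  stopifnot(inherits(counts, "read_count_matrix"))
  J <- counts$J; N <- counts$N
  r <- counts$r; n <- counts$n
  cc <- 1
  d1 <- r + cc
  d2 <- n - r + cc
  delta <- array(c(d1, d2), dim = c(J, N, 2))

  p <- (r + cc) / (n + 2 * cc)
  m <- rowMeans(p)
  if (N > 1) {
    v <- rowSums((p - m)^2) / (N - 1)
  } else {
    v <- rep(0, J)
  }
  v <- pmax(v, 1e-10)
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  prec <- pmin(pmax(m * (1 - m) / v - 1, 1e-3), 1e6)
  gamma <- cbind(m * prec, (1 - m) * prec)

  pooled <- rowSums(r) / pmax(1, rowSums(n))
  mu0 <- pmin(pmax(stats::median(pooled), 1e-6), 1 - 1e-6)

  mbar <- mean(m)
  vbar <- max(stats::var(m), 1e-10)
  if (!is.finite(vbar)) vbar <- 1e-10  # J = 1
  M0 <- pmin(pmax(mbar * (1 - mbar) / vbar - 1, 1e-3), 1e6)
  M <- prec

  list(params = model_params(mu0, M0, M),
       vparams = variational_params(gamma, delta))
}

# ---- internal batched optimizers ------------------------------------------

# Generic vectorized damped-Newton ascent over per-position parameter
# blocks (p = 1, 2 or 3 parameters per position). fn maps a (J x p)
# parameter matrix to a length-J objective vector; non-finite values are
# treated as -Inf (never accepted). Derivatives are central finite
# differences; the Newton system is solved in closed form per position,
# falling back to a normalized gradient step when the local Hessian is not
# negative definite.
batch_newton_ascent <- function(x, fn, lower, upper, max_iter = 40,
                                h = 1e-4, step_cap = 4) {
  safe <- function(z) { z[!is.finite(z)] <- -Inf; z }
  p <- ncol(x)
  J <- nrow(x)
  f0 <- safe(fn(x))
  active <- rep(TRUE, J)
  shift <- function(i, s, j = NULL) {
    y <- x; y[, i] <- y[, i] + s * h
    if (!is.null(j)) y[, j] <- y[, j] + s * h
    y
  }
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    if (p == 1L) {
      fp <- safe(fn(shift(1, 1))); fm <- safe(fn(shift(1, -1)))
      gr <- (fp - fm) / (2 * h)
      hess <- (fp - 2 * f0 + fm) / h^2
      d <- ifelse(is.finite(hess) & hess < 0, -gr / hess, sign(gr))
      d <- matrix(pmin(pmax(d, -step_cap), step_cap), ncol = 1)
    } else {
      fp <- fm <- matrix(0, J, p)
      for (i in seq_len(p)) {
        fp[, i] <- safe(fn(shift(i, 1)))
        fm[, i] <- safe(fn(shift(i, -1)))
      }
      gr <- (fp - fm) / (2 * h)
      H <- array(0, c(J, p, p))
      for (i in seq_len(p)) H[, i, i] <- (fp[, i] - 2 * f0 + fm[, i]) / h^2
      for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
        fij <- safe(fn(shift(i, 1, j)))
        H[, i, j] <- H[, j, i] <- (fij - fp[, i] - fp[, j] + f0) / h^2
      }
      d <- matrix(0, J, p)
      ok <- rep(FALSE, J)
      if (p == 2L) {
        det2 <- H[, 1, 1] * H[, 2, 2] - H[, 1, 2]^2
        ok <- is.finite(det2) & det2 > 0 & H[, 1, 1] < 0
        d[, 1] <- -(H[, 2, 2] * gr[, 1] - H[, 1, 2] * gr[, 2]) / det2
        d[, 2] <- -(-H[, 1, 2] * gr[, 1] + H[, 1, 1] * gr[, 2]) / det2
      } else {
        a <- H[, 1, 1]; b <- H[, 1, 2]; cc <- H[, 1, 3]
        e <- H[, 2, 2]; f <- H[, 2, 3]; g <- H[, 3, 3]
        det2 <- a * e - b^2
        det3 <- a * (e * g - f^2) - b * (b * g - cc * f) + cc * (b * f - cc * e)
        ok <- is.finite(det3) & a < 0 & det2 > 0 & det3 < 0
        # adjugate rows of the symmetric 3x3
        A11 <- e * g - f^2; A12 <- cc * f - b * g; A13 <- b * f - cc * e
        A22 <- a * g - cc^2; A23 <- b * cc - a * f
        A33 <- a * e - b^2
        d[, 1] <- -(A11 * gr[, 1] + A12 * gr[, 2] + A13 * gr[, 3]) / det3
        d[, 2] <- -(A12 * gr[, 1] + A22 * gr[, 2] + A23 * gr[, 3]) / det3
        d[, 3] <- -(A13 * gr[, 1] + A23 * gr[, 2] + A33 * gr[, 3]) / det3
      }
      gn <- sqrt(rowSums(gr^2))
      for (i in seq_len(p)) {
        d[, i] <- ifelse(ok, d[, i], gr[, i] / pmax(gn, 1e-12))
      }
      dn <- sqrt(rowSums(d^2))
      scl <- ifelse(dn > step_cap, step_cap / dn, 1)
      d <- d * scl
      d[!is.finite(d)] <- 0
    }
    d[!active, ] <- 0
    accepted <- rep(FALSE, nrow(x))
    x_new <- x; f_new <- f0
    for (t in c(1, 0.5, 0.1, 0.01)) {
      cand <- x + t * d
      for (k in seq_len(p)) cand[, k] <- pmin(pmax(cand[, k], lower[k]), upper[k])
      fc <- safe(fn(cand))
      take <- !accepted & active & (fc > f0 + 1e-12)
      if (any(take)) {
        x_new[take, ] <- cand[take, , drop = FALSE]
        f_new[take] <- fc[take]
        accepted <- accepted | take
      }
      if (all(accepted | !active)) break
    }
    moved <- sqrt(rowSums((x_new - x)^2))
    improved <- f_new - f0
    x <- x_new; f0 <- f_new
    active <- active & accepted & (moved > 1e-7 | improved > 1e-10 * (1 + abs(f0)))
  }
  list(x = x, f = f0)
}

# Inner-optimizer surface for the gamma update. The smooth part
# E_q[lgamma(1 + mu M) + lgamma(1 + (1 - mu) M)] is integrated in logit
# space by Gauss-Hermite with the proposal matched to the *exact* logit
# moments of Beta(g1, g2) (mean psi(g1) - psi(g2), variance
# psi'(g1) + psi'(g2)), so the rule adapts to every candidate without
# qbeta calls. Essentially exact when both shapes exceed ~2; for smaller
# shapes it is a smoothly biased surrogate, which is harmless because the
# E-step accepts a gamma move only if the exact block objective improves.
.gh_cache <- new.env(parent = emptyenv())

gauss_hermite_rule <- function(order) {
  key <- as.character(order)
  rule <- .gh_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussHermite(as.integer(order))
    rule$lw <- log(rule$w) + rule$x^2
    .gh_cache[[key]] <- rule
  }
  rule
}

# The conjugate maximizer of q(theta) given E_q[mu] and M is closed form,
# so q(theta) can be profiled out of the per-position objective: every
# evaluation at (gamma_j, M_j) implicitly carries its own optimal delta.
# Ascent on the profiled objective is ascent on the full ELBO, and it
# removes the delta <-> gamma coordinate coupling that makes strictly
# alternating updates crawl.
profile_delta <- function(r, n, M, emu, sh) {
  d1 <- pmin(pmax(r + M * emu, sh[1]), sh[2])
  d2 <- pmin(pmax(n - r + M * (1 - emu), sh[1]), sh[2])
  list(d1 = d1, d2 = d2)
}

# Per-position ELBO contribution (without the lchoose constant) with
# q(theta) profiled at its conjugate optimum. Shared by the approximate
# (Gauss-Hermite) optimizer surface and the exact (CDF-transform
# Gauss-Legendre) accept/revert guard.
profiled_block_terms <- function(g1, g2, M, quadQ, r, n, mu0, M0, sh) {
  emu <- g1 / (g1 + g2)
  pd <- profile_delta(r, n, M, emu, sh)
  d1 <- pd$d1; d2 <- pd$d2
  psi1 <- digamma(d1); psi2 <- digamma(d2); psi0 <- digamma(d1 + d2)
  elogt <- psi1 - psi0
  el1mt <- psi2 - psi0
  T1 <- rowSums(elogt - el1mt)
  T2 <- rowSums(el1mt)
  binom <- rowSums(r * elogt + (n - r) * el1mt)
  Hdelta <- rowSums(lbeta(d1, d2) - (d1 - 1) * psi1 - (d2 - 1) * psi2 +
                    (d1 + d2 - 2) * psi0)
  dgg0 <- digamma(g1 + g2)
  elog <- digamma(g1) - dgg0
  elog1m <- digamma(g2) - dgg0
  N <- ncol(r)
  Q <- lgamma(M) + 2 * log(M) + elog + elog1m - quadQ
  binom + N * Q + M * (emu * T1 + T2) - T1 - 2 * T2 +
    (mu0 * M0 - 1) * elog + ((1 - mu0) * M0 - 1) * elog1m +
    beta_entropy(g1, g2) + Hdelta
}

# Optimizer surface: the smooth part of the expected log Beta normalizer
# integrated by moment-matched Gauss-Hermite in logit space (see notes at
# gauss_hermite_rule). joint = TRUE reads M_j from the third column of x.
make_profiled_objective <- function(M, r, n, mu0, M0, gh, sh, joint = FALSE) {
  tk <- gh$x
  lwk <- gh$lw
  ones <- rep(1, length(tk))
  function(x) {
    g1 <- exp(x[, 1]); g2 <- exp(x[, 2])
    if (joint) M <- exp(x[, 3])
    mz <- digamma(g1) - digamma(g2)
    vz <- trigamma(g1) + trigamma(g2)
    z <- outer(mz, ones) + sqrt(2 * vz) %o% tk
    lmu <- stats::plogis(z, log.p = TRUE)
    l1m <- stats::plogis(-z, log.p = TRUE)
    logp <- g1 * lmu + g2 * l1m - lbeta(g1, g2)
    mu <- exp(lmu)
    s <- lgamma(1 + mu * M) + lgamma(1 + (1 - mu) * M)
    quadQ <- sqrt(2 * vz) * rowSums(exp(sweep(logp, 2, lwk, "+")) * s)
    profiled_block_terms(g1, g2, M, quadQ, r, n, mu0, M0, sh)
  }
}

# Exact profiled block objective: quadrature nodes at each position's own
# gamma via the CDF transform. Used for accept/revert decisions, which
# makes ELBO monotonicity exact.
profiled_block_exact <- function(gamma, M, r, n, mu0, M0, rule, sh) {
  g1 <- gamma[, 1]; g2 <- gamma[, 2]
  mu <- beta_quantile_nodes(gamma, rule$x)
  quadQ <- (lgamma(1 + mu * M) + lgamma(1 + (1 - mu) * M)) %*% rule$w
  profiled_block_terms(g1, g2, M, drop(quadQ), r, n, mu0, M0, sh)
}

#' E-step: update the variational distribution
#'
#' Updates `delta` by the exact conjugate coordinate maximizer
#' `Beta(r + M E_q[mu], n - r + M (1 - E_q[mu]))` and then `gamma` by
#' bounded Newton ascent of each position's ELBO block (the block involves
#' the numerically integrated expected log Beta normalizer). Positions are
#' independent; a position where the optimizer fails keeps its previous
#' values with a warning.
#'
#' @param counts a [read_count_matrix()].
#' @param vparams current [variational_params()].
#' @param params current [model_params()].
#' @param config a [fit_config()].
#' @return Updated [variational_params()].
#' @export
vb_e_step <- function(counts, vparams, params, config = fit_config()) {
  J <- counts$J; N <- counts$N
  M <- params$M
  sh <- config$bounds$shape
  rule <- gauss_legendre_01(config$quad_order)
  gh <- gauss_hermite_rule(24)
  r <- counts$r; n <- counts$n
  gamma <- vparams$gamma

  x0 <- cbind(log(gamma[, 1]), log(gamma[, 2]))
  xn <- .profiled_newton_cpp(x0, r, n, M, FALSE, params$mu0, params$M0,
                             gh$x, gh$lw, sh[1], sh[2],
                             rep(log(sh[1]), 2), rep(log(sh[2]), 2),
                             40L, 1e-4, 2)
  # exact monotone guard: revert positions whose block objective worsened
  gamma_new <- cbind(exp(xn[, 1]), exp(xn[, 2]))
  f_new <- profiled_block_exact(gamma_new, M, r, n, params$mu0, params$M0,
                                rule, sh)
  f_old <- profiled_block_exact(gamma, M, r, n, params$mu0, params$M0,
                                rule, sh)
  f_new[!is.finite(f_new)] <- -Inf
  worse <- f_new < f_old
  if (any(worse)) {
    bad <- f_new < f_old - 1e-6 * (1 + abs(f_old))
    if (any(bad)) {
      warn_vbsnv("gamma optimizer made no progress at %d position(s) (%s); keeping previous values",
                 sum(bad), paste(utils::head(which(bad), 5), collapse = ","))
    }
    gamma_new[worse, ] <- gamma[worse, , drop = FALSE]
  }
  emu <- gamma_new[, 1] / (gamma_new[, 1] + gamma_new[, 2])
  pd <- profile_delta(r, n, M, emu, sh)
  variational_params(gamma_new, array(c(pd$d1, pd$d2), dim = c(J, N, 2)))
}

# Exact (mu0, M0) block maximizer given q(mu); shared by vb_m_step and the
# ridge accelerator.
update_prior_block <- function(gamma, mu0, M0, config) {
  g1 <- gamma[, 1]; g2 <- gamma[, 2]
  dgg0 <- digamma(g1 + g2)
  selog <- sum(digamma(g1) - dgg0)
  selog1m <- sum(digamma(g2) - dgg0)
  J <- nrow(gamma)
  b <- config$bounds
  prior_obj <- function(m, MM) {
    J * (lgamma(MM) - lgamma(m * MM) - lgamma((1 - m) * MM)) +
      (m * MM - 1) * selog + ((1 - m) * MM - 1) * selog1m
  }
  f_old <- prior_obj(mu0, M0)
  if (is.null(config$fix_M0)) {
    res <- tryCatch(
      stats::optim(c(stats::qlogis(mu0), log(M0)),
                   fn = function(p) prior_obj(stats::plogis(p[1]), exp(p[2])),
                   method = "L-BFGS-B",
                   lower = c(stats::qlogis(b$mu0[1]), log(b$M0[1])),
                   upper = c(stats::qlogis(b$mu0[2]), log(b$M0[2])),
                   control = list(fnscale = -1, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && res$value >= f_old) {
      mu0 <- stats::plogis(res$par[1]); M0 <- exp(res$par[2])
    }
  } else {
    M0 <- config$fix_M0
    res <- tryCatch(
      stats::optimize(function(p) prior_obj(stats::plogis(p), M0),
                      interval = stats::qlogis(b$mu0), maximum = TRUE,
                      tol = 1e-10),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$objective) &&
        res$objective >= prior_obj(mu0, M0)) {
      mu0 <- stats::plogis(res$maximum)
    }
  }
  list(mu0 = mu0, M0 = M0)
}

# Global ridge accelerator. The blockwise updates can take tiny steps
# along the nearly flat direction where all q(mu_j) precisions grow or
# shrink together; this sub-step line-searches a global rescaling of
# every gamma precision (means fixed) and accepts the best candidate only
# if the full ELBO improves.
ridge_accelerate <- function(counts, vparams, params, config) {
  sh <- config$bounds$shape
  gamma <- vparams$gamma
  emu <- gamma[, 1] / (gamma[, 1] + gamma[, 2])
  prec <- gamma[, 1] + gamma[, 2]
  base <- elbo(counts, vparams, params, config$quad_order)
  best <- list(elbo = base, vparams = vparams, params = params)
  pd <- profile_delta(counts$r, counts$n, params$M, emu, sh)
  delta_prof <- array(c(pd$d1, pd$d2), dim = c(counts$J, counts$N, 2))
  for (lk in c(-1, -0.5, 0.5, 1, 2)) {
    k <- exp(lk)
    prec_k <- pmin(pmax(prec * k, 2 * sh[1]), sh[2])
    gam_k <- cbind(pmin(pmax(emu * prec_k, sh[1]), sh[2]),
                   pmin(pmax((1 - emu) * prec_k, sh[1]), sh[2]))
    vp_k <- variational_params(gam_k, delta_prof)
    val <- tryCatch(elbo(counts, vp_k, params, config$quad_order),
                    error = function(e) -Inf)
    if (is.finite(val) && val > best$elbo) {
      best <- list(elbo = val, vparams = vp_k, params = params)
    }
  }
  best
}

# Robust global error-parameter estimate. The position population of a
# case sample is a mixture of an error class and a (small) variant class;
# a maximum-likelihood fit of the Beta prior is destroyed by the variant
# outliers (M0 collapses toward 0, removing all shrinkage), while on a
# pure error sample at low depth it collapses the other way (M0 -> inf,
# homogenizing the sample). Both failure modes break the calibration of
# the downstream posterior-difference test. Instead, (mu0, M0) are
# estimated once from the bulk of the pooled per-position rates -- top 5%
# trimmed to exclude variant-like positions, binomial sampling noise
# subtracted by method of moments -- and held fixed during EM, in the
# spirit of robust empirical-Bayes hyperparameter estimation. The paper's
# sensitivity analysis for this model family shows the NRAF estimates are
# insensitive to M0 over orders of magnitude.
robust_prior_estimate <- function(counts, bounds) {
  n_tot <- rowSums(counts$n)
  ok <- n_tot > 0
  p <- rowSums(counts$r)[ok] / n_tot[ok]
  keep <- p <= stats::quantile(p, 0.95, names = FALSE)
  mu0 <- pmin(pmax(mean(p[keep]), bounds$mu0[1]), bounds$mu0[2])
  noise <- mean(mu0 * (1 - mu0) / n_tot[ok][keep])
  vp <- if (sum(keep) > 1) stats::var(p[keep]) else NA_real_
  vhat <- max(vp - noise, 1e-12)
  if (!is.finite(vhat)) vhat <- 1e-12
  M0 <- mu0 * (1 - mu0) / vhat - 1
  M0 <- pmin(pmax(M0, 10), bounds$M0[2])
  list(mu0 = mu0, M0 = M0)
}

#' M-step: update the model parameters
#'
#' Maximizes the ELBO terms that depend on phi = (mu0, M0, M): the pair
#' (mu0, M0) enters only the analytic prior block for mu and is optimized
#' jointly by bounded quasi-Newton; each local precision M_j enters only
#' its own position's replicate-level prior terms and is optimized by
#' bounded 1-D Newton with the integrated normalizer evaluated by
#' Gauss-Legendre at fixed q(mu_j) nodes. With `config$fix_M0` set, M0 is
#' left untouched.
#'
#' @inheritParams vb_e_step
#' @return Updated [model_params()].
#' @export
vb_m_step <- function(counts, vparams, params, config = fit_config()) {
  J <- counts$J; N <- counts$N
  g1 <- vparams$gamma[, 1]; g2 <- vparams$gamma[, 2]
  dgg0 <- digamma(g1 + g2)
  b <- config$bounds

  pr <- update_prior_block(vparams$gamma, params$mu0, params$M0, config)
  mu0 <- pr$mu0; M0 <- pr$M0

  # M_j block: 1-D Newton per position, vectorized across positions.
  mom <- delta_log_moments(vparams$delta)
  T1 <- rowSums(mom$elog) - rowSums(mom$elog1m)
  T2 <- rowSums(mom$elog1m)
  emu <- g1 / (g1 + g2)
  rule <- gauss_legendre_01(config$quad_order)
  mu_nodes <- beta_quantile_nodes(vparams$gamma, rule$x)
  W <- matrix(rule$w, J, length(rule$x), byrow = TRUE)
  elog_mu <- digamma(g1) - dgg0
  elog_1mmu <- digamma(g2) - dgg0
  lin <- emu * T1 + T2
  fn <- function(x) {
    M <- exp(x[, 1])
    quad <- rowSums((lgamma(1 + mu_nodes * M) +
                     lgamma(1 + (1 - mu_nodes) * M)) * W)
    Q <- lgamma(M) + 2 * log(M) + elog_mu + elog_1mmu - quad
    N * Q + M * lin
  }
  x0 <- matrix(log(params$M), ncol = 1)
  res <- batch_newton_ascent(x0, fn, log(b$M[1]), log(b$M[2]))
  f_old_M <- fn(x0); f_old_M[!is.finite(f_old_M)] <- -Inf
  worse <- res$f < f_old_M - 1e-9 * (1 + abs(f_old_M))
  if (any(worse)) {
    warn_vbsnv("M update failed at %d position(s); keeping previous values",
               sum(worse))
    res$x[worse, 1] <- x0[worse, 1]
  }
  model_params(mu0, M0, exp(res$x[, 1]))
}

# Joint per-position refinement of (gamma_j, M_j). The pair sits on a
# nearly flat ridge under strictly alternating block updates (tightening
# q(mu_j) favours a larger M_j and vice versa), which makes plain
# coordinate ascent crawl; a joint Newton step moves along the ridge
# directly. Each position's move is accepted only if its exact block
# objective improves, so this sub-step is monotone like the others.
refine_joint <- function(counts, vparams, params, config) {
  J <- counts$J; N <- counts$N
  sh <- config$bounds$shape
  bM <- config$bounds$M
  r <- counts$r; n <- counts$n
  rule <- gauss_legendre_01(config$quad_order)
  gh <- gauss_hermite_rule(24)
  x0 <- cbind(log(vparams$gamma[, 1]), log(vparams$gamma[, 2]),
              log(params$M))
  xn <- .profiled_newton_cpp(x0, r, n, params$M, TRUE, params$mu0,
                             params$M0, gh$x, gh$lw, sh[1], sh[2],
                             c(log(sh[1]), log(sh[1]), log(bM[1])),
                             c(log(sh[2]), log(sh[2]), log(bM[2])),
                             40L, 1e-4, 2)
  gamma_new <- cbind(exp(xn[, 1]), exp(xn[, 2]))
  M_new <- exp(xn[, 3])
  f_new <- profiled_block_exact(gamma_new, M_new, r, n, params$mu0,
                                params$M0, rule, sh)
  f_old <- profiled_block_exact(vparams$gamma, params$M, r, n, params$mu0,
                                params$M0, rule, sh)
  f_new[!is.finite(f_new)] <- -Inf
  worse <- f_new < f_old
  gamma_new[worse, ] <- vparams$gamma[worse, , drop = FALSE]
  M_new[worse] <- params$M[worse]
  emu <- gamma_new[, 1] / (gamma_new[, 1] + gamma_new[, 2])
  pd <- profile_delta(r, n, M_new, emu, sh)
  list(vparams = variational_params(gamma_new,
                                    array(c(pd$d1, pd$d2), dim = c(J, N, 2))),
       params = model_params(params$mu0, params$M0, M_new))
}

#' Fit the hierarchical Beta-Binomial model by variational EM
#'
#' Runs [vb_initialize()], pins the global error parameters (mu0, M0) at a
#' robust trimmed-moment estimate (see the methods vignette; `fix_M0`
#' overrides the precision), then iterates a monotone generalized EM: a
#' joint per-position Newton update of (q(mu_j), q(theta_j), M_j) followed
#' by a global precision-rescaling line search, recording the ELBO after
#' each full iteration, until the relative ELBO change falls below
#' `config$elbo_rel_tol` or `config$max_iterations` is reached. Every
#' sub-step is accepted only if the exact ELBO does not decrease, so the
#' recorded trace is non-decreasing up to quadrature tolerance. The
#' per-position NRAF estimate is the variational posterior mean
#' `gamma_j1 / (gamma_j1 + gamma_j2)`. The blockwise [vb_e_step()] and
#' [vb_m_step()] operations are exported for stepwise use and diagnostics.
#'
#' @param counts a [read_count_matrix()].
#' @param config a [fit_config()].
#' @return A `model_estimate` with elements `params`, `vparams`,
#'   `elbo_trace`, `converged`, `nraf`, plus the coordinates of the input.
#' @export
vb_fit <- function(counts, config = fit_config()) {
  if (!inherits(counts, "read_count_matrix")) {
    stop_input("counts must be a read_count_matrix")
  }
  if (!inherits(config, "fit_config")) stop_input("config must be a fit_config")
  state <- vb_initialize(counts)
  params <- state$params
  params$M <- pmin(pmax(params$M, config$bounds$M[1]), config$bounds$M[2])
  prior <- robust_prior_estimate(counts, config$bounds)
  params$mu0 <- prior$mu0
  params$M0 <- if (is.null(config$fix_M0)) prior$M0 else config$fix_M0
  vparams <- state$vparams
  trace <- numeric(0)
  converged <- FALSE
  prev <- NA_real_
  for (it in seq_len(config$max_iterations)) {
    ref <- refine_joint(counts, vparams, params, config)
    vparams <- ref$vparams
    params <- ref$params
    acc <- ridge_accelerate(counts, vparams, params, config)
    vparams <- acc$vparams
    params <- acc$params
    cur <- acc$elbo
    trace <- c(trace, cur)
    if (it > 1 && abs(cur - prev) <= config$elbo_rel_tol * (abs(prev) + 1e-8)) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  model_estimate(params, vparams, trace, converged,
                 chrom = counts$chrom, positions = counts$positions,
                 ref = counts$ref)
}
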