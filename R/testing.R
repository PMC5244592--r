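# Case/control posterior-difference testing and variant calling.

#' Test configuration
#'
#' @param alpha size of the posterior-difference test, in (0,1). A
#'   position is provisional when the posterior probability reaches
#'   `1 - alpha/2`.
#' @param tau effect-size threshold on the NRAF difference (>= 0).
#' @param sided `"one"` (default, `Pr(diff >= tau)`) or `"two"`
#'   (`Pr(|diff| >= tau)`). A two-sided test with `tau = 0` is degenerate
#'   (the probability is identically 1) and is rejected.
#' @param chi2_alpha size of the chi-squared promotion test.
#' @return Object of class `test_config`.
#' @export
test_config <- function(alpha = 0.05, tau = 0, sided = c("one", "two"),
                        chi2_alpha = 0.05) {
  sided <- match.arg(sided)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_input("alpha must lie in (0,1)")
  }
  if (!is.finite(tau) || tau < 0) stop_input("tau must be >= 0")
  if (sided == "two" && tau == 0) {
    stop_input("a two-sided test requires tau > 0 (Pr(|diff| >= 0) is identically 1)")
  }
  if (!is.finite(chi2_alpha) || chi2_alpha <= 0 || chi2_alpha >= 1) {
    stop_input("chi2_alpha must lie in (0,1)")
  }
  structure(list(alpha = alpha, tau = tau, sided = sided,
                 chi2_alpha = chi2_alpha),
            class = "test_config")
}

#' Gaussian moment matching of Beta posteriors
#'
#' Returns the exact mean and variance of Beta(gamma1, gamma2), used to
#' approximate each variational NRAF posterior by a Gaussian so that the
#' case-control difference has a tractable (Gaussian) distribution.
#'
#' @param gamma a length-2 shape pair, or a J x 2 matrix of shape pairs.
#' @return data.frame with columns `mean` and `variance`.
#' @export
gaussian_moments <- function(gamma) {
  if (is.null(dim(gamma))) gamma <- matrix(gamma, ncol = 2)
  g1 <- gamma[, 1]; g2 <- gamma[, 2]
  if (any(!is.finite(g1)) || any(!is.finite(g2)) || any(g1 <= 0) || any(g2 <= 0)) {
    stop_input("Beta shapes must be positive")
  }
  g0 <- g1 + g2
  data.frame(mean = g1 / g0, variance = g1 * g2 / ((g0 + 1) * g0^2))
}

#' Posterior probability of a case-control NRAF difference
#'
#' Under the Gaussian moment-matched approximation the difference
#' `diff = mu_case - mu_control` is Normal with mean equal to the
#' difference of means and variance equal to the sum of variances. The
#' one-sided probability is `Pr(diff >= tau)`; the two-sided probability
#' is `Pr(|diff| >= tau)`.
#'
#' @param case,control data.frames with columns `mean`, `variance`
#'   (see [gaussian_moments()]); vectorized over rows.
#' @param tau effect-size threshold.
#' @param sided `"one"` or `"two"`.
#' @return Probabilities in `[0,1]`.
#' @export
posterior_difference_prob <- function(case, control, tau = 0,
                                      sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (any(case$variance <= 0) || any(control$variance <= 0)) {
    stop_input("posterior variances must be positive")
  }
  m <- case$mean - control$mean
  s <- sqrt(case$variance + control$variance)
  if (sided == "one") {
    stats::pnorm((m - tau) / s)
  } else {
    stats::pnorm((m - tau) / s) + stats::pnorm((-tau - m) / s)
  }
}

#' Chi-squared test for non-uniform non-reference base distribution
#'
#' Pearson goodness-of-fit test of the three non-reference base counts
#' against the uniform expectation (total/3 each, 2 degrees of freedom).
#' A position whose non-reference reads are spread evenly across all
#' three alternative bases looks like indiscriminate sequencing error, so
#' only positions that reject uniformity are promoted to called variants.
#'
#' @param counts three non-negative integers.
#' @return Upper-tail p-value.
#' @export
chi2_nonuniform_test <- function(counts) {
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0)) {
    stop_input("counts must be three non-negative numbers")
  }
  if (sum(counts) == 0) {
    stop_undefined_test("all three non-reference base counts are zero; the uniformity test is undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, p = rep(1, 3) / 3))
  unname(ct$p.value)
}

#' Call variants between a case and a control sample
#'
#' For each position the case and control variational NRAF posteriors are
#' moment-matched to Gaussians and the posterior probability of an NRAF
#' difference exceeding `tau` is computed. A position is *provisional*
#' when that probability reaches `1 - alpha/2`; a provisional position is
#' *called* when the case sample's pooled non-reference base counts reject
#' uniformity in the chi-squared test at `chi2_alpha`. No multiple-testing
#' correction is applied.
#'
#' @param case_est,control_est `model_estimate` objects fitted on the
#'   case and control samples over the same positions.
#' @param case_counts the case [read_count_matrix()] (supplies the
#'   per-base counts for the chi-squared promotion test).
#' @param config a [test_config()].
#' @return data.frame with one row per position: `position`, `ref`,
#'   `nraf_case`, `nraf_control`, `diff_prob`, `chi2_p` (NA unless
#'   provisional), `provisional`, `called`.
#' @export
call_variants <- function(case_est, control_est, case_counts,
                          config = test_config()) {
  if (!inherits(case_est, "model_estimate") ||
      !inherits(control_est, "model_estimate")) {
    stop_input("case_est and control_est must be model_estimate objects")
  }
  if (!identical(case_est$positions, control_est$positions)) {
    stop_input("case and control estimates cover different position sets")
  }
  if (!identical(case_counts$positions, case_est$positions)) {
    stop_input("case_counts positions do not match the case estimate")
  }
  case_m <- gaussian_moments(case_est$vparams$gamma)
  ctrl_m <- gaussian_moments(control_est$vparams$gamma)
  diff_prob <- posterior_difference_prob(case_m, ctrl_m, config$tau,
                                         config$sided)
  provisional <- diff_prob >= 1 - config$alpha / 2

  J <- length(diff_prob)
  chi2_p <- rep(NA_real_, J)
  called <- rep(FALSE, J)
  ref_idx <- match(case_counts$ref, BASES)
  pooled <- apply(case_counts$base_counts, c(1, 3), sum)
  low_count <- 0L
  for (j in which(provisional)) {
    nonref <- pooled[j, -ref_idx[j]]
    if (sum(nonref) == 0) next  # cannot be promoted
    if (sum(nonref) < 6) low_count <- low_count + 1L
    chi2_p[j] <- chi2_nonuniform_test(nonref)
    called[j] <- chi2_p[j] < config$chi2_alpha
  }
  if (low_count > 0) {
    warn_vbsnv("chi-squared promotion test ran with fewer than 6 pooled non-reference reads at %d position(s)",
               low_count)
  }
  data.frame(position = case_est$positions,
             ref = case_counts$ref,
             nraf_case = case_est$nraf,
             nraf_control = control_est$nraf,
             diff_prob = diff_prob,
             chi2_p = chi2_p,
             provisional = provisional,
             called = called)
}

#' Sensitivity/specificity across a grid of test sizes
#'
#' Re-runs [call_variants()] for each `alpha` and scores the calls against
#' a known truth set, tracing out the operating characteristic of the
#' posterior-difference test.
#'
#' @inheritParams call_variants
#' @param truth integer vector of true variant positions.
#' @param alphas test sizes to scan.
#' @return data.frame with columns `alpha`, `sensitivity`, `specificity`.
#' @export
scan_alpha <- function(case_est, control_est, case_counts, truth, alphas,
                       config = test_config()) {
  if (length(alphas) == 0) stop_input("alphas must be non-empty")
  res <- lapply(alphas, function(a) {
    cfg <- test_config(alpha = a, tau = config$tau, sided = config$sided,
                       chi2_alpha = config$chi2_alpha)
    calls <- suppressWarnings(call_variants(case_est, control_est,
                                            case_counts, cfg))
    sc <- score_calls(calls, truth, nrow(calls))
    data.frame(alpha = a, sensitivity = sc[["sensitivity"]],
               specificity = sc[["specificity"]])
  })
  do.call(rbind, res)
}
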