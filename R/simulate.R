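# Generative-process simulator and the in-vitro mixture benchmark emulator.

#' Simulate read counts from the hierarchical Beta-Binomial model
#'
#' Draws `mu_j ~ Beta(mu0, M0)` (mean-precision form), `theta_ji ~
#' Beta(mu_j, M_j)` and `r_ji ~ Binomial(n_ji, theta_ji)`, returning the
#' counts together with the latent draws for parameter-recovery tests.
#' Non-reference reads are split uniformly at random across the three
#' non-reference bases (indiscriminate sequencing-noise default) unless a
#' designated `variant_base` should absorb them.
#'
#' @param params a [model_params()].
#' @param depths J x N matrix (or vector recycled per replicate) of total
#'   read depths.
#' @param seed integer seed; the output is deterministic given the seed.
#' @param chrom,positions,ref coordinates for the output matrix.
#' @param variant_base optional length-J character vector; where not NA,
#'   all non-reference reads at that position are assigned to this base
#'   instead of being spread uniformly.
#' @return list with elements `counts` (a [read_count_matrix()]), `mu`
#'   (length J) and `theta` (J x N).
#' @export
simulate_from_model <- function(params, depths, seed = NULL,
                                chrom = "sim", positions = NULL,
                                ref = NULL, variant_base = NULL) {
  stopifnot(inherits(params, "model_params"))
  J <- length(params$M)
  if (is.null(dim(depths))) depths <- matrix(depths, J, length(depths) / J)
  if (nrow(depths) != J) stop_input("depths must have one row per position")
  if (any(depths < 0) || any(depths != round(depths))) {
    stop_input("depths must be non-negative integers")
  }
  N <- ncol(depths)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- seq_len(J)
  if (is.null(ref)) ref <- rep("A", J)

  a0 <- params$mu0 * params$M0
  b0 <- (1 - params$mu0) * params$M0
  mu <- pmin(pmax(stats::rbeta(J, a0, b0), 1e-12), 1 - 1e-12)
  theta <- matrix(pmin(pmax(stats::rbeta(J * N, mu * params$M,
                                         (1 - mu) * params$M),
                            1e-12), 1 - 1e-12), J, N)
  n <- matrix(as.integer(depths), J, N)
  r <- matrix(stats::rbinom(J * N, n, theta), J, N)

  counts <- build_base_counts(r, n, ref, variant_base)
  list(counts = read_count_matrix(counts, positions, ref, chrom),
       mu = mu, theta = theta)
}

# Distribute non-reference reads over the three non-reference bases:
# uniformly at random, or all onto the designated variant base.
build_base_counts <- function(r, n, ref, variant_base = NULL) {
  J <- nrow(r); N <- ncol(r)
  bc <- array(0L, dim = c(J, N, 4), dimnames = list(NULL, NULL, BASES))
  ref_idx <- match(ref, BASES)
  for (j in seq_len(J)) {
    alt <- setdiff(seq_len(4L), ref_idx[j])
    bc[j, , ref_idx[j]] <- n[j, ] - r[j, ]
    if (!is.null(variant_base) && !is.na(variant_base[j])) {
      bc[j, , match(variant_base[j], BASES)] <- r[j, ]
    } else {
      for (i in seq_len(N)) {
        if (r[j, i] > 0) {
          split <- stats::rmultinom(1, r[j, i], rep(1, 3) / 3)
          bc[j, i, alt] <- bc[j, i, alt] + as.integer(split)
        }
      }
    }
  }
  bc
}

#' Simulate the in-vitro case/control mixture benchmark
#'
#' Emulates a two-sample benchmark in which a variant-bearing sequence is
#' mixed into a wild-type background at a defined non-reference allele
#' fraction: `J` positions, `n_variants` variant loci, `N` replicates per
#' sample. The control is drawn from the sequencing-error model alone; the
#' case is identical except at the variant loci, where each read
#' originates from the variant clone with probability `nraf` (carrying
#' the designated variant base) and otherwise from the background error
#' process, so the latent non-reference rate is
#' `nraf + (1 - nraf) * theta_err`. Per-cell depths are log-normally
#' jittered around `median_depth` (sd 0.25 in log10 units).
#'
#' @param nraf true non-reference allele fraction at variant loci, in (0,1].
#' @param median_depth target median read depth (>= 1).
#' @param seed integer seed.
#' @param J,n_variants,N design dimensions.
#' @param error_mu0,error_M0,M_j background error-model parameters.
#' @param variant_positions optional integer vector of variant loci
#'   (defaults to a seed-determined random draw).
#' @return list with elements `case`, `control` (read_count_matrix) and
#'   `truth` (sorted variant positions).
#' @export
simulate_mixture_experiment <- function(nraf, median_depth, seed = NULL,
                                        J = 400, n_variants = 14, N = 6,
                                        error_mu0 = 0.005, error_M0 = 100,
                                        M_j = 1e4,
                                        variant_positions = NULL) {
  if (!is.finite(nraf) || nraf <= 0 || nraf > 1) {
    stop_input("nraf must lie in (0, 1]")
  }
  if (median_depth < 1) stop_input("median_depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  ref <- sample(BASES, J, replace = TRUE)
  if (is.null(variant_positions)) {
    variant_positions <- sort(sample.int(J, n_variants))
  }
  variant_positions <- sort(as.integer(variant_positions))
  # designated variant base: the next base (cyclically) after the reference
  variant_base <- rep(NA_character_, J)
  variant_base[variant_positions] <-
    BASES[match(ref[variant_positions], BASES) %% 4L + 1L]

  draw_depths <- function() {
    matrix(pmax(1L, as.integer(round(
      median_depth * 10^stats::rnorm(J * N, 0, 0.25)))), J, N)
  }
  # One per-position error field shared by both samples: the case and
  # control libraries come from the same sequences on the same platform,
  # so under the null a position's error rate is common to both samples
  # and only replicate-level noise differs.
  mu_err <- pmin(pmax(stats::rbeta(J, error_mu0 * error_M0,
                                   (1 - error_mu0) * error_M0),
                      1e-12), 1 - 1e-12)
  draw_error_theta <- function() {
    matrix(pmin(pmax(stats::rbeta(J * N, mu_err * M_j, (1 - mu_err) * M_j),
                     1e-12), 1 - 1e-12), J, N)
  }

  n_ctrl <- draw_depths()
  theta_ctrl <- draw_error_theta()
  r_ctrl <- matrix(stats::rbinom(J * N, n_ctrl, theta_ctrl), J, N)
  bc_ctrl <- build_base_counts(r_ctrl, n_ctrl, ref)

  n_case <- draw_depths()
  theta_case <- draw_error_theta()
  # variant-clone reads at variant loci, error reads everywhere
  v <- matrix(0L, J, N)
  v[variant_positions, ] <- stats::rbinom(length(variant_positions) * N,
                                          n_case[variant_positions, ], nraf)
  e <- matrix(stats::rbinom(J * N, n_case - v, theta_case), J, N)
  bc_case <- build_base_counts(e, n_case - v, ref)
  for (j in variant_positions) {
    vb <- match(variant_base[j], BASES)
    bc_case[j, , vb] <- bc_case[j, , vb] + v[j, ]
  }

  list(case = read_count_matrix(bc_case, seq_len(J), ref, "mixture"),
       control = read_count_matrix(bc_ctrl, seq_len(J), ref, "mixture"),
       truth = variant_positions)
}

#' Score variant calls against a known truth set
#'
#' @param calls a data.frame from [call_variants()] (its `called` column
#'   is used) or an integer vector of called positions.
#' @param truth integer vector of true variant positions.
#' @param J total number of positions scored.
#' @return named vector with `sensitivity` and `specificity`.
#' @export
score_calls <- function(calls, truth, J) {
  if (length(truth) == 0) {
    stop_input("truth set is empty; sensitivity is undefined")
  }
  if (is.data.frame(calls)) {
    called <- calls$position[calls$called]
  } else {
    called <- calls
  }
  tp <- sum(called %in% truth)
  fp <- sum(!(called %in% truth))
  c(sensitivity = tp / length(truth),
    specificity = 1 - fp / (J - length(truth)))
}
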