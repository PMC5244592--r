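---
title: "Rare variant calling with a hierarchical Beta-Binomial model and variational EM"
author: "vbsnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare variant calling with a hierarchical Beta-Binomial model and variational EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep sequencing of a heterogeneous cell population can reveal single
nucleotide variants carried by a small fraction of the population — down
to one cell in a thousand — but at those frequencies the variant signal
is comparable to the sequencing error rate (typically a few reads per
thousand). Telling a rare variant apart from a recurrent sequencing
error requires a statistical model of the error process itself, and in
particular of how the error rate varies from position to position and
from library replicate to library replicate.

`vbsnv` estimates, for every genomic position $j$, the non-reference
allele frequency (NRAF): the fraction of reads carrying a base different
from the reference. Variants are called by comparing a *case* sample
against a *control* sample sequenced on the same platform: a position is
a variant when its NRAF in the case credibly exceeds its NRAF in the
control, and the non-reference reads are concentrated on one alternative
base rather than spread indiscriminately over all three.

## The model

The observed data for one sample are $r_{ji}$, the number of
non-reference reads at position $j \in 1..J$ in replicate $i \in 1..N$,
out of $n_{ji}$ total reads. The generative process is hierarchical:

* $\mu_j \sim \mathrm{Beta}(\mu_0, M_0)$ — a position-specific
  non-reference read rate, drawn around a global error rate $\mu_0$ with
  global precision $M_0$ (Beta distributions are parameterized here by
  mean and precision; the shapes are $(\mu M, (1-\mu) M)$);
* $\theta_{ji} \sim \mathrm{Beta}(\mu_j, M_j)$ — the realized rate in
  replicate $i$, jittered around $\mu_j$ with local precision $M_j$;
* $r_{ji} \mid n_{ji} \sim \mathrm{Binomial}(n_{ji}, \theta_{ji})$.

$\mu_j$ is the scientific quantity: the position's NRAF, separated from
both binomial counting noise and replicate-level technical variation.

## Variational inference

The posterior $p(\mu, \theta \mid r, n)$ is intractable, and the
$\mu$-level is non-conjugate. The package fits a factorized variational
approximation $q(\mu,\theta) = \prod_j q(\mu_j) \prod_i q(\theta_{ji})$
with $q(\mu_j) = \mathrm{Beta}(\gamma_{j1}, \gamma_{j2})$ and
$q(\theta_{ji}) = \mathrm{Beta}(\delta_{ji1}, \delta_{ji2})$, by
maximizing the evidence lower bound (ELBO)
$\mathcal{L}(q,\phi) = E_q[\log p(r,\mu,\theta|n;\phi)] - E_q[\log q]$,
which never exceeds the log evidence. The only non-analytic ingredient
is the expected log Beta normalizer
$E_q[\log(\Gamma(M_j)/(\Gamma(\mu_j M_j)\Gamma((1-\mu_j)M_j)))]$, which
must be integrated numerically (`expected_log_beta_norm()`).

### Numerical integration

Naive fixed-order Gauss–Legendre quadrature on $(0,1)$ fails here twice:
the integrand has logarithmic endpoint singularities (error about
$5\times10^{-4}$ at order 50), and $q(\mu_j)$ can concentrate on a
region much narrower than any node spacing. Both problems are removed
exactly rather than approximately:

* **Singularity extraction.** Using
  $\log\Gamma(x) = \log\Gamma(1+x) - \log x$, the singular parts reduce
  to $E_q[\log \mu_j]$ and $E_q[\log(1-\mu_j)]$, which are exact digamma
  identities. Only the entire (analytic) function
  $\log\Gamma(1 + \mu M) + \log\Gamma(1 + (1-\mu)M)$ is integrated
  numerically.
* **CDF transform.** The remaining integral is taken in the variable
  $u$ with $\mu = F^{-1}(u)$ (the Beta quantile function), so the nodes
  always sit inside the mass of $q$ no matter how concentrated it is.
  The exported `expected_log_beta_norm()` additionally uses a symmetric
  graded mesh in $u$, because the quantile map has endpoint-derivative
  singularities of the form $u^{1/\gamma}$ for large shapes. This
  reproduces the closed forms $-\log 2\pi$ (for
  $q = \mathrm{Beta}(1,1)$, $M=1$) and $1 - \log 2\pi$ ($M=2$), which
  follow from Raabe's integral of $\log\Gamma$, to near machine
  precision, and stays accurate (about $10^{-6}$) across six orders of
  magnitude of shape parameters.

Inside the optimizer a third scheme is used for speed: Gauss–Hermite
quadrature in logit space, with the proposal matched to the *exact*
logit moments of the current Beta (mean $\psi(\gamma_1)-\psi(\gamma_2)$,
variance $\psi'(\gamma_1)+\psi'(\gamma_2)$). It is essentially exact
when both shapes exceed about 2 and a smoothly biased surrogate below
that; correctness never depends on it because every optimizer move is
accepted only if the exact objective improves (see below).

### The fitting schedule

`vb_fit()` is a monotone generalized EM. The textbook schedule —
optimize $\delta$, then $\gamma$, then $(\mu_0, M_0, M_j)$, strictly in
turn — is available through `vb_e_step()`/`vb_m_step()` and satisfies
all the blockwise contracts, but as the main loop it crawls: $\delta$
and $\gamma$ are strongly coupled (the conjugate maximizer of
$q(\theta)$ given $E_q[\mu]$ is closed form,
$\delta = (r + M E_q[\mu],\; n - r + M(1-E_q[\mu]))$, and moves whenever
$\gamma$ moves), and $(\gamma_j, M_j)$ sit on a nearly flat ridge.
`vb_fit()` therefore:

1. profiles $q(\theta)$ out of each position's objective analytically
   (every evaluation at $(\gamma_j, M_j)$ implicitly carries its own
   optimal $\delta$ — ascent on the profiled objective is ascent on the
   full ELBO);
2. updates $(\gamma_{j1}, \gamma_{j2}, M_j)$ jointly with a batched
   damped-Newton ascent (compiled; finite-difference derivatives in
   log-shape space with backtracking line search);
3. runs a global line search over a joint rescaling of all $\gamma$
   precisions, the one remaining slow direction.

Every sub-step keeps a position's previous values unless its exact
block objective improves, so the recorded ELBO trace is non-decreasing
by construction (up to quadrature tolerance), and the whole fit is
deterministic — identical inputs give bit-identical estimates.

### Global error parameters are estimated robustly, then fixed

Point-maximizing the ELBO over $(\mu_0, M_0)$ is statistically fragile
in both directions. On a case sample, a handful of true variant
positions are extreme outliers under any Beta prior, and the
maximum-likelihood fit reacts by driving $M_0$ toward zero — abolishing
shrinkage for every position. On a pure error sample at low depth, the
data cannot resolve position-to-position heterogeneity and the
likelihood prefers $M_0 \to \infty$ — collapsing all positions onto
$\mu_0$. Either way the case and control fits end up shrunk by
*different* amounts, and the shared per-position error heterogeneity no
longer cancels in the case–control difference, inflating the false
positive rate.

`vb_fit()` instead estimates $(\mu_0, M_0)$ once, robustly, before the
EM loop: $\mu_0$ is the mean of the pooled per-position non-reference
rates after trimming the top 5% (which removes variant-like positions),
and $M_0$ is the method-of-moments precision of the same trimmed bulk
with the binomial sampling contribution subtracted, clipped to
$[10, 10^3]$. Both samples then receive the same, outlier-resistant
shrinkage. This mirrors robust empirical-Bayes hyperparameter
estimation as practiced in, for example, `limma::eBayes(robust = TRUE)`,
and is supported by the model's own sensitivity analysis: the NRAF
estimates change very little as $M_0$ varies over orders of magnitude.
`fit_config(fix_M0 = )` pins $M_0$ at any user-chosen value instead.

### Parameter bounds

The optimizer works in a box: $\mu_0 \in [10^{-6}, 1-10^{-6}]$,
$M_0 \in [10^{-3}, 10^{3}]$, $M_j \in [10^{2}, 10^{8}]$, Beta shapes in
$[10^{-3}, 10^{10}]$. The two informative bounds deserve comment.

* **Lower bound on $M_j$ (100).** With $M_j$ free, the ELBO's global
  optimum at low depth is a degenerate "all-or-nothing" configuration:
  $M_j \to 0$ makes $\mathrm{Beta}(\mu_j, M_j)$ a two-point mixture at
  $\{0, 1\}$, replicate-level overdispersion absorbs all position
  signal, and the $\mu$ level decouples from the data entirely (mean
  NRAF error roughly 0.03 instead of 0.004 in simulation). A floor of
  100 encodes that technical replicates share a position's error rate
  to within a few percent absolute
  ($\mathrm{sd}(\theta) \le \sqrt{1/(4 \cdot 101)} \approx 5\%$ at
  worst), which closes the degenerate channel while leaving realistic
  fits ($M_j \sim 10^3$–$10^5$) untouched. The cost is that genuine
  extreme replicate artifacts (jackpot effects) cannot be modeled at
  the $\theta$ level; the chi-squared filter below is the backstop.
* **Upper bound on $M_0$ (1000).** $M_0 = 10^3$ at $\mu_0 = 0.005$
  corresponds to a position-to-position error-rate standard deviation
  of $2\times10^{-3}$, i.e. a coefficient of variation of about 45%.
  Context-dependent NGS error rates vary at least this much on every
  platform, so larger precisions are not scientifically meaningful, and
  allowing them lets homogeneous-looking samples collapse (see above).

## Hypothesis testing

Each sample's variational NRAF posterior $q(\mu_j)$ is approximated by
a Gaussian via exact moment matching
(mean $\gamma_1/(\gamma_1+\gamma_2)$, variance
$\gamma_1\gamma_2 / ((\gamma_1+\gamma_2+1)(\gamma_1+\gamma_2)^2)$), so
the case–control difference is Gaussian with the difference of means
and the sum of variances. The test statistic is the posterior
probability $\Pr(\mu_j^{case} - \mu_j^{control} \ge \tau)$ (one-sided,
default $\tau = 0$) or $\Pr(|\Delta| \ge \tau)$ (two-sided, which
requires $\tau > 0$ — at $\tau = 0$ it is identically 1 and the
configuration is rejected rather than silently calling everything). A
position is *provisional* when this probability reaches
$1 - \alpha/2$ (default $\alpha = 0.05$); no multiple-testing
correction is applied, matching per-position thresholding practice.

A provisional position whose non-reference reads are spread evenly over
all three alternative bases looks like indiscriminate sequencing error,
not a variant. The case sample's non-reference base counts, pooled
across replicates, are therefore tested against the uniform expectation
with a Pearson chi-squared test (2 degrees of freedom, default level
0.05); only positions that reject uniformity are promoted to *called*
variants. Pooling maximizes power; when fewer than 6 pooled
non-reference reads are available the asymptotic p-value is used as-is
with a warning. The case sample's counts feed the test because the
variant signal resides there.

## The simulator

`simulate_mixture_experiment()` emulates an in-vitro benchmark in which
a variant-bearing 400 bp sequence with 14 variant loci is mixed into a
wild-type background at a defined NRAF, each sample sequenced in six
replicates. Design choices:

* **Error model defaults** ($\mu_0 = 0.005$, $M_0 = 100$,
  $M_j = 10^4$): a 0.5% mean error rate with order-one relative
  variation across positions and small replicate-level jitter —
  realistic NGS error levels, consistent with 0.1% NRAF variants being
  detectable only at tens of thousands of reads of depth.
* **A single error field shared by case and control.** Both libraries
  come from the same construct on the same platform, so under the null
  a position's error rate is common to the two samples; only
  replicate-level rates and depths are redrawn. This is what makes the
  case–control design informative at all: each sample's fit cancels
  the other's position effects.
* **Variant injection at the rate level:** at a variant locus each read
  originates from the variant clone with probability equal to the NRAF
  (carrying the designated variant base) and otherwise from the error
  process, so the latent non-reference rate is
  $\mathrm{NRAF} + (1-\mathrm{NRAF})\,\theta_{err}$ and the simulated
  data stay inside the model family.
* **Depths** are log-normally jittered around the target median
  (sd 0.25 in $\log_{10}$), giving realized medians close to the
  target.

What the simulator does *not* emulate: alignment artifacts, strand
bias, context-dependent (non-uniform) error-base preferences, and the
specific error heterogeneity of any real platform. Passing the
benchmark tests therefore certifies the statistical machinery under the
model's own assumptions — it does not certify performance on any
particular instrument's data.

## Verification scale and observed behavior

The test suite checks, among other things: the two Raabe closed forms
to $10^{-6}$; the ELBO against a nested-quadrature log evidence on
random single-position instances (the bound holds to $-10^{-6}$);
variational posterior means against exact quadrature posteriors (within
0.05); ELBO monotonicity on every fit; recovery of $\mu_0$ (within a
factor of 2) and of position NRAFs (mean absolute error well under
0.002) on generative draws at $J=100$, $N=6$, $10^4\times$ depth; null
calibration of the provisional rate on 10 error-only case/control pairs
at $J=400$; and median sensitivity/specificity over five simulation
seeds at six benchmark operating points spanning NRAF 0.1%–100% and
depths 27–2718 times. The operating points chosen are those whose
published values are determined by the method rather than by
platform-specific error behavior: conditions where the variant is
either far below or far above the error floor. Published intermediate
operating points (sensitivities like 0.29 or specificities like 0.98 at
borderline depth) depend on the real instrument's unpublished error
profile and are not meaningful targets for a distributional stand-in.
Typical observed values: sensitivity 0.00 at 0.1%/39x (the expected
variant signal is 0.04 reads per replicate), 1.00 at 10%/260x and
100%/27x, with specificity 0.995–1.000 throughout.

These problem sizes complete in a few minutes on a single core; the
per-condition fits are a few seconds each at quadrature order 50.

## Known limitations

* $M_j$ below 100 cannot be represented, so strong per-position
  replicate inconsistency is attributed to the binomial level.
* The global parameters are trimmed-moment estimates, not ELBO maxima;
  `vb_m_step()` provides the maximum-likelihood update for users who
  want it.
* The Gaussian moment-matched test is asymmetric in information terms
  when case and control depths differ grossly; the variational
  variances do not account for uncertainty in $\phi$.
* Indels, multi-allelic calls and strand-aware filtering are out of
  scope; the pileup reader skips indels entirely.
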