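// Batched damped-Newton ascent of the per-position profiled ELBO block.
//
// Each position j contributes an independent block objective in
// (log gamma_j1, log gamma_j2[, log M_j]) with q(theta) profiled at its
// conjugate optimum; the smooth part of the expected log Beta normalizer
// is integrated by moment-matched Gauss-Hermite in logit space. This
// mirrors the R reference implementation in fit.R; it exists because the
// optimizer is called once per EM iteration over hundreds of positions.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double beta_entropy1(double a, double b) {
  return R::lbeta(a, b) - (a - 1.0) * R::digamma(a) -
         (b - 1.0) * R::digamma(b) + (a + b - 2.0) * R::digamma(a + b);
}

namespace {

struct BlockObjective {
  const NumericMatrix& r;
  const NumericMatrix& n;
  const NumericVector& Mfix;
  bool joint;
  double mu0, M0;
  const NumericVector& tk;
  const NumericVector& lwk;
  double shlo, shhi;

  double eval(int j, const double* x) const {
    const double g1 = std::exp(x[0]);
    const double g2 = std::exp(x[1]);
    const double M = joint ? std::exp(x[2]) : Mfix[j];
    const double g0 = g1 + g2;
    const double emu = g1 / g0;
    const int N = r.ncol();
    const int K = tk.size();

    // delta profiled at the conjugate optimum
    double T1 = 0.0, T2 = 0.0, binom = 0.0, Hd = 0.0;
    for (int i = 0; i < N; ++i) {
      const double rr = r(j, i), nn = n(j, i);
      double d1 = rr + M * emu;
      double d2 = nn - rr + M * (1.0 - emu);
      d1 = std::min(std::max(d1, shlo), shhi);
      d2 = std::min(std::max(d2, shlo), shhi);
      const double p1 = R::digamma(d1);
      const double p2 = R::digamma(d2);
      const double p0 = R::digamma(d1 + d2);
      const double el = p1 - p0, e1m = p2 - p0;
      T1 += el - e1m;
      T2 += e1m;
      binom += rr * el + (nn - rr) * e1m;
      Hd += R::lbeta(d1, d2) - (d1 - 1.0) * p1 - (d2 - 1.0) * p2 +
            (d1 + d2 - 2.0) * p0;
    }

    // Gauss-Hermite in logit space, proposal matched to the exact logit
    // moments of Beta(g1, g2)
    const double mz = R::digamma(g1) - R::digamma(g2);
    const double vz = R::trigamma(g1) + R::trigamma(g2);
    const double sz = std::sqrt(2.0 * vz);
    const double lb = R::lbeta(g1, g2);
    double quad = 0.0;
    for (int k = 0; k < K; ++k) {
      const double z = mz + sz * tk[k];
      double lmu, l1m;
      if (z >= 0.0) {
        const double t = std::log1p(std::exp(-z));
        lmu = -t;
        l1m = -z - t;
      } else {
        const double t = std::log1p(std::exp(z));
        lmu = z - t;
        l1m = -t;
      }
      const double logp = g1 * lmu + g2 * l1m - lb;
      const double mu = std::exp(lmu);
      const double s = R::lgammafn(1.0 + mu * M) +
                       R::lgammafn(1.0 + (1.0 - mu) * M);
      quad += std::exp(lwk[k] + logp) * s;
    }
    quad *= sz;

    const double p0g = R::digamma(g0);
    const double elog = R::digamma(g1) - p0g;
    const double elog1m = R::digamma(g2) - p0g;
    const double Q = R::lgammafn(M) + 2.0 * std::log(M) + elog + elog1m -
                     quad;
    const double val = binom + N * Q + M * (emu * T1 + T2) - T1 - 2.0 * T2 +
                       (mu0 * M0 - 1.0) * elog +
                       ((1.0 - mu0) * M0 - 1.0) * elog1m +
                       beta_entropy1(g1, g2) + Hd;
    return std::isfinite(val) ? val : -INFINITY;
  }
};

inline void clipv(double* x, const double* lo, const double* hi, int p) {
  for (int k = 0; k < p; ++k) x[k] = std::min(std::max(x[k], lo[k]), hi[k]);
}

}  // namespace

// [[Rcpp::export(name = ".profiled_newton_cpp")]]
NumericMatrix profiled_newton_cpp(NumericMatrix x0, NumericMatrix r,
                                  NumericMatrix n, NumericVector Mfix,
                                  bool joint, double mu0, double M0,
                                  NumericVector tk, NumericVector lwk,
                                  double shlo, double shhi,
                                  NumericVector lower, NumericVector upper,
                                  int max_iter, double h, double step_cap) {
  const int J = x0.nrow();
  const int p = x0.ncol();
  BlockObjective obj{r, n, Mfix, joint, mu0, M0, tk, lwk, shlo, shhi};
  NumericMatrix out(clone(x0));
  const double* lo = lower.begin();
  const double* hi = upper.begin();
  const double tvals[4] = {1.0, 0.5, 0.1, 0.01};

  for (int j = 0; j < J; ++j) {
    double x[3], xc[3], xbest[3];
    for (int k = 0; k < p; ++k) x[k] = out(j, k);
    clipv(x, lo, hi, p);
    double f0 = obj.eval(j, x);

    for (int iter = 0; iter < max_iter; ++iter) {
      double fp[3], fm[3], gr[3], H[3][3], d[3];
      for (int k = 0; k < p; ++k) {
        std::copy(x, x + p, xc); xc[k] += h;
        fp[k] = obj.eval(j, xc);
        std::copy(x, x + p, xc); xc[k] -= h;
        fm[k] = obj.eval(j, xc);
        gr[k] = (fp[k] - fm[k]) / (2.0 * h);
        H[k][k] = (fp[k] - 2.0 * f0 + fm[k]) / (h * h);
      }
      for (int a = 0; a < p - 1; ++a) {
        for (int b = a + 1; b < p; ++b) {
          std::copy(x, x + p, xc); xc[a] += h; xc[b] += h;
          const double fab = obj.eval(j, xc);
          H[a][b] = H[b][a] = (fab - fp[a] - fp[b] + f0) / (h * h);
        }
      }
      // Newton direction if the Hessian is negative definite, otherwise
      // a normalized gradient step
      bool nd = false;
      if (p == 1) {
        nd = std::isfinite(H[0][0]) && H[0][0] < 0.0;
        if (nd) d[0] = -gr[0] / H[0][0];
      } else if (p == 2) {
        const double det = H[0][0] * H[1][1] - H[0][1] * H[0][1];
        nd = std::isfinite(det) && det > 0.0 && H[0][0] < 0.0;
        if (nd) {
          d[0] = -(H[1][1] * gr[0] - H[0][1] * gr[1]) / det;
          d[1] = -(-H[0][1] * gr[0] + H[0][0] * gr[1]) / det;
        }
      } else {
        const double a = H[0][0], b = H[0][1], c = H[0][2];
        const double e = H[1][1], f = H[1][2], g = H[2][2];
        const double det2 = a * e - b * b;
        const double det3 = a * (e * g - f * f) - b * (b * g - c * f) +
                            c * (b * f - c * e);
        nd = std::isfinite(det3) && a < 0.0 && det2 > 0.0 && det3 < 0.0;
        if (nd) {
          const double A11 = e * g - f * f, A12 = c * f - b * g,
                       A13 = b * f - c * e, A22 = a * g - c * c,
                       A23 = b * c - a * f, A33 = a * e - b * b;
          d[0] = -(A11 * gr[0] + A12 * gr[1] + A13 * gr[2]) / det3;
          d[1] = -(A12 * gr[0] + A22 * gr[1] + A23 * gr[2]) / det3;
          d[2] = -(A13 * gr[0] + A23 * gr[1] + A33 * gr[2]) / det3;
        }
      }
      if (!nd) {
        double gn = 0.0;
        for (int k = 0; k < p; ++k) gn += gr[k] * gr[k];
        gn = std::sqrt(gn);
        if (!(gn > 1e-12)) break;
        for (int k = 0; k < p; ++k) d[k] = gr[k] / gn;
      }
      double dn = 0.0;
      for (int k = 0; k < p; ++k) dn += d[k] * d[k];
      dn = std::sqrt(dn);
      if (!std::isfinite(dn) || dn < 1e-12) break;
      if (dn > step_cap) {
        for (int k = 0; k < p; ++k) d[k] *= step_cap / dn;
      }

      bool accepted = false;
      for (int it = 0; it < 4 && !accepted; ++it) {
        for (int k = 0; k < p; ++k) xbest[k] = x[k] + tvals[it] * d[k];
        clipv(xbest, lo, hi, p);
        const double fc = obj.eval(j, xbest);
        if (fc > f0 + 1e-12) {
          double moved = 0.0;
          for (int k = 0; k < p; ++k) {
            moved = std::max(moved, std::fabs(xbest[k] - x[k]));
            x[k] = xbest[k];
          }
          const double gain = fc - f0;
          f0 = fc;
          accepted = true;
          if (moved < 1e-7 && gain < 1e-10 * (1.0 + std::fabs(f0))) {
            iter = max_iter;  // converged
          }
        }
      }
      if (!accepted) break;
    }
    for (int k = 0; k < p; ++k) out(j, k) = x[k];
  }
  return out;
}
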