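#include <Rcpp.h>
#include <set>
#include <cmath>
using namespace Rcpp;

// Barry & Hartigan (1993) product-partition change-point model, Gibbs
// sampling over the change indicators rho_1..rho_{n-1} with uniform priors
// p ~ U(0, p0) on the change probability and w ~ U(0, w0) on the
// signal-to-noise ratio. The conditional odds for a change at boundary i are
//
//   odds = [ I_p(k+1) / I_p(k) ] * [ I_w((k+1)/2, W1, B1) / I_w(k/2, W0, B0) ]
//
// with I_p(c) = int_0^p0 p^c (1-p)^(n-1-c) dp,
//      I_w(a, W, B) = int_0^w0 w^a (W + B w)^(-(n-1)/2) dw,
// k the number of change points among the other boundaries, and (W, B) the
// within/between block sums of squares under rho_i = 0 / 1.
// Integrals are evaluated by 64-point Gauss-Legendre quadrature on the
// log scale (robust for the large exponents involved).

static const int GL_N = 64;
static double gl_x[GL_N], gl_w[GL_N];
static bool gl_ready = false;

static void gl_init() {
  // Golub-Welsch via Newton iteration on Legendre polynomials, [-1, 1]
  if (gl_ready) return;
  int m = (GL_N + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double x = std::cos(M_PI * (i + 0.75) / (GL_N + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < GL_N; ++j) {
        double p2 = p1; p1 = p0;
        p0 = ((2.0 * j + 1.0) * x * p1 - j * p2) / (j + 1.0);
      }
      pp = GL_N * (x * p0 - p1) / (x * x - 1.0);
      double dx = p0 / pp;
      x -= dx;
      if (std::fabs(dx) < 1e-15) break;
    }
    gl_x[i] = -x; gl_x[GL_N - 1 - i] = x;
    gl_w[i] = 2.0 / ((1.0 - x * x) * pp * pp);
    gl_w[GL_N - 1 - i] = gl_w[i];
  }
  gl_ready = true;
}

// log int_0^upper exp(a*log(w) + c*log1p(-w) - d*log(W + B*w)) dw
// (c = 0 or the (1-p) exponent; set W=1,B=0,d=0 for the p-integral)
static double log_int(double upper, double a, double c,
                      double W, double B, double d) {
  double logf[GL_N], mx = R_NegInf;
  for (int i = 0; i < GL_N; ++i) {
    double w = 0.5 * upper * (gl_x[i] + 1.0);
    double lf = (a > 0 ? a * std::log(w) : 0.0)
              + (c > 0 ? c * std::log1p(-w) : 0.0)
              - (d > 0 ? d * std::log(W + B * w) : 0.0);
    logf[i] = lf;
    if (lf > mx) mx = lf;
  }
  if (!R_finite(mx)) return R_NegInf;
  double s = 0.0;
  for (int i = 0; i < GL_N; ++i) s += gl_w[i] * std::exp(logf[i] - mx);
  return mx + std::log(0.5 * upper * s);
}

// [[Rcpp::export]]
List cpp_bcp(NumericVector x, double p0, double w0, int iters, int burnin) {
  gl_init();
  const int n = x.size();
  if (n < 3) stop("series too short");
  const double d = (n - 1.0) / 2.0;

  std::vector<double> cs1(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs1[i + 1] = cs1[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  const double S1 = cs1[n], S2 = cs2[n];
  const double totSS = S2 - S1 * S1 / n;
  NumericVector prob(n - 1), pmean(n);
  if (totSS <= 1e-300) {
    // constant series: partition is irrelevant; change probability at the
    // prior level, posterior mean flat
    double prior = p0 / 2.0;
    for (int i = 0; i < n - 1; ++i) prob[i] = prior;
    for (int i = 0; i < n; ++i) pmean[i] = x[0];
    return List::create(_["prob"] = prob, _["mean"] = pmean);
  }

  // Q = sum over blocks of S_blk^2 / n_blk; W = S2 - Q, B = Q - S1^2/n
  std::set<int> cp;  // change point after position i (0-based, i in 0..n-2)
  auto blkQ = [&](int lo, int hi) {  // block = positions [lo, hi)
    double s = cs1[hi] - cs1[lo];
    return s * s / (hi - lo);
  };
  double Q = blkQ(0, n);
  int k_tot = 0;  // current number of change points

  std::vector<double> prob_acc(n - 1, 0.0), mean_acc(n, 0.0);
  int kept = 0;

  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n - 1; ++i) {
      bool cur = cp.count(i) > 0;
      // block containing boundary i under "no change at i"
      auto up = cp.upper_bound(i);
      int hi = (up == cp.end()) ? n : (*up + 1);
      int lo = 0;
      if (up != cp.begin()) {
        auto lo_it = std::prev(up);
        if (*lo_it == i) {
          // shouldn't happen: cur would be true and *lo_it==i -> handle below
          lo = (lo_it == cp.begin()) ? 0 : (*std::prev(lo_it) + 1);
        } else lo = *lo_it + 1;
      }
      if (cur) {
        // recompute lo ignoring i itself
        auto it2 = cp.find(i);
        lo = (it2 == cp.begin()) ? 0 : (*std::prev(it2) + 1);
        auto it3 = std::next(it2);
        hi = (it3 == cp.end()) ? n : (*it3 + 1);
      }
      double q_join = blkQ(lo, hi);
      double q_split = blkQ(lo, i + 1) + blkQ(i + 1, hi);
      double Q0 = cur ? (Q - q_split + q_join) : Q;        // rho_i = 0
      double Q1 = cur ? Q : (Q - q_join + q_split);        // rho_i = 1
      double W0 = S2 - Q0, B0 = Q0 - S1 * S1 / n;
      double W1 = S2 - Q1, B1 = Q1 - S1 * S1 / n;
      if (W0 < 1e-12 * totSS) W0 = 1e-12 * totSS;
      if (W1 < 1e-12 * totSS) W1 = 1e-12 * totSS;
      if (B0 < 0) B0 = 0;
      if (B1 < 0) B1 = 0;
      int k = k_tot - (cur ? 1 : 0);  // changes among the other boundaries

      double lp = log_int(p0, k + 1.0, n - 2.0 - k, 1.0, 0.0, 0.0)
                - log_int(p0, (double)k, n - 1.0 - k, 1.0, 0.0, 0.0);
      double lw = log_int(w0, (k + 1.0) / 2.0, 0.0, W1, B1, d)
                - log_int(w0, k / 2.0, 0.0, W0, B0, d);
      double lodds = lp + lw;
      double pch = 1.0 / (1.0 + std::exp(-lodds));
      bool nw = unif_rand() < pch;
      if (nw && !cur) { cp.insert(i); Q = Q1; k_tot++; }
      else if (!nw && cur) { cp.erase(i); Q = Q0; k_tot--; }
    }
    if (it >= burnin) {
      kept++;
      int lo = 0;
      auto itc = cp.begin();
      while (lo < n) {
        int hi = (itc == cp.end()) ? n : (*itc + 1);
        double m = (cs1[hi] - cs1[lo]) / (hi - lo);
        for (int j = lo; j < hi; ++j) mean_acc[j] += m;
        lo = hi;
        if (itc != cp.end()) ++itc;
      }
      for (auto c : cp) prob_acc[c] += 1.0;
    }
  }
  for (int i = 0; i < n - 1; ++i) prob[i] = prob_acc[i] / kept;
  for (int i = 0; i < n; ++i) pmean[i] = mean_acc[i] / kept;
  return List::create(_["prob"] = prob, _["mean"] = pmean);
}
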