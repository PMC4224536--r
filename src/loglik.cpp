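#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Internal nodes sorted by increasing time give a valid post-order for an
// ultrametric genealogy: every parent is strictly older than its children.
static std::vector<int> internal_order(const NumericVector& node_time, int n_tips) {
  int m = node_time.size() - n_tips;
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = n_tips + i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return node_time[a] < node_time[b]; });
  return idx;
}

// Pruning log-likelihood of an alignment under a Kimura-type 2-parameter
// model parameterized by the transition/transversion event ratio R.
// Rates are scaled so one unit of branch "distance" is one expected mutation
// per site; distance on a branch of time-length dt is (theta/2) * dt.
//
// tip_patterns: n_tips x P matrix of base codes 1..4 (A,C,G,T), one column
//   per unique site pattern; weights: pattern multiplicities.
// children: (n_tips-1) x 2, row r = children (1-based node ids) of internal
//   node n_tips + r; node_time: length 2*n_tips-1, tips at 0.
// [[Rcpp::export]]
double k2p_loglik_cpp(const IntegerMatrix& tip_patterns,
                      const NumericVector& weights,
                      const IntegerMatrix& children,
                      const NumericVector& node_time,
                      double theta, double R) {
  const int n_tips = tip_patterns.nrow();
  const int P = tip_patterns.ncol();
  const int n_nodes = 2 * n_tips - 1;
  if (theta < 0) stop("theta must be >= 0");

  // transition rate alpha, per-target transversion rate beta, alpha+2beta=1
  const double alpha = R / (R + 1.0);
  const double beta  = 1.0 / (2.0 * (R + 1.0));

  // partial likelihoods: [node][pattern][state]
  std::vector<double> part((size_t)n_nodes * P * 4, 0.0);
  std::vector<double> logscale((size_t)P, 0.0);
  for (int t = 0; t < n_tips; ++t)
    for (int p = 0; p < P; ++p)
      part[((size_t)t * P + p) * 4 + (tip_patterns(t, p) - 1)] = 1.0;

  std::vector<int> order = internal_order(node_time, n_tips);
  for (int node : order) {
    double* dst = &part[((size_t)node * P) * 4];
    for (int p = 0; p < P; ++p)
      for (int s = 0; s < 4; ++s) dst[p * 4 + s] = 1.0;
    for (int side = 0; side < 2; ++side) {
      int child = children(node - n_tips, side) - 1;
      double d = 0.5 * theta * (node_time[node] - node_time[child]);
      double e4b = std::exp(-4.0 * beta * d);
      double e2ab = std::exp(-2.0 * (alpha + beta) * d);
      double p_same = 0.25 + 0.25 * e4b + 0.5 * e2ab;
      double p_ti   = 0.25 + 0.25 * e4b - 0.5 * e2ab;
      double p_tv   = 0.25 - 0.25 * e4b;  // each of the two transversions
      const double* src = &part[((size_t)child * P) * 4];
      for (int p = 0; p < P; ++p) {
        const double* L = src + p * 4;
        double tot = L[0] + L[1] + L[2] + L[3];
        for (int s = 0; s < 4; ++s) {
          int ti = (s + 2) % 4;  // A<->G, C<->T
          double v = p_same * L[s] + p_ti * L[ti] + p_tv * (tot - L[s] - L[ti]);
          dst[p * 4 + s] *= v;
        }
      }
    }
    // rescale to avoid underflow on deep trees
    for (int p = 0; p < P; ++p) {
      double mx = 0.0;
      for (int s = 0; s < 4; ++s) mx = std::max(mx, dst[p * 4 + s]);
      if (mx > 0.0 && mx < 1e-200) {
        for (int s = 0; s < 4; ++s) dst[p * 4 + s] /= mx;
        logscale[p] += std::log(mx);
      }
    }
  }

  int root = order.back();
  const double* rp = &part[((size_t)root * P) * 4];
  double ll = 0.0;
  for (int p = 0; p < P; ++p) {
    double lik = 0.25 * (rp[p * 4] + rp[p * 4 + 1] + rp[p * 4 + 2] + rp[p * 4 + 3]);
    if (lik <= 0.0) return R_NegInf;
    ll += weights[p] * (std::log(lik) + logscale[p]);
  }
  return ll;
}

// REML (root state integrated out under a flat prior) log-likelihood of tip
// values evolving as Brownian motion on the genealogy, variance accumulating
// at theta/2 per coalescent time unit. Felsenstein's contrast pruning; each
// local merge has unit Jacobian so the contrast product equals the flat-prior
// marginal exactly.
static double log_skellam_sa(double c, double vv) {
  double ac = std::fabs(c);
  if (vv < 1e-12) return ac < 0.5 ? 0.0 : R_NegInf;
  if (vv > 30.0) return -0.5 * (std::log(2.0 * M_PI * vv) + c * c / vv);
  double b = R::bessel_i(vv, ac, 2.0);
  return b > 0.0 ? std::log(b) : R_NegInf;
}

static double log_bin_prob_sa(double c, double sd) {
  double ac = std::fabs(c);
  if (sd < 1e-9) return ac < 0.5 ? 0.0 : R_NegInf;
  double a = (ac - 0.5) / sd, b = (ac + 0.5) / sd;
  double la = R::pnorm(a, 0.0, 1.0, 0, 1);
  double lb = R::pnorm(b, 0.0, 1.0, 0, 1);
  double d = lb - la;
  if (d > -1e-12) return R_NegInf;
  return la + std::log1p(-std::exp(d));
}

// `nugget` is an extra variance attached to every tip; with integer repeat
// counts modelled as continuous values, 1/12 (the variance of the rounding
// error) removes the singularity of the continuous density at zero-length
// cherries of identical alleles. With `discretize = TRUE` each contrast
// instead contributes the unit-bin normal integral (the continuous
// approximation to the probability of a whole-repeat displacement), which
// is bounded by 1 and is the default for genotype data.
// [[Rcpp::export]]
double bm_reml_loglik_cpp(const NumericVector& x,
                          const IntegerMatrix& children,
                          const NumericVector& node_time,
                          double theta, double nugget = 0.0,
                          int discretize = 0) {
  const int n_tips = x.size();
  const int n_nodes = 2 * n_tips - 1;
  if (theta <= 0) stop("theta must be > 0 for the Brownian likelihood");

  std::vector<double> val(n_nodes), vextra(n_nodes, nugget);
  for (int t = 0; t < n_tips; ++t) val[t] = x[t];
  for (int t = n_tips; t < n_nodes; ++t) vextra[t] = 0.0;

  std::vector<int> order = internal_order(node_time, n_tips);
  double ll = 0.0;
  for (int node : order) {
    int c1 = children(node - n_tips, 0) - 1;
    int c2 = children(node - n_tips, 1) - 1;
    double v1 = 0.5 * theta * (node_time[node] - node_time[c1]) + vextra[c1];
    double v2 = 0.5 * theta * (node_time[node] - node_time[c2]) + vextra[c2];
    double vv = v1 + v2;
    double diff = val[c1] - val[c2];
    if (discretize == 2) {
      ll += log_skellam_sa(diff, vv);
    } else if (discretize == 1) {
      ll += log_bin_prob_sa(diff, std::sqrt(vv));
    } else {
      if (vv <= 0.0) return R_NegInf;  // degenerate: zero-length cherry
      ll += -0.5 * (std::log(2.0 * M_PI * vv) + diff * diff / vv);
    }
    if (ll == R_NegInf) return R_NegInf;
    if (vv > 0.0) {
      val[node] = (val[c1] * v2 + val[c2] * v1) / vv;
      vextra[node] = v1 * v2 / vv;
    } else {
      val[node] = 0.5 * (val[c1] + val[c2]);
      vextra[node] = 0.0;
    }
  }
  return ll;
}
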