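#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-chain Metropolis-Hastings over (theta, per-locus genealogies),
// with the whole iteration loop in C++ so that desk-scale chains can run
// hundreds of thousands of states. Mirrors the R reference engine
// (run_theta_mcmc_r); the two are cross-checked in the test suite.
//
// State per locus: children matrix ((n-1) x 2, 1-based ids), node times
// (tips first, all zero), parent array. Moves:
//   theta-add   reflected Gaussian walk on theta
//   theta-mult  log-scale walk (Hastings u)
//   slide       node time uniform in its free interval / root excess scaling
//   exchange    narrow exchange (swap child with uncle)
//   tipswap     swap two tip leaves (topology relabeling)
//   scale       all times of one locus scaled by exp(u)
//   ridge       all times of all loci scaled, theta inversely (likelihood
//               invariant: branch mutational lengths theta/2*dt unchanged)

struct Locus {
  int n_tips;
  std::vector<int> child;    // 2*(n-1), 0-based node ids
  std::vector<double> time;  // 2n-1
  std::vector<int> parent;   // 2n-1, -1 for root
  // data (one of)
  std::vector<double> x;               // BM tip values
  std::vector<int> pat;                // K2P tip patterns, n_tips x P, codes 0..3
  std::vector<double> wt;              // pattern weights
  int P = 0;
  // BM pruning state, maintained incrementally: per-node REML value,
  // extra variance, and per-internal-node contrast contribution
  std::vector<double> val, vex, contrib;
  double ll_cache = 0.0;
  bool cache_ok = false;
};

static void rebuild_parent(Locus& L) {
  int n = L.n_tips;
  L.parent.assign(2 * n - 1, -1);
  for (int r = 0; r < n - 1; ++r) {
    L.parent[L.child[2 * r]] = n + r;
    L.parent[L.child[2 * r + 1]] = n + r;
  }
}

static int root_of(const Locus& L) {
  int n = L.n_tips, rt = n;
  for (int i = n; i < 2 * n - 1; ++i)
    if (L.time[i] > L.time[rt]) rt = i;
  return rt;
}

static const std::vector<int>& order_internal(const Locus& L) {
  int n = L.n_tips;
  static thread_local std::vector<int> idx;
  idx.resize(n - 1);
  for (int i = 0; i < n - 1; ++i) idx[i] = n + i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return L.time[a] < L.time[b]; });
  return idx;
}

static double coal_logdens(const Locus& L) {
  int n = L.n_tips;
  static thread_local std::vector<double> t;
  t.assign(L.time.begin() + n, L.time.end());
  std::sort(t.begin(), t.end());
  double lp = 0.0, prev = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    double k = n - i;
    lp -= k * (k - 1) / 2.0 * (t[i] - prev);
    prev = t[i];
  }
  return lp;
}

// log P(|N(0, sd^2)| in [|c|-1/2, |c|+1/2]): the unit-bin integral of the
// normal, i.e. the continuous approximation to the probability of a net
// displacement of c whole repeat units. Bounded by 0, so exact allele ties
// cannot reward unbounded variance collapse the way a density can.
static const double INV_SQRT2 = 0.70710678118654752440;

// log Skellam(c; v): exact displacement distribution of a +/-1 stepwise
// walk with Poisson-mean v steps, e^{-v} I_{|c|}(v), evaluated at the
// (possibly fractional) contrast via the non-integer-order Bessel I.
// Correct leptokurtosis at small v, Gaussian-like at large v.
static double log_skellam_prob(double c, double vv) {
  double ac = std::fabs(c);
  if (vv < 1e-12) return ac < 0.5 ? 0.0 : R_NegInf;
  if (vv > 30.0) {  // Gaussian limit; relative error < 1% and Bessel is slow
    return -0.5 * (std::log(2.0 * M_PI * vv) + c * c / vv);
  }
  double b = R::bessel_i(vv, ac, 2.0);  // I_nu(v) * exp(-v)
  return b > 0.0 ? std::log(b) : R_NegInf;
}

static double log_bin_prob(double c, double sd) {
  double ac = std::fabs(c);
  if (sd < 1e-9) return ac < 0.5 ? 0.0 : R_NegInf;
  double a = (ac - 0.5) / sd, b = (ac + 0.5) / sd;
  if (b < 7.0) {  // fast path: the bin mass is far from underflow
    double P = 0.5 * (std::erfc(a * INV_SQRT2) - std::erfc(b * INV_SQRT2));
    return P > 0.0 ? std::log(P) : R_NegInf;
  }
  double la = R::pnorm(a, 0.0, 1.0, 0, 1);  // log upper tails
  double lb = R::pnorm(b, 0.0, 1.0, 0, 1);
  double d = lb - la;  // <= 0
  if (d > -1e-12) return R_NegInf;
  return la + std::log1p(-std::exp(d));
}

// one pruning step at an internal node; updates val/vex and returns the
// node's contrast contribution
static inline double bm_node_contrib(Locus& L, int node, double theta,
                                     double nugget, int discretize) {
  int n = L.n_tips;
  int c1 = L.child[2 * (node - n)], c2 = L.child[2 * (node - n) + 1];
  double v1 = 0.5 * theta * (L.time[node] - L.time[c1]) + L.vex[c1];
  double v2 = 0.5 * theta * (L.time[node] - L.time[c2]) + L.vex[c2];
  double vv = v1 + v2, diff = L.val[c1] - L.val[c2];
  double ct;
  if (discretize == 2) {
    ct = log_skellam_prob(diff, vv);
  } else if (discretize == 1) {
    ct = log_bin_prob(diff, std::sqrt(vv));
  } else {
    ct = vv > 0.0
      ? -0.5 * (std::log(2.0 * M_PI * vv) + diff * diff / vv)
      : R_NegInf;
  }
  if (vv > 0.0) {
    L.val[node] = (L.val[c1] * v2 + L.val[c2] * v1) / vv;
    L.vex[node] = v1 * v2 / vv;
  } else {  // zero-length cherry of equal values (discretized mode only)
    L.val[node] = 0.5 * (L.val[c1] + L.val[c2]);
    L.vex[node] = 0.0;
  }
  return ct;
}

static double bm_full(Locus& L, double theta, double nugget, int discretize) {
  int n = L.n_tips;
  L.val.assign(2 * n - 1, 0.0);
  L.vex.assign(2 * n - 1, 0.0);
  L.contrib.assign(2 * n - 1, 0.0);
  for (int i = 0; i < n; ++i) { L.val[i] = L.x[i]; L.vex[i] = nugget; }
  double ll = 0.0;
  for (int node : order_internal(L)) {
    double ct = bm_node_contrib(L, node, theta, nugget, discretize);
    L.contrib[node] = ct;
    ll += ct;
    if (ll == R_NegInf) { L.cache_ok = false; return R_NegInf; }
  }
  L.ll_cache = ll;
  L.cache_ok = true;
  return ll;
}

// recompute only the contributions of `touched` nodes and their ancestors
// (the only pruning quantities a local tree move can change); assumes the
// cache is valid for the pre-move state restricted to untouched nodes
static double bm_update(Locus& L, double theta, double nugget,
                        int discretize, const std::vector<int>& touched) {
  int n = L.n_tips;
  static thread_local std::vector<int> aff;
  static thread_local std::vector<char> seen;
  aff.clear();
  seen.assign(2 * n - 1, 0);
  for (int t : touched) {
    for (int u = t; u >= 0; u = L.parent[u]) {
      if (u >= n && !seen[u]) { seen[u] = 1; aff.push_back(u); }
      else if (u >= n && seen[u]) break;
    }
  }
  std::sort(aff.begin(), aff.end(),
            [&](int a, int b) { return L.time[a] < L.time[b]; });
  double ll = L.ll_cache;
  for (int node : aff) {
    double ct = bm_node_contrib(L, node, theta, nugget, discretize);
    ll += ct - L.contrib[node];
    L.contrib[node] = ct;
    if (ct == R_NegInf) { L.cache_ok = false; return R_NegInf; }
  }
  L.ll_cache = ll;
  return ll;
}

static double k2p_ll(const Locus& L, double theta, double R) {
  int n = L.n_tips, P = L.P;
  double alpha = R / (R + 1.0), beta = 1.0 / (2.0 * (R + 1.0));
  std::vector<double> part((size_t)(2 * n - 1) * P * 4, 0.0);
  std::vector<double> logscale(P, 0.0);
  for (int t = 0; t < n; ++t)
    for (int p = 0; p < P; ++p)
      part[((size_t)t * P + p) * 4 + L.pat[(size_t)t * P + p]] = 1.0;
  const std::vector<int>& ord = order_internal(L);
  for (int node : ord) {
    double* dst = &part[((size_t)node * P) * 4];
    for (int p = 0; p < P * 4; ++p) dst[p] = 1.0;
    for (int side = 0; side < 2; ++side) {
      int ch = L.child[2 * (node - n) + side];
      double d = 0.5 * theta * (L.time[node] - L.time[ch]);
      double e4b = std::exp(-4.0 * beta * d);
      double e2ab = std::exp(-2.0 * (alpha + beta) * d);
      double p_same = 0.25 + 0.25 * e4b + 0.5 * e2ab;
      double p_ti = 0.25 + 0.25 * e4b - 0.5 * e2ab;
      double p_tv = 0.25 - 0.25 * e4b;
      const double* src = &part[((size_t)ch * P) * 4];
      for (int p = 0; p < P; ++p) {
        const double* Lc = src + p * 4;
        double tot = Lc[0] + Lc[1] + Lc[2] + Lc[3];
        for (int s = 0; s < 4; ++s) {
          int ti = (s + 2) % 4;
          dst[p * 4 + s] *= p_same * Lc[s] + p_ti * Lc[ti] +
                            p_tv * (tot - Lc[s] - Lc[ti]);
        }
      }
    }
    for (int p = 0; p < P; ++p) {
      double mx = 0.0;
      for (int s = 0; s < 4; ++s) mx = std::max(mx, dst[p * 4 + s]);
      if (mx > 0.0 && mx < 1e-200) {
        for (int s = 0; s < 4; ++s) dst[p * 4 + s] /= mx;
        logscale[p] += std::log(mx);
      }
    }
  }
  int rt = ord.back();
  const double* rp = &part[((size_t)rt * P) * 4];
  double ll = 0.0;
  for (int p = 0; p < P; ++p) {
    double lik = 0.25 * (rp[p * 4] + rp[p * 4 + 1] + rp[p * 4 + 2] + rp[p * 4 + 3]);
    if (lik <= 0.0) return R_NegInf;
    ll += L.wt[p] * (std::log(lik) + logscale[p]);
  }
  return ll;
}

// type: 0 = BM (values, nugget, discretize), 1 = K2P (patterns, R)
// [[Rcpp::export]]
List mcmc_engine_cpp(List children_list, List times_list, List data_list,
                     int type, double nugget, int discretize, double Rtv,
                     NumericVector bounds, double theta_init,
                     int warmup, int burn_in, int n_samples, int thin,
                     double theta_step, double time_step,
                     bool prior_only, NumericVector move_weights) {
  int n_loci = children_list.size();
  std::vector<Locus> loci(n_loci);
  for (int j = 0; j < n_loci; ++j) {
    Locus& L = loci[j];
    IntegerMatrix ch = children_list[j];
    NumericVector tm = times_list[j];
    L.n_tips = ch.nrow() + 1;
    L.child.resize(2 * (L.n_tips - 1));
    for (int r = 0; r < L.n_tips - 1; ++r) {
      L.child[2 * r] = ch(r, 0) - 1;
      L.child[2 * r + 1] = ch(r, 1) - 1;
    }
    L.time.assign(tm.begin(), tm.end());
    rebuild_parent(L);
    if (type == 0) {
      NumericVector x = data_list[j];
      L.x.assign(x.begin(), x.end());
    } else {
      List d = data_list[j];
      IntegerMatrix pat = d["patterns"];
      NumericVector wt = d["weights"];
      L.P = pat.ncol();
      L.pat.resize((size_t)L.n_tips * L.P);
      for (int t = 0; t < L.n_tips; ++t)
        for (int p = 0; p < L.P; ++p)
          L.pat[(size_t)t * L.P + p] = pat(t, p) - 1;
      L.wt.assign(wt.begin(), wt.end());
    }
  }

  double lo = bounds[0], hi = bounds[1];
  double theta = std::min(std::max(theta_init, lo + 1e-3 * (hi - lo)),
                          hi - 1e-3 * (hi - lo));
  auto loglik = [&](Locus& L, double th) -> double {
    if (prior_only) return 0.0;
    return type == 0 ? bm_full(L, th, nugget, discretize) : k2p_ll(L, th, Rtv);
  };
  std::vector<double> ll(n_loci), lpc(n_loci);
  double sum_ll = 0.0;
  for (int j = 0; j < n_loci; ++j) {
    ll[j] = loglik(loci[j], theta);
    lpc[j] = coal_logdens(loci[j]);
    sum_ll += ll[j];
  }
  long total_internal = 0;
  for (auto& L : loci) total_internal += L.n_tips - 1;

  // move weights: theta-add, theta-mult, slide, exchange, tipswap, scale,
  // ridge, spr
  const int n_mv = 8;
  double wts[n_mv] = {0.15, 0.10, 0.20, 0.10, 0.08, 0.08, 0.09, 0.20};
  if (move_weights.size() == n_mv)
    for (int i = 0; i < n_mv; ++i) wts[i] = move_weights[i];
  double cum[n_mv];
  double s = 0.0;
  for (int i = 0; i < n_mv; ++i) { s += wts[i]; cum[i] = s; }
  for (int i = 0; i < n_mv; ++i) cum[i] /= s;

  long n_iter = (long)warmup + (long)burn_in + (long)n_samples * thin;
  Locus backup;  // persistent scratch: vector assignment reuses capacity
  std::vector<int> spr_stack, spr_cand;
  std::vector<char> spr_inside;
  NumericVector samples(n_samples);
  NumericVector acc(n_mv, 0.0), att(n_mv, 0.0);
  double step_theta = theta_step * (hi - lo);
  int k_rec = 0;

  for (long it = 1; it <= n_iter; ++it) {
    double u01 = unif_rand();
    int mv = 0;
    while (mv < n_mv - 1 && u01 > cum[mv]) ++mv;
    // warm-up: adapt the latent genealogies with theta held fixed at its
    // moment-based start before the joint chain begins (pure initialization;
    // nothing from this phase is recorded)
    if (it <= warmup && (mv == 0 || mv == 1 || mv == 6)) mv = 2;
    att[mv] += 1;

    if (mv == 0 || mv == 1) {  // theta moves (recompute all loci)
      double th_new, logh;
      if (mv == 0) {
        double w = hi - lo;
        double z = theta + norm_rand() * step_theta - lo;
        double y = z - std::floor(z / (2 * w)) * (2 * w);
        th_new = lo + (y > w ? 2 * w - y : y);
        logh = 0.0;
      } else {
        double u = norm_rand() * 0.4;
        th_new = theta * std::exp(u);
        logh = u;
      }
      if (th_new > lo && th_new < hi) {
        double new_sum = 0.0;
        std::vector<double> ll_new(n_loci);
        for (int j = 0; j < n_loci; ++j) {
          ll_new[j] = loglik(loci[j], th_new);
          new_sum += ll_new[j];
        }
        if (std::log(unif_rand()) < new_sum - sum_ll + logh) {
          theta = th_new; ll = ll_new; sum_ll = new_sum; acc[mv] += 1;
        } else if (type == 0 && !prior_only) {
          // trial evaluation overwrote the pruning caches; rebuild them
          // for the retained theta
          for (int j = 0; j < n_loci; ++j) bm_full(loci[j], theta, nugget,
                                                   discretize);
        }
      }
    } else if (mv == 6) {  // ridge: scale all times, theta inversely
      double u = (unif_rand() - 0.5) * time_step;
      double th_new = theta * std::exp(-u);
      if (th_new > lo && th_new < hi) {
        double f = std::exp(u), d_lpc = 0.0;
        std::vector<double> lpc_new(n_loci);
        // coalescent density scales analytically: intervals scale by f
        for (int j = 0; j < n_loci; ++j) {
          // lpc is -sum(C(k,2) dt): scaling all times by f scales it by f
          lpc_new[j] = lpc[j] * f;
          d_lpc += lpc_new[j] - lpc[j];
        }
        double logr = d_lpc + (total_internal - 1) * u;
        if (std::log(unif_rand()) < logr) {
          for (auto& L : loci)
            for (auto& t : L.time) t *= f;
          theta = th_new; lpc = lpc_new; acc[mv] += 1;
          // likelihood exactly invariant: branch var theta/2*dt unchanged
        }
      }
    } else {  // per-locus tree moves
      int j = n_loci == 1 ? 0 : (int)(unif_rand() * n_loci);
      if (j >= n_loci) j = n_loci - 1;
      Locus& L = loci[j];
      int n = L.n_tips;
      backup = L;
      double logh = 0.0;
      bool ok = true;
      std::vector<int> touched;  // nodes whose pruning inputs a local move changed
      if (mv == 2) {  // slide
        int node = n + (int)(unif_rand() * (n - 1));
        if (node > 2 * n - 2) node = 2 * n - 2;
        if (L.parent[node] < 0) {
          double base = std::max(L.time[L.child[2 * (node - n)]],
                                 L.time[L.child[2 * (node - n) + 1]]);
          double u = (unif_rand() * 2 - 1) * time_step;
          L.time[node] = base + (L.time[node] - base) * std::exp(u);
          logh = u;
        } else {
          double lo_t = std::max(L.time[L.child[2 * (node - n)]],
                                 L.time[L.child[2 * (node - n) + 1]]);
          double hi_t = L.time[L.parent[node]];
          L.time[node] = lo_t + unif_rand() * (hi_t - lo_t);
        }
        touched.push_back(node);
      } else if (mv == 3) {  // narrow exchange
        int p = n + (int)(unif_rand() * (n - 1));
        if (p > 2 * n - 2) p = 2 * n - 2;
        int gp = L.parent[p];
        if (gp < 0) ok = false;
        else {
          int sib = L.child[2 * (gp - n)] == p ? L.child[2 * (gp - n) + 1]
                                               : L.child[2 * (gp - n)];
          if (L.time[sib] >= L.time[p]) ok = false;
          else {
            int ci = (int)(unif_rand() * 2);
            int c = L.child[2 * (p - n) + ci];
            if (L.child[2 * (gp - n)] == sib) L.child[2 * (gp - n)] = c;
            else L.child[2 * (gp - n) + 1] = c;
            L.child[2 * (p - n) + ci] = sib;
            L.parent[c] = gp; L.parent[sib] = p;
            touched.push_back(p); touched.push_back(gp);
          }
        }
      } else if (mv == 4) {  // tip swap
        int t1 = (int)(unif_rand() * n), t2 = (int)(unif_rand() * n);
        if (t1 >= n) t1 = n - 1;
        if (t2 >= n) t2 = n - 1;
        if (t1 == t2 || L.parent[t1] == L.parent[t2]) ok = false;
        else {
          int p1 = L.parent[t1], p2 = L.parent[t2];
          for (int s = 0; s < 2; ++s) {
            if (L.child[2 * (p1 - n) + s] == t1) L.child[2 * (p1 - n) + s] = t2;
            if (L.child[2 * (p2 - n) + s] == t2) L.child[2 * (p2 - n) + s] = t1;
          }
          L.parent[t1] = p2; L.parent[t2] = p1;
          touched.push_back(t1); touched.push_back(t2);
        }
      } else if (mv == 5) {  // scale one locus
        double u = (unif_rand() - 0.5) * time_step;
        double f = std::exp(u);
        for (auto& t : L.time) t *= f;
        logh = (n - 1) * u;
      } else {  // subtree prune-regraft (fixed subtree height)
        int rt = root_of(L);
        int v = (int)(unif_rand() * (2 * n - 2));
        if (v >= rt) ++v;
        if (v > 2 * n - 2) v = 2 * n - 2;
        int p = L.parent[v];
        int s = L.child[2 * (p - n)] == v ? L.child[2 * (p - n) + 1]
                                          : L.child[2 * (p - n)];
        int g = L.parent[p];
        double tv = L.time[v], t_old = L.time[p];
        // detach the unit (p above v); s takes p's place
        if (g >= 0) {
          if (L.child[2 * (g - n)] == p) L.child[2 * (g - n)] = s;
          else L.child[2 * (g - n) + 1] = s;
          L.parent[s] = g;
        } else {
          L.parent[s] = -1;  // p was the root
        }
        int rem_root = (g >= 0) ? rt : s;
        // nodes inside the pruned subtree cannot receive the attachment
        spr_inside.assign(2 * n - 1, 0);
        spr_stack.clear();
        spr_stack.push_back(v);
        while (!spr_stack.empty()) {
          int u_ = spr_stack.back(); spr_stack.pop_back();
          spr_inside[u_] = 1;
          if (u_ >= n) {
            spr_stack.push_back(L.child[2 * (u_ - n)]);
            spr_stack.push_back(L.child[2 * (u_ - n) + 1]);
          }
        }
        spr_cand.clear();
        for (int c = 0; c < 2 * n - 1; ++c) {
          if (c == p || spr_inside[c] || c == rem_root) continue;
          int q = L.parent[c];
          if (q < 0) continue;
          if (L.time[q] > std::max(L.time[c], tv)) spr_cand.push_back(c);
        }
        int K = (int)spr_cand.size();
        double root_lower = std::max(L.time[rem_root], tv);
        // reverse-proposal density of the old attachment (same detached tree)
        double log_q_rev;
        if (g >= 0) {
          double lower_old = std::max(L.time[s], tv);
          log_q_rev = -std::log((double)K + 1) -
                      std::log(L.time[g] - lower_old);
        } else {
          log_q_rev = -std::log((double)K + 1) - (t_old - root_lower);
        }
        // draw the new attachment
        int pick = (int)(unif_rand() * (K + 1));
        double t_new, log_q_fwd;
        if (pick >= K) {  // attach above the remaining root
          double e = exp_rand();
          t_new = root_lower + e;
          log_q_fwd = -std::log((double)K + 1) - e;
          L.parent[p] = -1;
          if (L.child[2 * (p - n)] == v) L.child[2 * (p - n) + 1] = rem_root;
          else L.child[2 * (p - n)] = rem_root;
          L.parent[rem_root] = p;
        } else {
          int c = spr_cand[pick];
          int q = L.parent[c];
          double lower = std::max(L.time[c], tv);
          double len = L.time[q] - lower;
          t_new = lower + unif_rand() * len;
          log_q_fwd = -std::log((double)K + 1) - std::log(len);
          if (L.child[2 * (q - n)] == c) L.child[2 * (q - n)] = p;
          else L.child[2 * (q - n) + 1] = p;
          L.parent[p] = q;
          if (L.child[2 * (p - n)] == v) L.child[2 * (p - n) + 1] = c;
          else L.child[2 * (p - n)] = c;
          L.parent[c] = p;
        }
        L.time[p] = t_new;
        logh = log_q_rev - log_q_fwd;
        touched.push_back(p); touched.push_back(s);
      }
      if (ok) {
        double ll_new;
        if (!prior_only && type == 0 && !touched.empty() && L.cache_ok)
          ll_new = bm_update(L, theta, nugget, discretize, touched);
        else
          ll_new = loglik(L, theta);
        double lpc_new = coal_logdens(L);
        if (std::log(unif_rand()) <
            ll_new - ll[j] + lpc_new - lpc[j] + logh) {
          sum_ll += ll_new - ll[j];
          ll[j] = ll_new; lpc[j] = lpc_new;
          acc[mv] += 1;
        } else {
          L = backup;
        }
      } else {
        L = backup;
      }
    }
    if (it > warmup + burn_in && (it - warmup - burn_in) % thin == 0)
      samples[k_rec++] = theta;
  }

  List out_children(n_loci), out_times(n_loci);
  for (int j = 0; j < n_loci; ++j) {
    Locus& L = loci[j];
    IntegerMatrix ch(L.n_tips - 1, 2);
    for (int r = 0; r < L.n_tips - 1; ++r) {
      ch(r, 0) = L.child[2 * r] + 1;
      ch(r, 1) = L.child[2 * r + 1] + 1;
    }
    out_children[j] = ch;
    out_times[j] = NumericVector(L.time.begin(), L.time.end());
  }
  CharacterVector mv_names = CharacterVector::create(
      "theta", "thetam", "slide", "exchange", "tipswap", "scale", "ridge",
      "spr");
  NumericVector rate(n_mv);
  for (int i = 0; i < n_mv; ++i)
    rate[i] = att[i] > 0 ? acc[i] / att[i] : NA_REAL;
  rate.names() = mv_names;
  return List::create(_["samples"] = samples, _["acceptance"] = rate,
                      _["children"] = out_children, _["times"] = out_times);
}
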