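// Compiled cores for the genotype-likelihood pipeline: the SAF dynamic
// program, weighted SFS EM, the fused per-subpopulation theta path (site
// pattern deduplication + SAF + EM + per-site estimators), the pooled SNP
// likelihood-ratio test, and low-coverage read simulation.
//
// All likelihood bookkeeping is done in linear space with per-step
// renormalization; SAF vectors are returned normalized to max 1 (log max 0),
// which is the only scale downstream consumers (EM, posteriors) depend on.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// hypergeometric convolution weights w[k][j][g] =
//   C(2,g) * C(2k-2, j-g) / C(2k, j)
// for adding individual k (1-based) to a partial SAF over 2k-2 chromosomes.
static std::vector<std::vector<std::array<double, 3>>> saf_weights(int n) {
  std::vector<std::vector<std::array<double, 3>>> w(n + 1);
  for (int k = 1; k <= n; ++k) {
    w[k].assign(2 * k + 1, {0.0, 0.0, 0.0});
    for (int j = 0; j <= 2 * k; ++j) {
      for (int g = 0; g <= 2 && g <= j; ++g) {
        if (j - g > 2 * k - 2) continue;
        double lw = R::lchoose(2.0, g) + R::lchoose(2.0 * k - 2.0, j - g) -
                    R::lchoose(2.0 * k, j);
        w[k][j][g] = std::exp(lw);
      }
    }
  }
  return w;
}

// One site's SAF from per-individual linear genotype likelihoods
// (gl[i][g], any positive scale). Output length 2n+1, normalized to max 1.
static void saf_site(const std::vector<std::array<double, 3>>& gl,
                     const std::vector<std::vector<std::array<double, 3>>>& w,
                     std::vector<double>& out) {
  int n = (int)gl.size();
  std::vector<double> h(2 * n + 1, 0.0), hn(2 * n + 1, 0.0);
  h[0] = 1.0;
  for (int k = 1; k <= n; ++k) {
    double mx = 0.0;
    for (int j = 0; j <= 2 * k; ++j) {
      double acc = 0.0;
      for (int g = 0; g <= 2 && g <= j; ++g) {
        double wt = w[k][j][g];
        if (wt > 0.0) acc += gl[k - 1][g] * wt * h[j - g];
      }
      hn[j] = acc;
      if (acc > mx) mx = acc;
    }
    if (mx <= 0.0) mx = 1.0;  // degenerate (all-zero likelihoods)
    for (int j = 0; j <= 2 * k; ++j) h[j] = hn[j] / mx;
  }
  out.assign(h.begin(), h.end());
}

// [[Rcpp::export]]
NumericMatrix cpp_saf(NumericMatrix ll0, NumericMatrix ll1, NumericMatrix ll2) {
  // ll*: S x n log genotype likelihoods. Returns S x (2n+1) log SAF, max 0.
  int S = ll0.nrow(), n = ll0.ncol();
  auto w = saf_weights(n);
  NumericMatrix out(S, 2 * n + 1);
  std::vector<std::array<double, 3>> gl(n);
  std::vector<double> h;
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) {
      double m = std::max(ll0(s, i), std::max(ll1(s, i), ll2(s, i)));
      gl[i][0] = std::exp(ll0(s, i) - m);
      gl[i][1] = std::exp(ll1(s, i) - m);
      gl[i][2] = std::exp(ll2(s, i) - m);
    }
    saf_site(gl, w, h);
    for (int j = 0; j <= 2 * n; ++j)
      out(s, j) = h[j] > 0.0 ? std::log(h[j]) : R_NegInf;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sfs_em(NumericMatrix saf_lin, NumericVector wts, double tol,
                int max_iter) {
  // saf_lin: U x (m+1) linear SAF (any per-row scale); wts: row weights.
  int U = saf_lin.nrow(), M = saf_lin.ncol();
  double W = 0.0;
  for (int s = 0; s < U; ++s) W += wts[s];
  std::vector<double> p(M, 1.0 / M), acc(M);
  std::vector<double> logliks;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    double ll = 0.0;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int s = 0; s < U; ++s) {
      double denom = 0.0;
      for (int j = 0; j < M; ++j) denom += p[j] * saf_lin(s, j);
      if (denom <= 0.0) continue;  // zero-mass row: no information
      ll += wts[s] * std::log(denom);
      double inv = wts[s] / denom;
      for (int j = 0; j < M; ++j) acc[j] += p[j] * saf_lin(s, j) * inv;
    }
    logliks.push_back(ll);
    double delta = 0.0;
    for (int j = 0; j < M; ++j) {
      double pn = acc[j] / W;
      delta = std::max(delta, std::fabs(pn - p[j]));
      p[j] = pn;
    }
    if (delta < tol) { converged = true; break; }
  }
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["loglik"] = NumericVector(logliks.begin(), logliks.end()),
                      _["iterations"] = (int)logliks.size(),
                      _["converged"] = converged);
}

// Fused per-subpopulation theta path. Sites are deduplicated by the sorted
// multiset of per-individual (k0, k1) read counts (the SAF is exchangeable
// over individuals), the SAF DP and EM run on unique patterns only, and
// per-site theta values are recovered by pattern lookup. Exactly equal to
// the modular route, site for site.
// [[Rcpp::export]]
List cpp_subpop_theta(IntegerMatrix depth, IntegerMatrix k1, double e,
                      int min_ind, double min_depth, double max_depth,
                      double tol, int max_iter) {
  int S = depth.nrow(), n = depth.ncol();
  int M = 2 * n + 1;
  double le = std::log(e), l1e = std::log1p(-e), lh = std::log(0.5);

  LogicalVector pass(S);
  IntegerVector pat(S);  // 1-based pattern id for passing sites, 0 otherwise
  std::map<std::vector<int>, int> ids;
  std::vector<std::vector<int>> patterns;  // interleaved sorted (depth, k1)
  std::vector<double> wts;
  std::vector<int> key(2 * n);
  std::vector<std::pair<int, int>> prs(n);

  for (int s = 0; s < S; ++s) {
    int ncov = 0;
    long tot = 0;
    for (int i = 0; i < n; ++i) {
      int d = depth(s, i);
      if (d > 0) ++ncov;
      tot += d;
      prs[i] = {d, k1(s, i)};
    }
    bool ok = ncov >= min_ind && tot >= min_depth && tot <= max_depth;
    pass[s] = ok;
    if (!ok) { pat[s] = 0; continue; }
    std::sort(prs.begin(), prs.end());
    for (int i = 0; i < n; ++i) { key[2 * i] = prs[i].first; key[2 * i + 1] = prs[i].second; }
    auto it = ids.find(key);
    if (it == ids.end()) {
      int id = (int)patterns.size();
      ids.emplace(key, id);
      patterns.push_back(key);
      wts.push_back(1.0);
      pat[s] = id + 1;
    } else {
      wts[it->second] += 1.0;
      pat[s] = it->second + 1;
    }
  }

  int U = (int)patterns.size();
  auto w = saf_weights(n);
  NumericMatrix saf_lin(U, M);
  std::vector<std::array<double, 3>> gl(n);
  std::vector<double> h;
  for (int u = 0; u < U; ++u) {
    for (int i = 0; i < n; ++i) {
      int d = patterns[u][2 * i], kk1 = patterns[u][2 * i + 1];
      int kk0 = d - kk1;
      double a = kk0 * l1e + kk1 * le;
      double b = d * lh;
      double c = kk0 * le + kk1 * l1e;
      double m = std::max(a, std::max(b, c));
      gl[i][0] = std::exp(a - m);
      gl[i][1] = std::exp(b - m);
      gl[i][2] = std::exp(c - m);
    }
    saf_site(gl, w, h);
    for (int j = 0; j < M; ++j) saf_lin(u, j) = h[j];
  }

  List em = U > 0
                ? cpp_sfs_em(saf_lin, NumericVector(wts.begin(), wts.end()),
                             tol, max_iter)
                : List::create(_["p"] = NumericVector(M, 1.0 / M),
                               _["loglik"] = NumericVector(0),
                               _["iterations"] = 0, _["converged"] = true);
  NumericVector p = em["p"];

  // per-pattern posterior thetas
  double am = 0.0;
  for (int i = 1; i < M - 1; ++i) am += 1.0 / i;  // a_m = sum_{1}^{m-1} 1/i
  double cm2 = (double)(M - 1) * (M - 2) / 2.0;   // C(m, 2), m = 2n
  NumericVector tp_u(U), tw_u(U);
  for (int u = 0; u < U; ++u) {
    double tot = 0.0;
    std::vector<double> q(M);
    for (int j = 0; j < M; ++j) { q[j] = p[j] * saf_lin(u, j); tot += q[j]; }
    double tp = 0.0, seg = 0.0;
    if (tot > 0.0) {
      for (int j = 0; j < M; ++j) {
        double qq = q[j] / tot;
        tp += qq * j * (M - 1 - j) / cm2;
        if (j > 0 && j < M - 1) seg += qq;
      }
    }
    tp_u[u] = tp;
    tw_u[u] = am > 0 ? seg / am : 0.0;
  }

  return List::create(_["pass"] = pass, _["pattern"] = pat,
                      _["saf_unique"] = saf_lin,
                      _["weights"] = NumericVector(wts.begin(), wts.end()),
                      _["sfs"] = p, _["loglik"] = em["loglik"],
                      _["iterations"] = em["iterations"],
                      _["converged"] = em["converged"],
                      _["theta_pi_u"] = tp_u, _["theta_w_u"] = tw_u,
                      _["n_unique"] = U);
}

// pooled-sample log likelihood of allele frequency f under HWE, from linear
// per-individual genotype likelihoods (scale-free up to a constant).
static double freq_loglik(const std::vector<std::array<double, 3>>& gl,
                          double f) {
  // product accumulation with occasional rescaling: one log per site
  // instead of one per individual (exact up to floating point).
  double p0 = (1.0 - f) * (1.0 - f), p1 = 2.0 * f * (1.0 - f), p2 = f * f;
  double ll = 0.0, prod = 1.0;
  for (size_t i = 0; i < gl.size(); ++i) {
    double v = gl[i][0] * p0 + gl[i][1] * p1 + gl[i][2] * p2;
    prod *= (v > 0.0 ? v : 1e-300);
    if (prod < 1e-280) { ll += std::log(prod); prod = 1.0; }
  }
  return ll + std::log(prod);
}

// [[Rcpp::export]]
List cpp_snp_lrt(NumericMatrix ll0, NumericMatrix ll1, NumericMatrix ll2,
                 double tol) {
  // Likelihood-ratio test of minor allele frequency = 0 against the ML
  // frequency, per site. The site is oriented by its major allele (the
  // monomorphic state with the higher likelihood); the golden-section search
  // runs on the minor-allele frequency in [0, 0.5].
  int S = ll0.nrow(), n = ll0.ncol();
  NumericVector fhat(S), lrt(S);
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  std::vector<std::array<double, 3>> gl(n);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) {
      double m = std::max(ll0(s, i), std::max(ll1(s, i), ll2(s, i)));
      gl[i][0] = std::exp(ll0(s, i) - m);
      gl[i][1] = std::exp(ll1(s, i) - m);
      gl[i][2] = std::exp(ll2(s, i) - m);
    }
    double l_at0 = freq_loglik(gl, 0.0), l_at1 = freq_loglik(gl, 1.0);
    bool major0 = l_at0 >= l_at1;
    double lnull = major0 ? l_at0 : l_at1;
    // minor-frequency likelihood: f_minor -> allele-1 freq
    auto lmin = [&](double fm) {
      return freq_loglik(gl, major0 ? fm : 1.0 - fm);
    };
    double a = 0.0, b = 0.5;
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    double f1 = lmin(x1), f2 = lmin(x2);
    while (b - a > tol) {
      if (f1 < f2) { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = lmin(x2); }
      else         { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = lmin(x1); }
    }
    double fm = 0.5 * (a + b);
    double lhat = std::max(lmin(fm), lnull);
    fhat[s] = major0 ? fm : 1.0 - fm;
    lrt[s] = 2.0 * (lhat - lnull);
  }
  return List::create(_["fhat"] = fhat, _["lrt"] = lrt);
}

// [[Rcpp::export]]
List cpp_simulate_reads(IntegerMatrix hap, IntegerVector pos0, int L,
                        double mean_depth, double e, IntegerVector ind_idx) {
  // hap: (2*n_all) x S_seg 0/1 alleles; pos0: 0-based sorted positions of the
  // segregating columns; ind_idx: 1-based individual indices to simulate.
  // Draw order is site-major then individual, fixed for reproducibility.
  // Depth ~ Poisson(mean_depth) and the ancestral-background error count
  // ~ Binomial(d, e) are drawn by inverse-CDF table lookup from a single
  // uniform each (exact distributions, one fast draw per cell);
  // heterozygous/derived cells fall back to R::rbinom.
  int n = ind_idx.size();
  int Sseg = hap.ncol();
  const int DMAX = 64;
  std::vector<double> pois_cdf;
  {
    double p = std::exp(-mean_depth), c = p;
    pois_cdf.push_back(c);
    for (int k = 1; k <= DMAX && c < 1.0 - 1e-15; ++k) {
      p *= mean_depth / k;
      c += p;
      pois_cdf.push_back(c);
    }
  }
  // binom(d, e) CDFs for background cells, indexed by depth
  std::vector<std::vector<double>> bin_cdf(DMAX + 1);
  for (int d = 1; d <= DMAX; ++d) {
    double p = std::pow(1.0 - e, d), c = p;
    bin_cdf[d].push_back(c);
    for (int k = 1; k <= d && c < 1.0 - 1e-15; ++k) {
      p *= (double)(d - k + 1) / k * e / (1.0 - e);
      c += p;
      bin_cdf[d].push_back(c);
    }
  }
  auto draw_cdf = [](const std::vector<double>& cdf) {
    double u = unif_rand();
    int k = 0, m = (int)cdf.size();
    while (k < m - 1 && u > cdf[k]) ++k;
    return k;
  };
  IntegerMatrix depth(L, n), k1(L, n);
  std::vector<int> dos(n);
  RNGScope scope;
  int sp = 0;  // pointer into pos0
  for (int l = 0; l < L; ++l) {
    bool seg = sp < Sseg && pos0[sp] == l;
    if (seg) {
      for (int i = 0; i < n; ++i) {
        int ind = ind_idx[i] - 1;
        dos[i] = hap(2 * ind, sp) + hap(2 * ind + 1, sp);
      }
    }
    for (int i = 0; i < n; ++i) {
      int d = draw_cdf(pois_cdf);
      if (d == (int)pois_cdf.size() - 1 && pois_cdf.back() < 1.0 - 1e-15)
        d = (int)R::rpois(mean_depth);  // saturated table: exact fallback
      depth(l, i) = d;
      if (d == 0) { k1(l, i) = 0; continue; }
      if (seg && dos[i] > 0) {
        double p = e + 0.5 * dos[i] * (1.0 - 2.0 * e);
        k1(l, i) = (int)R::rbinom(d, p);
      } else if (e <= 0.0) {
        k1(l, i) = 0;
      } else if (d <= DMAX) {
        k1(l, i) = draw_cdf(bin_cdf[d]);
      } else {
        k1(l, i) = (int)R::rbinom(d, e);
      }
    }
    if (seg) ++sp;
  }
  return List::create(_["depth"] = depth, _["k1"] = k1);
}
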