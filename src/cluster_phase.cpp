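// Haplotype-cluster model engines: EM for the template allele
// frequencies and joint Viterbi decoding of the template pair.
// States are ordered s = a + K*b (a fastest), matching the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// genotype emission P(g | theta_a, theta_b)
static inline double emit(int g, double ta, double tb) {
  switch (g) {
  case 0: return (1.0 - ta) * (1.0 - tb);
  case 1: return ta * (1.0 - tb) + (1.0 - ta) * tb;
  default: return ta * tb;
  }
}

// The forward/backward quantities are exactly symmetric in the two
// template slots (symmetric emission, transition and prior), so the
// EM works on the packed lower triangle: state (a, b) with b <= a,
// weight 2 off the diagonal.  The two independent per-slot
// transitions compose into the closed form
//   F''[a,b] = r^2 F[a,b] + (r q / K)(R[a] + R[b]) + (q / K)^2 T
// with R the full row sums and T the full total.

struct TriIndex {
  int K, S;
  std::vector<int> ia, ib;
  std::vector<double> w;
  explicit TriIndex(int K_) : K(K_), S(K_ * (K_ + 1) / 2) {
    ia.resize(S); ib.resize(S); w.resize(S);
    int t = 0;
    for (int a = 0; a < K; ++a)
      for (int b = 0; b <= a; ++b, ++t) {
        ia[t] = a; ib[t] = b; w[t] = (a == b) ? 1.0 : 2.0;
      }
  }
};

// fused double transition on the packed triangle (in place)
static void trans_tri(std::vector<double>& F, const TriIndex& ti,
                      double r, double q) {
  const int K = ti.K, S = ti.S;
  std::vector<double> R(K, 0.0);
  double T = 0.0;
  for (int t = 0; t < S; ++t) {
    R[ti.ia[t]] += F[t];
    if (ti.ia[t] != ti.ib[t]) R[ti.ib[t]] += F[t];  // mirrored entry
    T += ti.w[t] * F[t];
  }
  const double r2 = r * r, rq = r * q / ti.K;
  const double qq = (q / ti.K) * (q / ti.K) * T;
  for (int t = 0; t < S; ++t)
    F[t] = r2 * F[t] + rq * (R[ti.ia[t]] + R[ti.ib[t]]) + qq;
}

// [[Rcpp::export]]
NumericMatrix em_theta_cpp(IntegerMatrix G, NumericMatrix theta0,
                           double persistence, int n_em) {
  const int n = G.nrow(), m = G.ncol(), K = theta0.nrow();
  const TriIndex ti(K);
  const int S = ti.S;
  const double r = persistence, q = 1.0 - persistence;
  NumericMatrix theta = clone(theta0);

  std::vector<double> alpha((size_t)m * S);
  std::vector<double> beta(S), F(S);
  std::vector<double> num((size_t)K * m), den((size_t)K * m);
  std::vector<double> th(K);

  for (int iter = 0; iter < n_em; ++iter) {
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      // forward, locally normalised, stored per locus
      for (int l = 0; l < m; ++l) {
        const int g = G(i, l);
        for (int k = 0; k < K; ++k) th[k] = theta(k, l);
        if (l > 0) trans_tri(F, ti, r, q);
        double s = 0.0;
        for (int t = 0; t < S; ++t) {
          const double ta = th[ti.ia[t]], tb = th[ti.ib[t]];
          double e;
          if (g == 0) e = (1.0 - ta) * (1.0 - tb);
          else if (g == 2) e = ta * tb;
          else e = ta + tb - 2.0 * ta * tb;
          const double v = (l == 0 ? 1.0 : F[t]) * e;
          F[t] = v;
          s += ti.w[t] * v;
        }
        if (s <= 0) s = 1e-300;
        for (int t = 0; t < S; ++t) F[t] /= s;
        std::copy(F.begin(), F.end(), alpha.begin() + (size_t)l * S);
      }
      // backward with immediate accumulation
      std::fill(beta.begin(), beta.end(), 1.0 / (K * (double)K));
      for (int l = m - 1; l >= 0; --l) {
        const int g = G(i, l);
        for (int k = 0; k < K; ++k) th[k] = theta(k, l);
        double gs = 0.0;
        const double* al = alpha.data() + (size_t)l * S;
        for (int t = 0; t < S; ++t) gs += ti.w[t] * al[t] * beta[t];
        if (gs <= 0) gs = 1e-300;
        double* nl = num.data() + (size_t)K * l;
        double* dl = den.data() + (size_t)K * l;
        if (g == 1) {
          for (int t = 0; t < S; ++t) {
            const double gam = ti.w[t] * al[t] * beta[t] / gs;
            const double ta = th[ti.ia[t]], tb = th[ti.ib[t]];
            const double p1 = ta * (1.0 - tb);
            double p1s = p1 + (1.0 - ta) * tb;
            if (p1s < 1e-12) p1s = 1e-12;
            const double ea = p1 / p1s;
            nl[ti.ia[t]] += gam * ea;
            nl[ti.ib[t]] += gam * (1.0 - ea);
            dl[ti.ia[t]] += gam;
            dl[ti.ib[t]] += gam;
          }
        } else {
          const double allele = (g == 2) ? 1.0 : 0.0;
          for (int t = 0; t < S; ++t) {
            const double gam = ti.w[t] * al[t] * beta[t] / gs;
            nl[ti.ia[t]] += gam * allele;
            nl[ti.ib[t]] += gam * allele;
            dl[ti.ia[t]] += gam;
            dl[ti.ib[t]] += gam;
          }
        }
        if (l > 0) {
          double s = 0.0;
          for (int t = 0; t < S; ++t) {
            const double ta = th[ti.ia[t]], tb = th[ti.ib[t]];
            double e;
            if (g == 0) e = (1.0 - ta) * (1.0 - tb);
            else if (g == 2) e = ta * tb;
            else e = ta + tb - 2.0 * ta * tb;
            beta[t] *= e;
          }
          trans_tri(beta, ti, r, q);   // transition matrix is symmetric
          for (int t = 0; t < S; ++t) s += ti.w[t] * beta[t];
          if (s <= 0) s = 1e-300;
          for (int t = 0; t < S; ++t) beta[t] /= s;
        }
      }
    }
    for (int l = 0; l < m; ++l)
      for (int k = 0; k < K; ++k) {
        double d = den[k + (size_t)K * l];
        double v = num[k + (size_t)K * l] / (d > 1e-12 ? d : 1e-12);
        theta(k, l) = std::min(0.999, std::max(0.001, v));
      }
  }
  return theta;
}

// [[Rcpp::export]]
IntegerVector viterbi_pair_cpp(IntegerVector g, NumericMatrix theta,
                               double persistence) {
  const int m = g.size(), K = theta.nrow(), S = K * K;
  const double lstay = std::log(persistence);
  const double ljump = std::log((1.0 - persistence) / K);
  std::vector<double> f(S), best(S);
  std::vector<int> ptr((size_t)m * S);
  std::vector<double> rmx(K), cmx(K);
  std::vector<int> rmx_i(K), cmx_i(K);

  for (int s = 0; s < S; ++s)
    f[s] = std::log(std::max(emit(g[0], theta(s % K, 0), theta(s / K, 0)),
                             1e-300));
  for (int l = 1; l < m; ++l) {
    // per-a max over b, per-b max over a, global max of f
    for (int a = 0; a < K; ++a) { rmx[a] = -INFINITY; rmx_i[a] = 0; }
    for (int b = 0; b < K; ++b) { cmx[b] = -INFINITY; cmx_i[b] = 0; }
    double gmx = -INFINITY; int gmx_s = 0;
    for (int s = 0; s < S; ++s) {
      const int a = s % K, b = s / K;
      if (f[s] > rmx[a]) { rmx[a] = f[s]; rmx_i[a] = b; }
      if (f[s] > cmx[b]) { cmx[b] = f[s]; cmx_i[b] = a; }
      if (f[s] > gmx) { gmx = f[s]; gmx_s = s; }
    }
    for (int s = 0; s < S; ++s) {
      const int a = s % K, b = s / K;
      double v = f[s] + 2.0 * lstay;          // both chains stay
      int p = s;
      const double v2 = rmx[a] + lstay + ljump;   // b jumps
      if (v2 > v) { v = v2; p = a + K * rmx_i[a]; }
      const double v3 = cmx[b] + ljump + lstay;   // a jumps
      if (v3 > v) { v = v3; p = cmx_i[b] + K * b; }
      const double v4 = gmx + 2.0 * ljump;        // both jump
      if (v4 > v) { v = v4; p = gmx_s; }
      best[s] = v +
        std::log(std::max(emit(g[l], theta(a, l), theta(b, l)), 1e-300));
      ptr[(size_t)l * S + s] = p;
    }
    double mx = -INFINITY;
    for (int s = 0; s < S; ++s) mx = std::max(mx, best[s]);
    for (int s = 0; s < S; ++s) f[s] = best[s] - mx;
  }
  IntegerVector path(m);
  int s_best = 0;
  for (int s = 1; s < S; ++s) if (f[s] > f[s_best]) s_best = s;
  path[m - 1] = s_best + 1;                  // 1-based for R
  for (int l = m - 1; l >= 1; --l)
    path[l - 1] = ptr[(size_t)l * S + (path[l] - 1)] + 1;
  return path;
}
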