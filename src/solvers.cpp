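#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sparse (CSC) matrix-vector product y = A * v.
static void csc_matvec(const int *Ai, const int *Ap, const double *Ax,
                       int n, const double *v, double *y) {
  for (int i = 0; i < n; ++i) y[i] = 0.0;
  for (int j = 0; j < n; ++j) {
    const double vj = v[j];
    if (vj == 0.0) continue;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) y[Ai[k]] += Ax[k] * vj;
  }
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_expv_unif(IntegerVector Ai, IntegerVector Ap,
                            NumericVector Ax, NumericVector v,
                            double t, double lambda, double tail_tol) {
  const int n = v.size();
  NumericVector out(n);
  if (t == 0.0 || lambda == 0.0) {
    for (int i = 0; i < n; ++i) out[i] = v[i];
    return out;
  }
  const double lt = lambda * t;
  // Poisson(lt) window [k_lo, k_hi] holding all but < 2*tail_tol of the
  // mass; weights outside it are dropped (u is still advanced below k_lo).
  const int k_lo = (int)R::qpois(tail_tol, lt, 1, 0);
  int k_hi = (int)R::qpois(tail_tol, lt, 0, 0) + 5;
  if (k_hi < k_lo + 5) k_hi = k_lo + 5;

  // u carries B^k v in double; the weighted accumulation runs in long
  // double so the summed mass stays accurate over ~1e3 terms. The weight
  // recurrence w_{k+1} = w_k * lt/(k+1) is seeded at k_lo from the
  // log-scale Poisson density (a normal double inside the window even for
  // very large lt, where dpois(0, lt) itself underflows).
  std::vector<double> u(v.begin(), v.end());
  std::vector<double> au(n);
  std::vector<long double> acc(n, 0.0L);
  const double inv_lambda = 1.0 / lambda;
  long double w = (long double)std::exp(R::dpois((double)k_lo, lt, 1));
  if (k_lo == 0) {
    for (int i = 0; i < n; ++i) acc[i] = w * u[i];
  }
  for (int k = 1; k <= k_hi; ++k) {
    // u <- (I + A/lambda) u
    csc_matvec(Ai.begin(), Ap.begin(), Ax.begin(), n, u.data(), au.data());
    for (int i = 0; i < n; ++i) u[i] += au[i] * inv_lambda;
    if (k < k_lo) continue;
    if (k > k_lo) w *= lt / (long double)k;
    for (int i = 0; i < n; ++i) acc[i] += w * u[i];
  }
  for (int i = 0; i < n; ++i) out[i] = (double)acc[i];
  return out;
}

// Gillespie SSA for the n-allele two-state promoter model.
// State per trajectory: rho (active alleles), m (mRNA count, untruncated).
// Uses R's RNG so results are reproducible under set.seed().
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_ssa_two_state(double k1, double k0, double mu0, double mu1,
                                double delta, int n_alleles, double t_end,
                                IntegerVector rho_init, IntegerVector m_init) {
  const int n_traj = rho_init.size();
  IntegerMatrix out(n_traj, 2);
  RNGScope scope;
  for (int tr = 0; tr < n_traj; ++tr) {
    int rho = rho_init[tr];
    long m = m_init[tr];
    double t = 0.0;
    for (;;) {
      const double a1 = k1 * (n_alleles - rho);      // activation
      const double a2 = k0 * rho;                    // inactivation
      const double a3 = mu0 * (n_alleles - rho) + mu1 * rho;  // synthesis
      const double a4 = delta * m;                   // degradation
      const double a0 = a1 + a2 + a3 + a4;
      if (a0 <= 0.0) break;
      t += R::exp_rand() / a0;
      if (t > t_end) break;
      const double r = unif_rand() * a0;
      if (r < a1) ++rho;
      else if (r < a1 + a2) --rho;
      else if (r < a1 + a2 + a3) ++m;
      else --m;
    }
    out(tr, 0) = rho;
    out(tr, 1) = (int)m;
  }
  return out;
}
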