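#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// State-dependent speciation-extinction derivatives for k states.
// y = (E_1..E_k, D_1..D_k); q is row-major with q[i*k+j] the i->j rate.
static void sse_derivs(int k, const double* lam, const double* mu,
                       const double* q, const double* y, double* dy) {
  for (int i = 0; i < k; ++i) {
    double qsum = 0.0, qe = 0.0, qd = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      double qij = q[i * k + j];
      qsum += qij;
      qe += qij * y[j];
      qd += qij * y[k + j];
    }
    double s = lam[i] + mu[i] + qsum;
    dy[i]     = mu[i] - s * y[i] + lam[i] * y[i] * y[i] + qe;
    dy[k + i] = -s * y[k + i] + 2.0 * lam[i] * y[i] * y[k + i] + qd;
  }
}

// Dormand-Prince 5(4) adaptive stepper on raw buffers; integrates y in
// place from t0 to t1. Returns 0 on success, 1 on step-size failure.
static int rk45(int k, const double* lam, const double* mu, const double* q,
                double* y, double t0, double t1, double rtol, double atol,
                double* work /* 9 * 2k doubles */) {
  const int n = 2 * k;
  if (t1 <= t0) return 0;

  static const double a21 = 1.0 / 5.0;
  static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
  static const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
  static const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
                      a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
  static const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
                      a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0,
                      a65 = -5103.0 / 18656.0;
  static const double b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0,
                      b4 = 125.0 / 192.0, b5 = -2187.0 / 6784.0,
                      b6 = 11.0 / 84.0;
  static const double e1 = 35.0 / 384.0 - 5179.0 / 57600.0,
                      e3 = 500.0 / 1113.0 - 7571.0 / 16695.0,
                      e4 = 125.0 / 192.0 - 393.0 / 640.0,
                      e5 = -2187.0 / 6784.0 + 92097.0 / 339200.0,
                      e6 = 11.0 / 84.0 - 187.0 / 2100.0,
                      e7 = -1.0 / 40.0;

  double *k1 = work, *k2 = work + n, *k3 = work + 2 * n, *k4 = work + 3 * n,
         *k5 = work + 4 * n, *k6 = work + 5 * n, *k7 = work + 6 * n,
         *ytmp = work + 7 * n, *y5 = work + 8 * n;

  double t = t0;
  const double span = t1 - t0;
  double h = span / 4.0;
  const double hmin = span * 1e-14;
  const long maxsteps = 1000000;
  long steps = 0;

  sse_derivs(k, lam, mu, q, y, k1);

  while (t < t1) {
    if (++steps > maxsteps) return 1;
    if (h < hmin) return 1;
    if (t + h > t1) h = t1 - t;

    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    sse_derivs(k, lam, mu, q, ytmp, k2);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sse_derivs(k, lam, mu, q, ytmp, k3);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sse_derivs(k, lam, mu, q, ytmp, k4);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    sse_derivs(k, lam, mu, q, ytmp, k5);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    sse_derivs(k, lam, mu, q, ytmp, k6);
    for (int i = 0; i < n; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    sse_derivs(k, lam, mu, q, y5, k7);

    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);

    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) y[i] = y5[i];
      // tiny numerical excursions of E outside [0, 1]
      for (int i = 0; i < k; ++i) {
        if (y[i] < 0.0 && y[i] > -1e-12) y[i] = 0.0;
        if (y[i] > 1.0 && y[i] < 1.0 + 1e-12) y[i] = 1.0;
      }
      for (int i = 0; i < n; ++i) k1[i] = k7[i];  // FSAL
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      double fac = 0.9 * std::pow(errnorm, -0.2);
      h *= std::max(0.2, fac);
      // k1 unchanged (same y)
    }
  }
  return 0;
}

// Integrate the SSE system along one branch, from t0 (tipward) to t1
// (rootward). Returns the state at t1, or NULL if step-size control fails
// (caller falls back to a stiff solver).
// [[Rcpp::export(name = ".sse_branch_cpp")]]
SEXP sse_branch_cpp(NumericVector y0, double t0, double t1,
                    NumericVector lambda, NumericVector mu,
                    NumericMatrix qmat, double rtol, double atol) {
  const int k = lambda.size();
  const int n = 2 * k;
  if (y0.size() != n) stop("y0 must have length 2k");

  std::vector<double> q(k * k, 0.0);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j) q[i * k + j] = qmat(i, j);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> work(9 * n);
  if (rk45(k, REAL(lambda), REAL(mu), q.data(), y.data(), t0, t1, rtol,
           atol, work.data()) != 0)
    return R_NilValue;
  return NumericVector(y.begin(), y.end());
}

// Whole-tree MuSSE log-likelihood: postorder edge traversal, lambda
// products at internal nodes with per-node renormalization, FitzJohn
// ("obs", root_mode 0) or flat root weighting, optional survival
// conditioning. Returns NULL on integrator failure (caller falls back to
// the R path with a stiff solver).
// [[Rcpp::export(name = ".musse_lnl_cpp")]]
SEXP musse_lnl_cpp(IntegerMatrix edge, NumericVector t_node,
                   NumericMatrix tipD, NumericVector lambda,
                   NumericVector mu, NumericMatrix qmat,
                   int root_mode, bool condition_surv,
                   double rtol, double atol) {
  const int k = lambda.size();
  const int n = 2 * k;
  const int nedge = edge.nrow();
  const int ntip = tipD.nrow();
  const int nn = t_node.size();

  std::vector<double> q(k * k, 0.0);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j) q[i * k + j] = qmat(i, j);

  std::vector<double> E(nn * k, 0.0), D(nn * k, 0.0);
  std::vector<bool> seen(nn, false);
  for (int i = 0; i < ntip; ++i)
    for (int j = 0; j < k; ++j) D[i * k + j] = tipD(i, j);

  const double* lam = REAL(lambda);
  const double* mup = REAL(mu);
  std::vector<double> y(n), work(9 * n);
  double logcomp = 0.0;
  int rootnode = -1;

  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    rootnode = p;
    for (int j = 0; j < k; ++j) {
      y[j] = E[ch * k + j];
      y[k + j] = D[ch * k + j];
    }
    if (rk45(k, lam, mup, q.data(), y.data(), t_node[ch], t_node[p], rtol,
             atol, work.data()) != 0)
      return R_NilValue;
    if (!seen[p]) {
      for (int j = 0; j < k; ++j) {
        E[p * k + j] = y[j];
        D[p * k + j] = y[k + j];
      }
      seen[p] = true;
    } else {
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        D[p * k + j] *= lam[j] * y[k + j];
        s += D[p * k + j];
      }
      if (!(s > 0.0) || !std::isfinite(s))
        return NumericVector::create(R_NegInf);
      for (int j = 0; j < k; ++j) D[p * k + j] /= s;
      logcomp += std::log(s);
    }
  }
  double sD = 0.0;
  for (int j = 0; j < k; ++j) sD += D[rootnode * k + j];
  if (!(sD > 0.0)) return NumericVector::create(R_NegInf);
  double L = 0.0, denom = 0.0;
  for (int j = 0; j < k; ++j) {
    double w = (root_mode == 0) ? D[rootnode * k + j] / sD : 1.0 / k;
    L += w * D[rootnode * k + j];
    double oe = 1.0 - E[rootnode * k + j];
    denom += w * lam[j] * oe * oe;
  }
  if (condition_surv) {
    if (!(denom > 0.0)) return NumericVector::create(R_NegInf);
    L /= denom;
  }
  if (!(L > 0.0) || !std::isfinite(L))
    return NumericVector::create(R_NegInf);
  return NumericVector::create(std::log(L) + logcomp);
}
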