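// Numerical core for the two-type branching process with immigration.
//
// Everything here works with the single-ancestor PGF f(z, u) of the process
// started from one adenoma (type-A) cell, marginalised as requested:
//
//   mode 0 ("M"): z marks malignant cells, A is marginalised out;
//                 f solves  df/du = b1 f^2 - (b1+d1+mu2) f + d1 + mu2 h(z,u),
//                 f(z,0) = 1, where h is the linear birth-death PGF of a
//                 single M cell.
//   mode 1 ("A"): z marks A cells, the M argument is frozen at s0
//                 (s0 = 0 gives the joint "M extinct" generating function,
//                 s0 = 1 the exact A marginal);  f(z,0) = z and the
//                 inhomogeneity is h(s0,u), independent of z.
//
// Immigration at rate mu1 gives the population PGF
//   log G(z,t) = mu1 * Int_0^t (f(z,u) - 1) du,
// so the integral of f (and of its first two z-derivatives, used by the
// saddle point machinery) is carried along as extra ODE state.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline double cabs1(double x) { return std::fabs(x); }
static inline double cabs1(const cplx& x) { return std::abs(x); }

// ---------------------------------------------------------------------------
// linear birth-death PGF h(s,u) for one M cell, with s-derivatives.  h is a
// Moebius map h = (As+B)/(Cs+D) with AD-BC = g2^2 exp(-g2 u), so the n-th
// derivative is n! (-C)^(n-1) (AD-BC) / (Cs+D)^(n+1).
struct BDH {
  double b2, d2, g2;
  bool critical;
  BDH(double b2_, double d2_) : b2(b2_), d2(d2_), g2(b2_ - d2_) {
    critical = std::fabs(g2) < 1e-9 * (b2 + d2 + 1.0);
  }
  template <typename T>
  void eval(const T& s, double u, T& h, T& h1, T& h2, T& h3, T& h4) const {
    if (critical) {
      // b2 = d2: h = 1 - (1-s)/q, q = 1 + b2 u (1-s);  C = -b2 u, K = 1
      T q = 1.0 + b2 * u * (1.0 - s);
      double C = b2 * u;
      h = 1.0 - (1.0 - s) / q;
      h1 = 1.0 / (q * q);
      h2 = 2.0 * C * h1 / q;
      h3 = 3.0 * C * h2 / q;
      h4 = 4.0 * C * h3 / q;
    } else {
      double E = std::exp(-g2 * u);
      T w = (b2 * s - d2) * E;
      T den = b2 * (1.0 - s) + w;
      h = (d2 * (1.0 - s) + w) / den;
      double K = g2 * g2 * E;
      double mC = b2 * (1.0 - E);  // -C
      h1 = K / (den * den);
      h2 = 2.0 * mC * h1 / den;
      h3 = 3.0 * mC * h2 / den;
      h4 = 4.0 * mC * h3 / den;
    }
  }
};

// ---------------------------------------------------------------------------
// ODE right-hand side over a vector of PGF argument nodes
template <typename T>
struct PgfSys {
  double mu1, b1, d1, mu2, a;
  BDH bd;
  int mode;   // 0: nodes mark M; 1: nodes mark A, M arg frozen at s0
  double s0;
  int order;  // 0: (f, If); 2: + first 2 derivs; 4: + derivs 3 and 4
  std::vector<T> nodes;

  PgfSys(const NumericVector& par, int mode_, double s0_, int order_)
      : bd(par[4], par[5]), mode(mode_), s0(s0_), order(order_) {
    mu1 = par[0]; b1 = par[1]; d1 = par[2]; mu2 = par[3];
    a = b1 + d1 + mu2;
  }
  int nst() const { return order == 4 ? 10 : (order == 2 ? 6 : 2); }

  void rhs(double u, const std::vector<T>& y, std::vector<T>& dy) const {
    const int k = nst();
    const int nd = order;            // number of derivative states
    T hfix[5];
    if (mode == 1)
      bd.eval(T(s0), u, hfix[0], hfix[1], hfix[2], hfix[3], hfix[4]);
    for (size_t i = 0; i < nodes.size(); ++i) {
      T hv[5];
      if (mode == 0) bd.eval(nodes[i], u, hv[0], hv[1], hv[2], hv[3], hv[4]);
      else {
        hv[0] = hfix[0];
        for (int j = 1; j < 5; ++j) hv[j] = T(0.0);
      }
      const T* yy = &y[i * k];
      T* dd = &dy[i * k];
      // freeze a node whose derivative states saturate the double range
      // (they grow like exp(4 gamma2 t) near s = 1); its recorded values
      // are filtered out downstream
      if (order >= 2 && cabs1(yy[order]) > 1e280) {
        for (int j = 0; j < k; ++j) dd[j] = T(0.0);
        continue;
      }
      T f = yy[0];
      dd[0] = b1 * f * f - a * f + d1 + mu2 * hv[0];
      if (order >= 2) {
        T g = yy[1], w = yy[2];
        T lin = 2.0 * b1 * f - a;
        dd[1] = lin * g + mu2 * hv[1];
        dd[2] = 2.0 * b1 * g * g + lin * w + mu2 * hv[2];
        if (order == 4) {
          // Leibniz expansion of d^n/ds^n (f^2)
          T y3 = yy[3], y4 = yy[4];
          dd[3] = 6.0 * b1 * g * w + lin * y3 + mu2 * hv[3];
          dd[4] = 6.0 * b1 * w * w + 8.0 * b1 * g * y3 + lin * y4 +
                  mu2 * hv[4];
        }
        dd[1 + nd] = f - 1.0;
        for (int j = 1; j <= nd; ++j) dd[1 + nd + j] = yy[j];
      } else {
        dd[1] = f - 1.0;
      }
    }
  }

  void init_state(std::vector<T>& y) const {
    const int k = nst();
    y.assign(nodes.size() * k, T(0.0));
    for (size_t i = 0; i < nodes.size(); ++i) {
      if (mode == 0) {
        y[i * k] = T(1.0);             // M(0) = 0 from a fresh A cell
      } else {
        y[i * k] = nodes[i];           // one A ancestor marked by z
        if (order == 2) y[i * k + 1] = T(1.0);
      }
    }
  }
};

// ---------------------------------------------------------------------------
// adaptive Cash-Karp RK45 with records at requested (sorted) output times
// returns false if the solution diverges (PGF argument beyond the radius
// of convergence: the Riccati solution blows up in finite time)
template <typename T>
bool rk45_integrate(const PgfSys<T>& sys, std::vector<T>& y,
                    const std::vector<double>& tout,
                    std::vector<std::vector<T> >& records,
                    double rtol, double atol) {
  const size_t n = y.size();
  std::vector<T> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), ytmp(n), y5(n), y4(n);
  double t = 0.0, h = 1e-4;
  const double hmin = 1e-12, hmax = 1.0;
  long nstep = 0, max_step = 2000000;

  records.clear();
  records.reserve(tout.size());
  size_t iout = 0;
  while (iout < tout.size() && tout[iout] <= 0.0) {
    records.push_back(y);
    ++iout;
  }

  while (iout < tout.size()) {
    double target = tout[iout];
    while (t < target - 1e-13) {
      if (++nstep > max_step) stop("PGF ODE integration failed: step budget exceeded");
      double hs = std::min(h, target - t);
      // Cash-Karp stages
      sys.rhs(t, y, k1);
      for (size_t i = 0; i < n; ++i) ytmp[i] = y[i] + hs * (0.2 * k1[i]);
      sys.rhs(t + 0.2 * hs, ytmp, k2);
      for (size_t i = 0; i < n; ++i)
        ytmp[i] = y[i] + hs * (3.0 / 40.0 * k1[i] + 9.0 / 40.0 * k2[i]);
      sys.rhs(t + 0.3 * hs, ytmp, k3);
      for (size_t i = 0; i < n; ++i)
        ytmp[i] = y[i] + hs * (0.3 * k1[i] - 0.9 * k2[i] + 1.2 * k3[i]);
      sys.rhs(t + 0.6 * hs, ytmp, k4);
      for (size_t i = 0; i < n; ++i)
        ytmp[i] = y[i] + hs * (-11.0 / 54.0 * k1[i] + 2.5 * k2[i]
                               - 70.0 / 27.0 * k3[i] + 35.0 / 27.0 * k4[i]);
      sys.rhs(t + hs, ytmp, k5);
      for (size_t i = 0; i < n; ++i)
        ytmp[i] = y[i] + hs * (1631.0 / 55296.0 * k1[i] + 175.0 / 512.0 * k2[i]
                               + 575.0 / 13824.0 * k3[i]
                               + 44275.0 / 110592.0 * k4[i]
                               + 253.0 / 4096.0 * k5[i]);
      sys.rhs(t + 0.875 * hs, ytmp, k6);
      double errnorm = 0.0;
      for (size_t i = 0; i < n; ++i) {
        T v5 = y[i] + hs * (37.0 / 378.0 * k1[i] + 250.0 / 621.0 * k3[i]
                            + 125.0 / 594.0 * k4[i] + 512.0 / 1771.0 * k6[i]);
        T v4 = y[i] + hs * (2825.0 / 27648.0 * k1[i] + 18575.0 / 48384.0 * k3[i]
                            + 13525.0 / 55296.0 * k4[i]
                            + 277.0 / 14336.0 * k5[i] + 0.25 * k6[i]);
        y5[i] = v5;
        double sc = atol + rtol * std::max(cabs1(y[i]), cabs1(v5));
        double e = cabs1(v5 - v4) / sc;
        if (e > errnorm) errnorm = e;
      }
      if (errnorm <= 1.0 || hs <= hmin) {
        t += hs;
        y.swap(y5);
        // divergence (Riccati blow-up) is judged on f only; derivative
        // states may legitimately be enormous
        const int k = sys.nst();
        for (size_t i = 0; i < n; i += k)
          if (cabs1(y[i]) > 1e10) return false;
      }
      double fac = (errnorm > 1e-12) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h = std::min(hmax, std::max(hmin, hs * fac));
    }
    records.push_back(y);
    ++iout;
  }
  return true;
}

// ---------------------------------------------------------------------------
template <typename T>
static List profile_impl(const NumericVector& par, const std::vector<T>& nodes,
                         const NumericVector& ages, int mode, double s0,
                         int order, double rtol, double atol) {
  PgfSys<T> sys(par, mode, s0, order);
  sys.nodes = nodes;
  std::vector<T> y;
  sys.init_state(y);
  std::vector<double> tout(ages.begin(), ages.end());
  std::vector<std::vector<T> > rec;
  if (!rk45_integrate(sys, y, tout, rec, rtol, atol))
    stop("PGF ODE diverged: argument outside the radius of convergence");

  const int na = ages.size(), ns = nodes.size(), k = sys.nst();
  const int nd = order;
  auto cm = [&](int state) {
    ComplexMatrix M(na, ns);
    for (int ia = 0; ia < na; ++ia)
      for (int is = 0; is < ns; ++is) {
        cplx v(rec[ia][is * k + state]);
        M(ia, is).r = v.real(); M(ia, is).i = v.imag();
      }
    return M;
  };
  if (order == 4)
    return List::create(_["f"] = cm(0), _["If"] = cm(5), _["g"] = cm(1),
                        _["w"] = cm(2), _["Ig"] = cm(6), _["Iw"] = cm(7),
                        _["g3"] = cm(3), _["g4"] = cm(4), _["I3"] = cm(8),
                        _["I4"] = cm(9));
  if (order == 2)
    return List::create(_["f"] = cm(0), _["If"] = cm(3), _["g"] = cm(1),
                        _["w"] = cm(2), _["Ig"] = cm(4), _["Iw"] = cm(5));
  return List::create(_["f"] = cm(0), _["If"] = cm(1));
}

// Solve the PGF system at a set of argument nodes, recording the state at
// each requested age.  Returns complex matrices (ages x nodes).
// [[Rcpp::export]]
List pgf_profile_cpp(NumericVector par, NumericVector s_re, NumericVector s_im,
                     NumericVector ages, int mode, double s0, int order,
                     double rtol, double atol) {
  if (par.size() != 6) stop("par must have 6 elements");
  bool is_real = true;
  for (int i = 0; i < s_im.size(); ++i)
    if (s_im[i] != 0.0) { is_real = false; break; }
  if (is_real) {
    std::vector<double> nodes(s_re.begin(), s_re.end());
    return profile_impl<double>(par, nodes, ages, mode, s0, order, rtol, atol);
  }
  std::vector<cplx> nodes(s_re.size());
  for (int i = 0; i < s_re.size(); ++i) nodes[i] = cplx(s_re[i], s_im[i]);
  return profile_impl<cplx>(par, nodes, ages, mode, s0, order, rtol, atol);
}

// ---------------------------------------------------------------------------
// scalar helper: integrals of f and its first four s-derivatives at a
// single real node and single time; false if the solution diverges
static bool solve_scalar(const NumericVector& par, double s, double t, int mode,
                         double s0, double rtol, double atol, double I[5]) {
  PgfSys<double> sys(par, mode, s0, 4);
  sys.nodes.assign(1, s);
  std::vector<double> y;
  sys.init_state(y);
  std::vector<double> tout(1, t);
  std::vector<std::vector<double> > rec;
  if (!rk45_integrate(sys, y, tout, rec, rtol, atol)) return false;
  for (int j = 0; j < 5; ++j) I[j] = rec[0][5 + j];
  return true;
}

// Saddle-point log-coefficient of the contour integral
//   (1/2 pi i) \oint exp(V(s)) ds,
//   V(s) = tail * (-log(1-s)) + log G(s,t) - (N+1) log s,
// where tail = 1 extracts CDF-type coefficients of G/(1-s) and tail = 0
// plain coefficients of G.  Newton iteration safeguarded by bisection;
// V' is strictly increasing in s on (0,1).
// When `correction` is true the second-order stationary-phase term
// 1 + V''''/(8 V''^2) - 5 V'''^2/(24 V''^3) multiplies the leading-order
// result (clamped to [0.2, 2] for safety far outside the asymptotic
// regime); the uncorrected value is returned as log_coef0.
// [[Rcpp::export]]
List saddle_cdf_cpp(NumericVector par, double t, NumericVector N, int mode,
                    double s0, int tail, double rtol, double atol,
                    bool correction = true) {
  if (par.size() != 6) stop("par must have 6 elements");
  const double mu1 = par[0];
  const int nN = N.size();
  NumericVector s_star(nN), V(nN), V2(nN), logcoef(nN), logcoef0(nN),
      corrv(nN);
  IntegerVector iters(nN), conv(nN);

  for (int j = 0; j < nN; ++j) {
    double Nj = N[j];
    double lo = 1e-9, hi = 1.0 - 1e-13;
    // For plain coefficients (tail = 0) of a PGF that is analytic beyond 1
    // the saddle lies between 1 and the singularity: push the bracket out
    // until V' changes sign or the ODE diverges (past the singularity).
    if (tail == 0) {
      double I[5];
      bool found = false;
      double s_hi = hi;
      if (solve_scalar(par, s_hi, t, mode, s0, rtol, atol, I) &&
          1.0 / (1.0 - s_hi) * 0.0 + mu1 * I[1] - (Nj + 1.0) / s_hi > 0) {
        found = true;
      } else {
        for (int e = 0; e < 64; ++e) {
          s_hi = 1.0 + 1e-12 * std::pow(2.0, e);
          if (!solve_scalar(par, s_hi, t, mode, s0, rtol, atol, I)) {
            found = true;  // diverged: treat as V' = +inf
            break;
          }
          if (mu1 * I[1] - (Nj + 1.0) / s_hi > 0) { found = true; break; }
          lo = s_hi;
        }
      }
      if (found) hi = s_hi;
      else hi = 1.0 + 1e-12 * std::pow(2.0, 63.0);
    }
    double s = 0.5 * (lo + std::min(hi, (Nj + 1.0) / (Nj + 2.0) + 0.5));
    if (tail == 1) s = (Nj + 1.0) / (Nj + 2.0);
    double I[5] = {0, 0, 0, 0, 0};
    double Vp = 0, Vpp = 0;
    int it = 0; bool ok = false;
    for (it = 0; it < 90; ++it) {
      bool fine = solve_scalar(par, s, t, mode, s0, rtol, atol, I);
      if (!fine) {          // past the singularity: shrink from above
        hi = s;
        s = 0.5 * (lo + hi);
        continue;
      }
      Vp = tail / (1.0 - s) + mu1 * I[1] - (Nj + 1.0) / s;
      Vpp = tail / ((1.0 - s) * (1.0 - s)) + mu1 * I[2] +
            (Nj + 1.0) / (s * s);
      double scale = (Nj + 1.0) / s + std::fabs(tail / (1.0 - s)) +
                     std::fabs(mu1 * I[1]);
      if (std::fabs(Vp) <= 1e-9 * scale) { ok = true; break; }
      if (Vp > 0) hi = s; else lo = s;
      double snew = s - Vp / Vpp;
      if (!(snew > lo && snew < hi) || !std::isfinite(snew))
        snew = 0.5 * (lo + hi);
      if (std::fabs(snew - s) < 1e-16 * std::fabs(s)) { s = snew; ok = true; break; }
      s = snew;
    }
    double om = 1.0 - s;
    double Vv = (tail ? -tail * std::log(om) : 0.0) + mu1 * I[0] -
                (Nj + 1.0) * std::log(s);
    double V3 = 2.0 * tail / (om * om * om) + mu1 * I[3] -
                2.0 * (Nj + 1.0) / (s * s * s);
    double V4 = 6.0 * tail / (om * om * om * om) + mu1 * I[4] +
                6.0 * (Nj + 1.0) / (s * s * s * s);
    double corr = 1.0 + V4 / (8.0 * Vpp * Vpp) -
                  5.0 * V3 * V3 / (24.0 * Vpp * Vpp * Vpp);
    if (!std::isfinite(corr)) corr = 1.0;
    if (corr < 0.2) corr = 0.2;
    if (corr > 2.0) corr = 2.0;
    s_star[j] = s; V[j] = Vv; V2[j] = Vpp;
    double lc0 = Vv - 0.5 * std::log(2.0 * M_PI * Vpp);
    logcoef0[j] = lc0;
    logcoef[j] = correction ? lc0 + std::log(corr) : lc0;
    corrv[j] = corr;
    iters[j] = it; conv[j] = ok ? 1 : 0;
  }
  return List::create(_["s_star"] = s_star, _["V"] = V, _["V2"] = V2,
                      _["log_coef"] = logcoef, _["log_coef0"] = logcoef0,
                      _["correction"] = corrv, _["iterations"] = iters,
                      _["converged"] = conv);
}

// V(s), V'(s), V''(s) at user-chosen s (diagnostics / tests)
// [[Rcpp::export]]
List V_profile_cpp(NumericVector par, NumericVector s, double t, double N,
                   int mode, double s0, int tail, double rtol, double atol) {
  const double mu1 = par[0];
  int n = s.size();
  NumericVector V(n), V1(n), V2(n);
  for (int i = 0; i < n; ++i) {
    double I[5];
    solve_scalar(par, s[i], t, mode, s0, rtol, atol, I);
    V[i] = -tail * std::log(1.0 - s[i]) + mu1 * I[0] - (N + 1.0) * std::log(s[i]);
    V1[i] = tail / (1.0 - s[i]) + mu1 * I[1] - (N + 1.0) / s[i];
    V2[i] = tail / ((1.0 - s[i]) * (1.0 - s[i])) + mu1 * I[2] + (N + 1.0) / (s[i] * s[i]);
  }
  return List::create(_["V"] = V, _["V1"] = V1, _["V2"] = V2);
}

// Does the single-ancestor ODE solution diverge before time t?  Used to
// locate the radius of convergence (Riccati blow-up point) by bisection.
// Solves the order-0 system so that only f itself (not its much
// faster-growing derivative states) defines divergence.
// [[Rcpp::export]]
bool pgf_diverges_cpp(NumericVector par, double s, double t, int mode,
                      double s0, double rtol, double atol) {
  PgfSys<double> sys(par, mode, s0, 0);
  sys.nodes.assign(1, s);
  std::vector<double> y;
  sys.init_state(y);
  std::vector<double> tout(1, t);
  std::vector<std::vector<double> > rec;
  return !rk45_integrate(sys, y, tout, rec, rtol, atol);
}
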