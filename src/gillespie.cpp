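// Stochastic simulation of the two-type branching process with immigration.
//
// Reactions (per-year rates):
//   0 -> A        mu1
//   A -> 2A       b1 * A
//   A -> 0        d1 * A
//   A -> M        mu2 * A     (an adenoma cell transforms)
//   M -> 2M       b2 * M
//   M -> 0        d2 * M
//
// Exact SSA below a per-compartment size threshold; above it, tau-leaping
// with Cao-style step selection (relative propensity change bounded by eps),
// keeping whichever compartment is still small on an exact sub-clock with
// the large compartment frozen during the leap.  All randomness goes
// through the R RNG so set.seed() gives bit-reproducible paths.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rpois_big(double lam) {
  if (lam <= 0.0) return 0.0;
  if (lam < 1e7) return R::rpois(lam);
  double x = std::floor(R::rnorm(lam, std::sqrt(lam)) + 0.5);
  return x > 0.0 ? x : 0.0;
}

static inline double rbinom_big(double n, double p) {
  if (n <= 0.0) return 0.0;
  if (n < 1e7) return R::rbinom(n, p);
  double m = n * p, s = std::sqrt(n * p * (1.0 - p));
  double x = std::floor(R::rnorm(m, s) + 0.5);
  if (x < 0.0) x = 0.0;
  if (x > n) x = n;
  return x;
}

struct TwoType {
  double mu1, b1, d1, mu2, b2, d2;
  double Ath, Mth, eps, tau_max;
  double A, M, t;
  double budget;  // remaining exact-event budget

  TwoType(const NumericVector& par, double Ath_, double Mth_, double eps_,
          double tau_max_, double budget_)
      : mu1(par[0]), b1(par[1]), d1(par[2]), mu2(par[3]), b2(par[4]), d2(par[5]),
        Ath(Ath_), Mth(Mth_), eps(eps_), tau_max(tau_max_),
        A(0.0), M(0.0), t(0.0), budget(budget_) {}

  // exact SSA until tend; if stop_at_threshold, return as soon as a
  // compartment reaches its leaping threshold
  void exact_until(double tend, bool stop_at_threshold) {
    while (t < tend) {
      double a1 = mu1, a2 = b1 * A, a3 = d1 * A, a4 = mu2 * A,
             a5 = b2 * M, a6 = d2 * M;
      double atot = a1 + a2 + a3 + a4 + a5 + a6;
      if (atot <= 0.0) { t = tend; return; }
      double dt = R::rexp(1.0 / atot);
      if (t + dt >= tend) { t = tend; return; }
      t += dt;
      if (--budget < 0)
        stop("exact event budget exceeded; use the hybrid (tau-leaping) simulator");
      double u = unif_rand() * atot;
      if ((u -= a1) < 0) A += 1;
      else if ((u -= a2) < 0) A += 1;
      else if ((u -= a3) < 0) A -= 1;
      else if ((u -= a4) < 0) { A -= 1; M += 1; }
      else if ((u -= a5) < 0) M += 1;
      else M -= 1;
      if (stop_at_threshold && (A >= Ath || M >= Mth)) return;
    }
  }

  void leap(double tend) {
    bool bigA = A >= Ath, bigM = M >= Mth;
    double tau = std::min(tau_max, tend - t);
    if (bigA) {
      double x = A > 1.0 ? A : 1.0;
      double dr = std::fabs(mu1 + (b1 - d1 - mu2) * A);
      double va = mu1 + (b1 + d1 + mu2) * A;
      if (dr > 0) tau = std::min(tau, eps * x / dr);
      if (va > 0) tau = std::min(tau, eps * eps * x * x / va);
    }
    if (bigM) {
      double x = M > 1.0 ? M : 1.0;
      double dr = std::fabs(mu2 * A + (b2 - d2) * M);
      double va = mu2 * A + (b2 + d2) * M;
      if (dr > 0) tau = std::min(tau, eps * x / dr);
      if (va > 0) tau = std::min(tau, eps * eps * x * x / va);
    }
    if (tau <= 0.0) tau = 1e-8;

    // Deterministic midpoint rates remove the O(tau) weak bias of
    // frozen-rate (Euler) tau-leaping, which otherwise compounds over the
    // many leaps of an exponentially growing compartment.  The seeding
    // exposure additionally uses the *realized* trapezoidal midpoint of A
    // within the leap so that the A-M correlation survives conditioning
    // on atypical A paths.
    double driftA = mu1 + (b1 - d1 - mu2) * A;
    double driftM = mu2 * A + (b2 - d2) * M;
    double Amid = A + 0.5 * tau * driftA; if (Amid < 0) Amid = 0;
    double Mmid = M + 0.5 * tau * driftM; if (Mmid < 0) Mmid = 0;

    double tau_eff = tau, seeds = 0.0;
    double ni = 0, nb = 0, nd = 0, A_end = A;
    if (bigA) {
      ni = rpois_big(mu1 * tau);
      nb = rpois_big(b1 * Amid * tau);
      nd = rpois_big(d1 * Amid * tau);
      A_end = A + ni + nb - nd; if (A_end < 0) A_end = 0;
    }
    double Aexp = bigA ? 0.5 * (A + A_end) : A;  // realized exposure
    if (!bigM) {
      // exact M sub-clock; A frozen at its realized midpoint
      double ts = 0.0;
      while (true) {
        double a4 = mu2 * Aexp, a5 = b2 * M, a6 = d2 * M;
        double at = a4 + a5 + a6;
        if (at <= 0.0) break;
        double dt = R::rexp(1.0 / at);
        if (ts + dt >= tau) break;
        ts += dt;
        double u = unif_rand() * at;
        if ((u -= a4) < 0) { M += 1; seeds += 1; }
        else if ((u -= a5) < 0) M += 1;
        else M -= 1;
        if (M >= Mth) { tau_eff = ts; break; }
      }
      if (bigA && tau_eff < tau) {
        // truncated leap: thin the A updates to the elapsed fraction
        double fr = tau_eff / tau;
        ni = rbinom_big(ni, fr); nb = rbinom_big(nb, fr);
        nd = rbinom_big(nd, fr);
        A_end = A + ni + nb - nd; if (A_end < 0) A_end = 0;
      }
    } else if (!bigA) {
      // exact A sub-clock with M frozen
      double ts = 0.0;
      while (true) {
        double a1 = mu1, a2 = b1 * A, a3 = d1 * A, a4 = mu2 * A;
        double at = a1 + a2 + a3 + a4;
        if (at <= 0.0) break;
        double dt = R::rexp(1.0 / at);
        if (ts + dt >= tau) break;
        ts += dt;
        double u = unif_rand() * at;
        if ((u -= a1) < 0) A += 1;
        else if ((u -= a2) < 0) A += 1;
        else if ((u -= a3) < 0) A -= 1;
        else { A -= 1; M += 1; }
        if (A >= Ath) { tau_eff = ts; break; }
      }
    }
    if (bigA) {
      double ns = bigM ? rpois_big(mu2 * Aexp * tau_eff) : seeds;
      A = A_end - ns;
      if (bigM) M += ns;
    }
    if (bigM) {
      double mb = rpois_big(b2 * Mmid * tau_eff);
      double md = rpois_big(d2 * Mmid * tau_eff);
      M += mb - md;
    }
    if (A < 0) A = 0;
    if (M < 0) M = 0;
    t += tau_eff;
  }

  void advance_hybrid(double tend) {
    while (t < tend - 1e-12) {
      if (A < Ath && M < Mth) exact_until(tend, true);
      else leap(tend);
    }
  }
};

// Exact Gillespie path recorded at the given (sorted) times.
// [[Rcpp::export]]
List gillespie_cpp(NumericVector par, NumericVector record_times,
                   double A0, double M0, double max_events) {
  TwoType st(par, R_PosInf, R_PosInf, 0.0, 0.0, max_events);
  st.A = A0; st.M = M0;
  int nt = record_times.size();
  NumericVector Av(nt), Mv(nt);
  for (int i = 0; i < nt; ++i) {
    st.exact_until(record_times[i], false);
    Av[i] = st.A; Mv[i] = st.M;
  }
  return List::create(_["A"] = Av, _["M"] = Mv,
                      _["events_used"] = max_events - st.budget);
}

// Hybrid (exact + tau-leap) paths: n individuals each assessed at one age.
// [[Rcpp::export]]
List hybrid_assess_cpp(NumericVector par, NumericVector assess_age,
                       double A_thresh, double M_thresh, double eps,
                       double tau_max) {
  int n = assess_age.size();
  NumericVector Av(n), Mv(n);
  for (int i = 0; i < n; ++i) {
    TwoType st(par, A_thresh, M_thresh, eps, tau_max, 1e15);
    st.advance_hybrid(assess_age[i]);
    Av[i] = st.A; Mv[i] = st.M;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["A"] = Av, _["M"] = Mv);
}

// Hybrid paths for n individuals recorded at every time in record_times.
// [[Rcpp::export]]
List hybrid_traj_cpp(NumericVector par, int n, NumericVector record_times,
                     double A_thresh, double M_thresh, double eps,
                     double tau_max) {
  int nt = record_times.size();
  NumericMatrix Am(n, nt), Mm(n, nt);
  for (int i = 0; i < n; ++i) {
    TwoType st(par, A_thresh, M_thresh, eps, tau_max, 1e15);
    for (int j = 0; j < nt; ++j) {
      st.advance_hybrid(record_times[j]);
      Am(i, j) = st.A; Mm(i, j) = st.M;
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["A"] = Am, _["M"] = Mm);
}
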