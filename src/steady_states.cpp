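// Steady-state enumeration for shifted-Hill regulatory ODEs.
//
// For each initial condition the trajectory is integrated with an adaptive
// Cash-Karp RK45 scheme until the scale-free residual max_i |dp_i| / (k_i
// |p_i|) drops below conv_tol (or the time budget runs out), the endpoint is
// polished by a damped Newton iteration on rhs = 0 with the analytic
// Jacobian, endpoints with any Jacobian eigenvalue real part above stab_tol
// are discarded as saddles, and the survivors are deduplicated in log2 space.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Circuit {
  vec g, k;              // per node basal production, degradation
  uvec src, tgt;         // per edge, 0-based node indices
  vec lam, mu;
  ivec nh;               // Hill coefficients
  int nn;                // node count
};

// shifted Hill factor: (1 + lam * r) / (1 + r), r = (p/mu)^n
inline double hs(double p, double mu, double lam, int n) {
  double r = std::pow(p / mu, n);
  if (!std::isfinite(r)) return lam;
  return (1.0 + lam * r) / (1.0 + r);
}

// d/dp of the shifted Hill factor, numerically safe at p = 0
inline double dhs(double p, double mu, double lam, int n) {
  double s = std::pow(p / mu, n - 1) / mu; // (p/mu)^(n-1) / mu
  if (!std::isfinite(s)) return 0.0;
  double r = s * p;                        // (p/mu)^n
  double d = 1.0 + r;
  return (lam - 1.0) * n * s / (d * d);
}

void rhs(const Circuit& c, const vec& p, vec& dp) {
  dp = c.g;
  for (uword e = 0; e < c.src.n_elem; ++e) {
    dp[c.tgt[e]] *= hs(p[c.src[e]], c.mu[e], c.lam[e], c.nh[e]);
  }
  dp -= c.k % p;
}

// production vector (rhs + k*p) and Jacobian
void jacobian(const Circuit& c, const vec& p, mat& J) {
  vec prod = c.g;
  for (uword e = 0; e < c.src.n_elem; ++e) {
    prod[c.tgt[e]] *= hs(p[c.src[e]], c.mu[e], c.lam[e], c.nh[e]);
  }
  J.zeros(c.nn, c.nn);
  J.diag() = -c.k;
  for (uword e = 0; e < c.src.n_elem; ++e) {
    uword i = c.tgt[e], j = c.src[e];
    double h = hs(p[j], c.mu[e], c.lam[e], c.nh[e]);
    J(i, j) += prod[i] * dhs(p[j], c.mu[e], c.lam[e], c.nh[e]) / h;
  }
}

double residual(const Circuit& c, const vec& p, const vec& dp) {
  double r = 0.0;
  for (int i = 0; i < c.nn; ++i) {
    double ri = std::abs(dp[i]) / (c.k[i] * (std::abs(p[i]) + 1e-300));
    if (ri > r) r = ri;
  }
  return r;
}

// Cash-Karp RK45 tableau
const double B21 = 1.0 / 5.0;
const double B31 = 3.0 / 40.0, B32 = 9.0 / 40.0;
const double B41 = 3.0 / 10.0, B42 = -9.0 / 10.0, B43 = 6.0 / 5.0;
const double B51 = -11.0 / 54.0, B52 = 5.0 / 2.0, B53 = -70.0 / 27.0,
             B54 = 35.0 / 27.0;
const double B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0,
             B63 = 575.0 / 13824.0, B64 = 44275.0 / 110592.0,
             B65 = 253.0 / 4096.0;
const double C1 = 37.0 / 378.0, C3 = 250.0 / 621.0, C4 = 125.0 / 594.0,
             C6 = 512.0 / 1771.0;
const double D1 = C1 - 2825.0 / 27648.0, D3 = C3 - 18575.0 / 48384.0,
             D4 = C4 - 13525.0 / 55296.0, D5 = -277.0 / 14336.0,
             D6 = C6 - 1.0 / 4.0;

bool newton_polish(const Circuit& c, vec& p, double newton_tol);
bool is_stable(const Circuit& c, const vec& p, double stab_tol);

// integrate one trajectory in place; returns true once the endpoint sits on
// a steady state meeting the residual criterion. When the residual falls
// below a trigger the endpoint is handed to Newton polishing early; a polish
// that lands on an unstable root (a saddle shadowed by the trajectory) is
// rolled back and integration continues.
bool integrate(const Circuit& c, vec& p, const vec& scale, double rtol,
               double conv_tol, double stab_tol, double tmax) {
  const int nn = c.nn;
  vec k1(nn), k2(nn), k3(nn), k4(nn), k5(nn), k6(nn), ptmp(nn), perr(nn),
      pnew(nn);
  double t = 0.0, h = 0.05;
  const double hmax = 5.0, hmin = 1e-10, clip = 1e-12;
  double trigger = 1e-3; // residual level at which Newton polishing is tried
  // stall detection: trajectories on limit cycles (or other non-convergent
  // sets) keep a bounded residual; abandon them early instead of spending
  // the whole time budget
  double res_min = 1e300, t_improve = 0.0;
  rhs(c, p, k1);
  long max_steps = 2000000;
  while (t < tmax && max_steps-- > 0) {
    double res = residual(c, p, k1);
    if (res < conv_tol) return true;
    if (res < 0.5 * res_min) {
      res_min = res;
      t_improve = t;
    } else if (res < res_min) {
      res_min = res;
    }
    if (t > 400.0 && t - t_improve > 200.0 && res > 10.0 * conv_tol) {
      return false; // stalled: treated as non-converged
    }
    if (res < trigger) {
      vec psave = p;
      if (newton_polish(c, p, 1e-9) && is_stable(c, p, stab_tol)) return true;
      p = psave;          // saddle or stalled polish: keep integrating
      rhs(c, p, k1);
      trigger = res * 0.1; // retry only once markedly closer
    }
    if (t + h > tmax) h = tmax - t;
    // stages
    ptmp = p + h * B21 * k1;
    ptmp.transform([&](double v) { return v < clip ? clip : v; });
    rhs(c, ptmp, k2);
    ptmp = p + h * (B31 * k1 + B32 * k2);
    ptmp.transform([&](double v) { return v < clip ? clip : v; });
    rhs(c, ptmp, k3);
    ptmp = p + h * (B41 * k1 + B42 * k2 + B43 * k3);
    ptmp.transform([&](double v) { return v < clip ? clip : v; });
    rhs(c, ptmp, k4);
    ptmp = p + h * (B51 * k1 + B52 * k2 + B53 * k3 + B54 * k4);
    ptmp.transform([&](double v) { return v < clip ? clip : v; });
    rhs(c, ptmp, k5);
    ptmp = p + h * (B61 * k1 + B62 * k2 + B63 * k3 + B64 * k4 + B65 * k5);
    ptmp.transform([&](double v) { return v < clip ? clip : v; });
    rhs(c, ptmp, k6);
    pnew = p + h * (C1 * k1 + C3 * k3 + C4 * k4 + C6 * k6);
    perr = h * (D1 * k1 + D3 * k3 + D4 * k4 + D5 * k5 + D6 * k6);
    // scaled error norm
    double err = 0.0;
    for (int i = 0; i < nn; ++i) {
      double sc = rtol * (std::abs(p[i]) + 1e-4 * scale[i]);
      double e = std::abs(perr[i]) / sc;
      if (e > err) err = e;
    }
    if (err <= 1.0) {
      t += h;
      p = pnew;
      p.transform([&](double v) { return v < clip ? clip : v; });
      rhs(c, p, k1);
      double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
      if (h > hmax) h = hmax;
    } else {
      double fac = 0.9 * std::pow(err, -0.25);
      h *= std::max(0.1, fac);
      if (h < hmin) return false; // step size underflow
    }
  }
  rhs(c, p, k1);
  return residual(c, p, k1) < conv_tol;
}

// damped Newton on rhs = 0; returns true on success (residual < newton_tol)
bool newton_polish(const Circuit& c, vec& p, double newton_tol) {
  vec f(c.nn), ftry(c.nn), step(c.nn), ptry(c.nn);
  mat J(c.nn, c.nn);
  rhs(c, p, f);
  double res = residual(c, p, f);
  for (int it = 0; it < 60; ++it) {
    if (res < newton_tol) return true;
    jacobian(c, p, J);
    bool ok = solve(step, J, -f, solve_opts::no_approx);
    if (!ok) return res < 1e-6;
    double damp = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 12; ++ls) {
      ptry = p + damp * step;
      ptry.transform([](double v) { return v < 1e-15 ? 1e-15 : v; });
      rhs(c, ptry, ftry);
      double rtry = residual(c, ptry, ftry);
      if (rtry < res) {
        p = ptry;
        f = ftry;
        res = rtry;
        improved = true;
        break;
      }
      damp *= 0.5;
    }
    if (!improved) break;
  }
  return res < newton_tol;
}

bool is_stable(const Circuit& c, const vec& p, double stab_tol) {
  mat J(c.nn, c.nn);
  jacobian(c, p, J);
  cx_vec ev;
  if (!eig_gen(ev, J)) return false;
  return real(ev).max() <= stab_tol;
}

} // namespace

//' @keywords internal
// [[Rcpp::export(name = ".cpp_find_states")]]
Rcpp::List cpp_find_states(Rcpp::NumericVector g, Rcpp::NumericVector k,
                           Rcpp::IntegerVector src, Rcpp::IntegerVector tgt,
                           Rcpp::NumericVector lambda, Rcpp::NumericVector mu,
                           Rcpp::IntegerVector nhill, Rcpp::NumericMatrix ics,
                           Rcpp::NumericVector scale, double rtol,
                           double conv_tol, double dedup_log2,
                           double stab_tol, double tmax) {
  Circuit c;
  c.g = vec(g.begin(), g.size());
  c.k = vec(k.begin(), k.size());
  c.nn = g.size();
  c.src = conv_to<uvec>::from(ivec(src.begin(), src.size()));
  c.tgt = conv_to<uvec>::from(ivec(tgt.begin(), tgt.size()));
  c.lam = vec(lambda.begin(), lambda.size());
  c.mu = vec(mu.begin(), mu.size());
  c.nh = ivec(nhill.begin(), nhill.size());
  vec sc(scale.begin(), scale.size());

  const int n_ics = ics.nrow();
  std::vector<vec> states;
  int n_converged = 0;
  for (int j = 0; j < n_ics; ++j) {
    vec p(c.nn);
    for (int i = 0; i < c.nn; ++i) p[i] = ics(j, i);
    if (!integrate(c, p, sc, rtol, conv_tol, stab_tol, tmax)) continue;
    newton_polish(c, p, 1e-9); // keep endpoint even if polish stalls early
    vec f(c.nn);
    rhs(c, p, f);
    if (residual(c, p, f) >= conv_tol) continue;
    ++n_converged;
    if (!is_stable(c, p, stab_tol)) continue;
    // dedup in log2 space against accepted states
    bool dup = false;
    vec lp = log2(p);
    for (const vec& s : states) {
      if (abs(lp - log2(s)).max() < dedup_log2) {
        dup = true;
        break;
      }
    }
    if (!dup) states.push_back(p);
  }
  Rcpp::NumericMatrix out(states.size(), c.nn);
  for (size_t r = 0; r < states.size(); ++r) {
    for (int i = 0; i < c.nn; ++i) out(r, i) = states[r][i];
  }
  return Rcpp::List::create(
      Rcpp::Named("states") = out,
      Rcpp::Named("n_converged") = n_converged,
      Rcpp::Named("conv_frac") = n_ics > 0 ? double(n_converged) / n_ics : 0.0);
}
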