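#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Wang-Buzsaki rate constants (per ms, V in mV).  The R-level
// rate_functions() mirrors these exactly; keep the two in sync.

static inline double vtrap(double x) {
  // x / (1 - exp(-x)) with its removable singularity at x = 0
  if (std::fabs(x) < 1e-7) return 1.0;
  return x / (-std::expm1(-x));
}

static inline double alpha_m(double v) { return vtrap(0.1 * (v + 35.0)); }
static inline double beta_m(double v)  { return 4.0 * std::exp(-(v + 60.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 58.0) / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (std::exp(-0.1 * (v + 28.0)) + 1.0); }
static inline double alpha_n(double v) { return 0.1 * vtrap(0.1 * (v + 34.0)); }
static inline double beta_n(double v)  { return 0.125 * std::exp(-(v + 44.0) / 80.0); }

struct Params {
  double cm, gna, ena, gk, ek, gl, el, phi, esyn;
};

static inline void deriv(double v, double h, double n, double gsyn,
                         double iapp, const Params &p,
                         double &dv, double &dh, double &dn) {
  double am = alpha_m(v), bm = beta_m(v);
  double minf = am / (am + bm);
  double ina = p.gna * minf * minf * minf * h * (v - p.ena);
  double ik  = p.gk * n * n * n * n * (v - p.ek);
  double il  = p.gl * (v - p.el);
  double isyn = gsyn * (v - p.esyn);
  dv = (-ina - ik - il - isyn + iapp) / p.cm;
  dh = p.phi * (alpha_h(v) * (1.0 - h) - beta_h(v) * h);
  dn = p.phi * (alpha_n(v) * (1.0 - n) - beta_n(v) * n);
}

// Fixed-step RK4.  gsyn_half and iapp_half are sampled on the half grid
// t_k = k*dt/2, k = 0..2*nsteps, so mid-step values are exact samples.
// [[Rcpp::export(name = ".rk4_integrate")]]
List rk4_integrate(NumericVector gsyn_half, NumericVector iapp_half,
                   double dt, int nsteps,
                   double v0, double h0, double n0,
                   double cm, double gna, double ena,
                   double gk, double ek, double gl, double el,
                   double phi, double esyn) {
  if (gsyn_half.size() != 2 * nsteps + 1 || iapp_half.size() != 2 * nsteps + 1)
    stop("drive vectors must have length 2*nsteps + 1");
  Params p = {cm, gna, ena, gk, ek, gl, el, phi, esyn};

  NumericVector V(nsteps + 1), H(nsteps + 1), N(nsteps + 1);
  double v = v0, h = h0, n = n0;
  V[0] = v; H[0] = h; N[0] = n;
  bool ok = true;
  double t_fail = NA_REAL;

  double k1v, k1h, k1n, k2v, k2h, k2n, k3v, k3h, k3n, k4v, k4h, k4n;
  for (int i = 0; i < nsteps; ++i) {
    double g1 = gsyn_half[2 * i], g2 = gsyn_half[2 * i + 1],
           g4 = gsyn_half[2 * i + 2];
    double a1 = iapp_half[2 * i], a2 = iapp_half[2 * i + 1],
           a4 = iapp_half[2 * i + 2];
    deriv(v, h, n, g1, a1, p, k1v, k1h, k1n);
    deriv(v + 0.5 * dt * k1v, h + 0.5 * dt * k1h, n + 0.5 * dt * k1n,
          g2, a2, p, k2v, k2h, k2n);
    deriv(v + 0.5 * dt * k2v, h + 0.5 * dt * k2h, n + 0.5 * dt * k2n,
          g2, a2, p, k3v, k3h, k3n);
    deriv(v + dt * k3v, h + dt * k3h, n + dt * k3n,
          g4, a4, p, k4v, k4h, k4n);
    v += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    h += dt / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h);
    n += dt / 6.0 * (k1n + 2.0 * k2n + 2.0 * k3n + k4n);
    if (!std::isfinite(v) || !std::isfinite(h) || !std::isfinite(n)) {
      ok = false;
      t_fail = (i + 1) * dt;
      for (int j = i + 1; j <= nsteps; ++j) {
        V[j] = NA_REAL; H[j] = NA_REAL; N[j] = NA_REAL;
      }
      break;
    }
    V[i + 1] = v; H[i + 1] = h; N[i + 1] = n;
  }
  return List::create(_["v"] = V, _["h"] = H, _["n"] = N,
                      _["ok"] = ok, _["t_fail"] = t_fail);
}
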