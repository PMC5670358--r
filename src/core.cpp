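// Fixed-step RK4 integrator for the coupled clock / source-leaf / phloem /
// sink system.  The state layout, the functional forms of beta(phi), Z_S(phi)
// and f_S, and the upwind advection scheme are mirrored 1:1 by the R reference
// implementation in R/derivatives.R; the two are held equal by the test suite.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// state indices ------------------------------------------------------------
// 0  phi            circadian phase (h, wrapped to [0,24))
// 1  S_G            source sucrose (umolC6 / gFW)
// 2  C              source starch  (umolC6 / gFW)
// 3..8  g0..g5      phloem concentrations (umolC6 / volume unit)
// 9  S_Y (SAM)      10 S_Y (RAM)   sink sucrose (umolC6 / gFW)
// 11 W (SAM)        12 W (RAM)     sink fresh biomass (gFW)
// 13..17 cumulative bookkeeping integrals (source respiration, sink
//        respiration, growth consumption, phloem loading, phloem unloading)
const int NS = 18;
const int parent_of[6] = {-1, 0, 1, 1, 2, 3};

// below this starch level the degradation power law C^kappa is linearized
// (C^kappa has unbounded slope at 0 for kappa < 1, which would destabilize
// the fixed-step integrator as the reserve empties)
const double STARCH_EPS = 0.2;

struct ModelP {
  double omega, phi_star, Z_amp, fS_K, fS_n;
  bool sugar_on;
  double a, gamma_, h_G, eta_G, kappa, beta_min, beta_max, beta_shape_day, beta_shape_night;
  double eta_Y, h_Y, alpha_max, n_tilde, K_tilde, lambda, lin_slope;
  bool linear_growth;
  double V[6];
  double keps[5];  // hydraulic conductance x van 't Hoff coefficient, edge e -> node e+1
  bool freeze_sink;
};

inline double pospart(double x) { return x > 0.0 ? x : 0.0; }

// clock-gated starch degradation rate: shaped piecewise half-cosine with the
// peak at dawn (phi = 0/24) and the trough at the subjective dusk phi*.
// Each branch is a half-cosine ramp u in [0,1] (1 at dawn, 0 at the trough)
// raised to a branch-specific exponent: a large day exponent holds the rate
// near the trough through the subjective day, a night exponent < 1 lifts it
// quickly after dusk (both 1 recovers the plain half-cosine).
inline double beta_of(double phi, const ModelP& p) {
  double u, m;
  if (phi <= p.phi_star) {
    u = 0.5 * (1.0 + std::cos(M_PI * phi / p.phi_star));
    m = p.beta_shape_day;
  } else {
    u = 0.5 * (1.0 - std::cos(M_PI * (phi - p.phi_star) / (24.0 - p.phi_star)));
    m = p.beta_shape_night;
  }
  return p.beta_min + (p.beta_max - p.beta_min) * std::pow(u, m);
}

// sucrose phase-response curve: sine lobe, advance before phi*, delay after
inline double prc_of(double phi, const ModelP& p) {
  if (phi <= p.phi_star) return p.Z_amp * std::sin(M_PI * phi / p.phi_star);
  return -p.Z_amp * std::sin(M_PI * (phi - p.phi_star) / (24.0 - p.phi_star));
}

// signed Hill transform of the sucrose rate of change
inline double hill_signed(double x, double K, double n) {
  if (x == 0.0) return 0.0;
  double ax = std::pow(std::fabs(x), n);
  double v = ax / (std::pow(K, n) + ax);
  return x > 0.0 ? v : -v;
}

inline double alpha_of(double SY, const ModelP& p) {
  if (SY <= 0.0) return 0.0;
  if (p.linear_growth) return p.lin_slope * SY;
  double sn = std::pow(SY, p.n_tilde);
  return p.alpha_max * sn / (std::pow(p.K_tilde, p.n_tilde) + sn);
}

void deriv(const double* y, bool light, const ModelP& p, double* dy) {
  const double phi = y[0], SG = y[1], C = y[2];
  // degradation stops at zero starch; the power law is linearized below
  // STARCH_EPS to keep the right-hand side Lipschitz at the exhaustion point
  double degr = 0.0;
  if (C >= STARCH_EPS)
    degr = beta_of(phi, p) * std::pow(C, p.kappa);
  else if (C > 0.0)
    degr = beta_of(phi, p) * std::pow(STARCH_EPS, p.kappa) * (C / STARCH_EPS);
  const double aL = light ? p.a : 0.0;
  const double dSG = aL * (1.0 - p.gamma_) + degr - (p.h_G + p.eta_G) * SG;
  const double dC = aL * p.gamma_ - degr;
  const double fs = (light && p.sugar_on) ? hill_signed(dSG, p.fS_K, p.fS_n) : 0.0;
  dy[0] = p.omega + prc_of(phi, p) * fs;
  dy[1] = dSG;
  dy[2] = dC;

  const double* g = y + 3;
  double J[5];
  for (int e = 0; e < 5; ++e)
    J[e] = p.keps[e] * (g[parent_of[e + 1]] - g[e + 1]);

  double dg[6];
  dg[0] = p.eta_G * SG + g[1] * pospart(-J[0]) - g[0] * pospart(J[0]);
  for (int i = 1; i <= 3; ++i) {
    const double Ji = J[i - 1];
    double acc = g[parent_of[i]] * pospart(Ji) - g[i] * pospart(-Ji);
    for (int c = 1; c <= 5; ++c)
      if (parent_of[c] == i) {
        const double Jc = J[c - 1];
        acc -= g[i] * pospart(Jc) - g[c] * pospart(-Jc);
      }
    dg[i] = acc;
  }
  for (int i = 4; i <= 5; ++i) {
    const double Ji = J[i - 1];
    dg[i] = g[parent_of[i]] * pospart(Ji) - g[i] * (pospart(-Ji) + p.eta_Y);
  }
  for (int i = 0; i < 6; ++i) dy[3 + i] = dg[i] / p.V[i];

  const double a4 = alpha_of(y[9], p), a5 = alpha_of(y[10], p);
  if (p.freeze_sink) {
    dy[9] = 0.0;
    dy[10] = 0.0;
  } else {
    dy[9] = p.eta_Y * g[4] - p.h_Y * y[9] - a4;
    dy[10] = p.eta_Y * g[5] - p.h_Y * y[10] - a5;
  }
  dy[11] = p.lambda * a4 * y[11];
  dy[12] = p.lambda * a5 * y[12];

  dy[13] = p.h_G * SG;
  dy[14] = p.h_Y * (y[9] + y[10]);
  dy[15] = a4 + a5;
  dy[16] = p.eta_G * SG;
  dy[17] = p.eta_Y * (g[4] + g[5]);
}

ModelP unpack(const List& pars) {
  ModelP p;
  p.omega = as<double>(pars["omega"]);
  p.phi_star = as<double>(pars["phi_star"]);
  p.Z_amp = as<double>(pars["Z_amplitude"]);
  p.fS_K = as<double>(pars["fS_K"]);
  p.fS_n = as<double>(pars["fS_n"]);
  p.sugar_on = as<bool>(pars["sugar_response"]);
  p.a = as<double>(pars["a"]);
  p.gamma_ = as<double>(pars["gamma"]);
  p.h_G = as<double>(pars["h_G"]);
  p.eta_G = as<double>(pars["eta_G"]);
  p.kappa = as<double>(pars["kappa"]);
  p.beta_min = as<double>(pars["beta_min"]);
  p.beta_max = as<double>(pars["beta_max"]);
  p.beta_shape_day = as<double>(pars["beta_shape_day"]);
  p.beta_shape_night = as<double>(pars["beta_shape_night"]);
  p.eta_Y = as<double>(pars["eta_Y"]);
  p.h_Y = as<double>(pars["h_Y"]);
  p.alpha_max = as<double>(pars["alpha_max"]);
  p.n_tilde = as<double>(pars["n_tilde"]);
  p.K_tilde = as<double>(pars["K_tilde"]);
  p.lambda = as<double>(pars["lambda"]);
  p.lin_slope = as<double>(pars["linear_slope"]);
  p.linear_growth = as<bool>(pars["linear_growth"]);
  p.freeze_sink = as<bool>(pars["freeze_sink"]);
  NumericVector V = pars["V"], keps = pars["keps"];
  if (V.size() != 6 || keps.size() != 5) stop("V must have 6 entries and keps 5");
  for (int i = 0; i < 6; ++i) p.V[i] = V[i];
  for (int e = 0; e < 5; ++e) p.keps[e] = keps[e];
  return p;
}

const char* state_name(int i) {
  static const char* nm[NS] = {"phi",     "S_G",      "C",        "g0",     "g1",
                               "g2",      "g3",       "g4",       "g5",     "S_Y_sam",
                               "S_Y_ram", "W_sam",    "W_ram",    "resp_source",
                               "resp_sink", "consumed_growth", "loaded", "unloaded"};
  return nm[i];
}

}  // namespace

//' @useDynLib phloemclock, .registration = TRUE
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector y0, List pars, NumericVector photoperiods, double dt,
              int record_stride) {
  if (y0.size() != NS) stop("state vector must have %d entries", NS);
  ModelP p = unpack(pars);
  const int ndays = photoperiods.size();
  const long spd = std::lround(24.0 / dt);
  if (spd <= 0 || std::fabs(spd * dt - 24.0) > 1e-9)
    stop("rk4 step must divide 24 h evenly");
  if (record_stride < 1 || spd % record_stride != 0)
    stop("record stride must divide the steps per day");
  std::vector<long> dusk_step(ndays);
  for (int d = 0; d < ndays; ++d) {
    const double tl = photoperiods[d];
    if (!(tl > 0.0 && tl <= 24.0)) stop("photoperiod must lie in (0, 24]");
    const long ds = std::lround(tl / dt);
    if (std::fabs(ds * dt - tl) > 1e-9) stop("photoperiod must be a multiple of the rk4 step");
    dusk_step[d] = (long)d * spd + ds;
  }
  const long nsteps = spd * (long)ndays;
  const int nrec = (int)(nsteps / record_stride) + 1;

  std::vector<double> y(y0.begin(), y0.end());
  NumericMatrix out(nrec, NS + 2);
  long clamps = 0;
  int row = 0;
  double k1[NS], k2[NS], k3[NS], k4[NS], tmp[NS];

  for (long s = 0; s <= nsteps; ++s) {
    int d = (int)(s / spd);
    if (d >= ndays) d = ndays - 1;
    // light transitions sit exactly on step boundaries; resets fire before the step
    if (s < nsteps) {
      if (s % spd == 0)
        y[0] = 0.0;  // dawn
      else if (s == dusk_step[d])
        y[0] = photoperiods[d];  // dusk
    }
    const bool light = (s >= (long)d * spd) && (s < dusk_step[d]);
    if (s % record_stride == 0) {
      out(row, 0) = s * dt;
      out(row, 1) = light ? 1.0 : 0.0;
      for (int i = 0; i < NS; ++i) out(row, 2 + i) = y[i];
      ++row;
    }
    if (s == nsteps) break;

    deriv(y.data(), light, p, k1);
    for (int i = 0; i < NS; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    deriv(tmp, light, p, k2);
    for (int i = 0; i < NS; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    deriv(tmp, light, p, k3);
    for (int i = 0; i < NS; ++i) tmp[i] = y[i] + dt * k3[i];
    deriv(tmp, light, p, k4);
    for (int i = 0; i < NS; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // wrap the phase and guard tiny negative pools produced by the fixed step
    y[0] -= 24.0 * std::floor(y[0] / 24.0);
    if (y[0] >= 24.0) y[0] = 0.0;
    for (int i = 1; i <= 10; ++i) {
      if (y[i] < 0.0) {
        if (y[i] < -1e-9) ++clamps;
        y[i] = 0.0;
      }
    }
    for (int i = 0; i < NS; ++i)
      if (!std::isfinite(y[i]))
        stop("non-finite state in component '%s' at t = %g h", state_name(i),
             (s + 1) * dt);
  }

  return List::create(_["states"] = out, _["clamps"] = (double)clamps);
}
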