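// Compiled hot loop: fixed-step RK4 for the Huber-Braun vector field with
// optional sinusoidal forcing, plus online spike detection, the adaptive
// settle/verdict kernel used by continuation sweeps, and the Benettin
// two-trajectory maximum-Lyapunov estimator.  Everything here is
// deterministic; there is no RNG anywhere in this file.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

struct HBPar {
  double Cm, gl, gd, gr, gsd, gsr;
  double Vl, Vd, Vr, Vsd, Vsr;
  double taur, tausd, tausr;
  double sd_, sr_, ssd;
  double V0d, V0r, V0sd;
  double eta, theta, rho, phi;
};

static HBPar unpack(const NumericVector& pv) {
  HBPar p;
  p.Cm = pv["C_m"];
  p.gl = pv["g_l"]; p.gd = pv["g_d"]; p.gr = pv["g_r"];
  p.gsd = pv["g_sd"]; p.gsr = pv["g_sr"];
  p.Vl = pv["V_l"]; p.Vd = pv["V_d"]; p.Vr = pv["V_r"];
  p.Vsd = pv["V_sd"]; p.Vsr = pv["V_sr"];
  p.taur = pv["tau_r"]; p.tausd = pv["tau_sd"]; p.tausr = pv["tau_sr"];
  p.sd_ = pv["s_d"]; p.sr_ = pv["s_r"]; p.ssd = pv["s_sd"];
  p.V0d = pv["V0_d"]; p.V0r = pv["V0_r"]; p.V0sd = pv["V0_sd"];
  p.eta = pv["eta"]; p.theta = pv["theta"];
  p.rho = pv["rho"]; p.phi = pv["phi"];
  return p;
}

// Right-hand side.  a_d is the instantaneous sigmoid of V; only
// (V, a_r, a_sd, a_sr) are state variables.
static inline void hb_deriv(const HBPar& p, const double s[4], double Iext,
                            double out[4]) {
  const double V = s[0], ar = s[1], asd = s[2], asr = s[3];
  const double ad     = 1.0 / (1.0 + std::exp(-p.sd_ * (V - p.V0d)));
  const double arinf  = 1.0 / (1.0 + std::exp(-p.sr_ * (V - p.V0r)));
  const double asdinf = 1.0 / (1.0 + std::exp(-p.ssd * (V - p.V0sd)));
  const double Il  = p.gl * (V - p.Vl);
  const double Id  = p.rho * p.gd * ad * (V - p.Vd);
  const double Ir  = p.rho * p.gr * ar * (V - p.Vr);
  const double Isd = p.rho * p.gsd * asd * (V - p.Vsd);
  const double Isr = p.rho * p.gsr * asr * (V - p.Vsr);
  out[0] = -(Il + Id + Ir + Isd + Isr + Iext) / p.Cm;
  out[1] = p.phi * (arinf - ar) / p.taur;
  out[2] = p.phi * (asdinf - asd) / p.tausd;
  out[3] = p.phi * (-p.eta * Isd - p.theta * asr) / p.tausr;
}

static inline double forcing(double t, double I0, double B, double omega,
                             double phase0) {
  return I0 * (1.0 + B * std::sin(omega * t + phase0));
}

// Classical RK4 with the time-dependent forcing evaluated at t, t+dt/2, t+dt.
static inline void rk4(const HBPar& p, double t, double dt, double s[4],
                       double I0, double B, double omega, double phase0) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  const double I1 = forcing(t, I0, B, omega, phase0);
  const double I2 = forcing(t + 0.5 * dt, I0, B, omega, phase0);
  const double I3 = forcing(t + dt, I0, B, omega, phase0);
  hb_deriv(p, s, I1, k1);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  hb_deriv(p, tmp, I2, k2);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  hb_deriv(p, tmp, I2, k3);
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + dt * k3[i];
  hb_deriv(p, tmp, I3, k4);
  for (int i = 0; i < 4; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Integrate n_transient + n_measure steps from t = 0.  During the measured
// span, record every `stride`-th sample (stride <= 0 disables recording;
// the transient-end sample is always sample 0 when recording) and optionally
// detect upward threshold crossings with linear interpolation and a
// refractory guard.  Times are reported from the start of the run, so the
// first recorded time equals n_transient * dt.
// [[Rcpp::export]]
List hb_run_cpp(NumericVector state0, NumericVector pv,
                double I0, double B, double omega, double phase0,
                double dt, double n_transient, double n_measure,
                int stride, bool detect, double threshold, double refractory) {
  HBPar p = unpack(pv);
  double s[4] = {state0[0], state0[1], state0[2], state0[3]};
  const long long ntr = (long long)(n_transient + 0.5);
  const long long nme = (long long)(n_measure + 0.5);
  for (long long i = 0; i < ntr; ++i) {
    rk4(p, i * dt, dt, s, I0, B, omega, phase0);
    if (!std::isfinite(s[0]))
      stop("integration blow-up at t = %g ms", (i + 1) * dt);
  }
  const long long nrec = (stride > 0) ? nme / stride + 1 : 0;
  NumericVector T(nrec), V(nrec), AR(nrec), ASD(nrec), ASR(nrec), IE(nrec);
  std::vector<double> spikes;
  const double t0 = ntr * dt;
  if (stride > 0) {
    T[0] = t0; V[0] = s[0]; AR[0] = s[1]; ASD[0] = s[2]; ASR[0] = s[3];
    IE[0] = forcing(t0, I0, B, omega, phase0);
  }
  double vprev = s[0], last_spike = -1e300;
  long long j = 1;
  for (long long i = 0; i < nme; ++i) {
    const double t = (ntr + i) * dt;
    rk4(p, t, dt, s, I0, B, omega, phase0);
    if (!std::isfinite(s[0]))
      stop("integration blow-up at t = %g ms", t + dt);
    if (detect && vprev < threshold && s[0] >= threshold) {
      const double tc = t + dt * (threshold - vprev) / (s[0] - vprev);
      if (tc - last_spike >= refractory) {
        spikes.push_back(tc);
        last_spike = tc;
      }
    }
    vprev = s[0];
    if (stride > 0 && (i + 1) % stride == 0 && j < nrec) {
      const double tnew = t + dt;
      T[j] = tnew; V[j] = s[0]; AR[j] = s[1]; ASD[j] = s[2]; ASR[j] = s[3];
      IE[j] = forcing(tnew, I0, B, omega, phase0);
      ++j;
    }
  }
  return List::create(
      _["t"] = T, _["V"] = V, _["a_r"] = AR, _["a_sd"] = ASD,
      _["a_sr"] = ASR, _["i_ext"] = IE,
      _["end_state"] = NumericVector::create(s[0], s[1], s[2], s[3]),
      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}

// Constant-current residence with early verdicts, used by continuation
// sweeps.  Near a Hopf bifurcation the escape rate from the fixed point can
// be ~1e-6/ms, so a fixed residence either misses the bifurcation or wastes
// enormous time on clearly stable points.  Verdicts:
//   "spiking"   -- spike_target threshold crossings seen;
//   "quiescent" -- after t_settle, the block-wise V amplitude (max-min over
//                  t_block) has decreased for two consecutive blocks and is
//                  below spike size: a contracting subthreshold oscillation;
//   "undetermined" -- t_max reached with neither (amplitude still growing).
// [[Rcpp::export]]
List hb_settle_cpp(NumericVector state0, NumericVector pv, double I0,
                   double dt, double t_settle, double t_block, double t_max,
                   int spike_target, double threshold, double refractory) {
  HBPar p = unpack(pv);
  double s[4] = {state0[0], state0[1], state0[2], state0[3]};
  const long long nset = (long long)(t_settle / dt + 0.5);
  const long long nblk = (long long)(t_block / dt + 0.5);
  const long long nmax = (long long)(t_max / dt + 0.5);
  std::vector<double> spikes;
  double vprev = s[0], last_spike = -1e300;
  double amp_prev = R_PosInf;
  int decreasing = 0;
  double blk_max = -1e300, blk_min = 1e300;
  std::string verdict = "undetermined";
  long long i = 0;
  for (; i < nmax; ++i) {
    rk4(p, i * dt, dt, s, I0, 0.0, 0.0, 0.0);
    if (!std::isfinite(s[0]))
      stop("integration blow-up at t = %g ms", (i + 1) * dt);
    if (vprev < threshold && s[0] >= threshold) {
      const double tc = i * dt + dt * (threshold - vprev) / (s[0] - vprev);
      if (tc - last_spike >= refractory) {
        spikes.push_back(tc);
        last_spike = tc;
      }
    }
    vprev = s[0];
    if (s[0] > blk_max) blk_max = s[0];
    if (s[0] < blk_min) blk_min = s[0];
    if ((int)spikes.size() >= spike_target) {
      verdict = "spiking";
      ++i;
      break;
    }
    if ((i + 1) % nblk == 0 && i >= nset) {
      const double amp = blk_max - blk_min;
      if (amp < amp_prev) {
        if (++decreasing >= 2 && amp < 30.0) {
          verdict = "quiescent";
          ++i;
          break;
        }
      } else {
        decreasing = 0;
      }
      amp_prev = amp;
      blk_max = -1e300;
      blk_min = 1e300;
    }
  }
  return List::create(
      _["verdict"] = verdict,
      _["end_state"] = NumericVector::create(s[0], s[1], s[2], s[3]),
      _["t_used"] = i * dt,
      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}

// Benettin two-trajectory maximum Lyapunov exponent.  The companion is
// offset by delta0 along V (in the scaled norm), both trajectories are
// advanced with identical forcing, and the companion is renormalized back
// to separation delta0 every renorm_steps steps.  The norm rescales V by
// v_scale so that millivolts and dimensionless activations are comparable.
// [[Rcpp::export]]
List hb_lyapunov_cpp(NumericVector state0, NumericVector pv,
                     double I0, double B, double omega, double phase0,
                     double dt, double n_transient, double n_accum,
                     int renorm_steps, double delta0, double v_scale) {
  HBPar p = unpack(pv);
  double x[4] = {state0[0], state0[1], state0[2], state0[3]};
  const long long ntr = (long long)(n_transient + 0.5);
  const long long nac = (long long)(n_accum + 0.5);
  for (long long i = 0; i < ntr; ++i) {
    rk4(p, i * dt, dt, x, I0, B, omega, phase0);
    if (!std::isfinite(x[0]))
      stop("integration blow-up at t = %g ms", (i + 1) * dt);
  }
  double y[4] = {x[0] + delta0 / v_scale, x[1], x[2], x[3]};
  const long long nren = nac / renorm_steps;
  if (nren < 1) stop("accumulation span shorter than one renormalization");
  std::vector<double> trace(nren);
  double sumlog = 0.0;
  long long step = ntr;
  for (long long r = 0; r < nren; ++r) {
    for (int k = 0; k < renorm_steps; ++k) {
      const double t = step * dt;
      rk4(p, t, dt, x, I0, B, omega, phase0);
      rk4(p, t, dt, y, I0, B, omega, phase0);
      ++step;
    }
    const double d0 = (y[0] - x[0]) * v_scale;
    const double d1 = y[1] - x[1], d2 = y[2] - x[2], d3 = y[3] - x[3];
    const double d = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2 + d3 * d3);
    if (d <= 0.0)
      stop("trajectory separation collapsed below machine precision; "
           "decrease renorm_interval");
    sumlog += std::log(d / delta0);
    const double f = delta0 / d;
    for (int i = 0; i < 4; ++i) y[i] = x[i] + (y[i] - x[i]) * f;
    trace[r] = sumlog / ((r + 1.0) * renorm_steps * dt);
  }
  return List::create(
      _["lambda"] = sumlog / ((double)nren * renorm_steps * dt),
      _["log_stretch"] = NumericVector(trace.begin(), trace.end()),
      _["n_renorm"] = (double)nren);
}
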