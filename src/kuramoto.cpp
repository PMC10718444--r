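#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// wrap an angle to (-pi, pi]
static inline double wrap_pi(double a) {
  const double twopi = 2.0 * M_PI;
  a = std::fmod(a, twopi);
  if (a <= -M_PI) a += twopi;
  else if (a > M_PI) a -= twopi;
  return a;
}

// Explicit-Euler integration of the coupled Kuramoto population
//
//   dtheta_i/dt = omega_i + gamma*rho*sin(psi - theta_i) + I*X(t)*Z(theta_i)
//
// with Z(theta) = -sin(theta + prc_offset).  The mean-field drift is the
// exact O(N) form of the pairwise coupling sum (identical arithmetic up to
// the order parameter factorization); set pairwise = true to force the
// O(N^2) double sum (used only in equivalence tests).
//
// The inner loop evaluates one sin/cos pair per oscillator per step and
// expands sin(psi - theta_i) and Z(theta_i) by angle addition; the order
// parameter after a step is reused as the "current" one of the next step.
//
// Phase-locked stimulation: when stim_on, a rectangular pulse of
// pulse_steps integration steps is triggered each time the population mean
// phase psi crosses psi_target in the direction of phase advance, with at
// least refractory_steps steps between consecutive pulse onsets.
//
// Returns the per-step mean phase-coherence rho (after each step), the
// final phases, and the number of pulses delivered.
// [[Rcpp::export]]
List kuramoto_integrate_cpp(NumericVector phases, NumericVector omegas,
                            double dt, double gamma, double intensity,
                            double prc_offset, int n_steps,
                            bool stim_on, double psi_target,
                            int pulse_steps, int refractory_steps,
                            bool pairwise = false,
                            bool record_psi = false) {
  const int n = phases.size();
  if (n < 1) stop("empty oscillator population");
  std::vector<double> th(phases.begin(), phases.end());
  std::vector<double> cth(n), sth(n);
  NumericVector rho_trace(n_steps);
  NumericVector psi_trace(record_psi ? n_steps : 0);

  const double c_off = std::cos(prc_offset), s_off = std::sin(prc_offset);

  // state of the pulse generator
  int pulse_left = 0;                  // remaining steps of current pulse
  int since_onset = refractory_steps;  // steps since last pulse onset
  int n_pulses = 0;

  double sc = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) {
    cth[i] = std::cos(th[i]); sth[i] = std::sin(th[i]);
    sc += cth[i]; ss += sth[i];
  }
  double rx = sc / n, ry = ss / n;
  double rho = std::sqrt(rx * rx + ry * ry);
  double psi = std::atan2(ry, rx);
  double d_prev = wrap_pi(psi - psi_target);

  std::vector<double> dth(n);

  for (int s = 0; s < n_steps; ++s) {
    bool x_t = false;
    if (stim_on) {
      if (pulse_left > 0) {
        x_t = true;
      } else if (since_onset >= refractory_steps) {
        // crossing of psi_target in the direction of phase advance: the
        // wrapped distance d = psi - psi_target passes through 0 from
        // below without a branch jump
        double d_now = wrap_pi(psi - psi_target);
        if (d_prev < 0.0 && d_now >= 0.0 && (d_now - d_prev) < M_PI) {
          x_t = true;
          pulse_left = pulse_steps;
          since_onset = 0;
          ++n_pulses;
        }
      }
      d_prev = wrap_pi(psi - psi_target);
    }

    if (pairwise) {
      for (int i = 0; i < n; ++i) {
        double cpl = 0.0;
        for (int j = 0; j < n; ++j) cpl += std::sin(th[j] - th[i]);
        dth[i] = omegas[i] + (gamma / n) * cpl;
      }
    } else {
      // sin(psi - th) = sin(psi)cos(th) - cos(psi)sin(th)
      const double gs = gamma * rho * std::sin(psi);
      const double gc = gamma * rho * std::cos(psi);
      for (int i = 0; i < n; ++i)
        dth[i] = omegas[i] + gs * cth[i] - gc * sth[i];
    }
    if (x_t) {
      // Z(th) = -sin(th + off) = -(sin(th)cos(off) + cos(th)sin(off))
      for (int i = 0; i < n; ++i)
        dth[i] -= intensity * (sth[i] * c_off + cth[i] * s_off);
    }
    sc = 0.0; ss = 0.0;
    for (int i = 0; i < n; ++i) {
      th[i] = wrap_pi(th[i] + dth[i] * dt);
      cth[i] = std::cos(th[i]); sth[i] = std::sin(th[i]);
      sc += cth[i]; ss += sth[i];
    }

    if (x_t) --pulse_left;
    ++since_onset;

    // order parameter after the step: the recorded control signal, and
    // the current state for the next step's drift and trigger
    rx = sc / n; ry = ss / n;
    rho = std::sqrt(rx * rx + ry * ry);
    psi = std::atan2(ry, rx);
    rho_trace[s] = rho;
    if (record_psi) psi_trace[s] = psi;
  }

  NumericVector out_phases(n);
  for (int i = 0; i < n; ++i) out_phases[i] = th[i];
  List out = List::create(_["phases"] = out_phases,
                          _["rho"] = rho_trace,
                          _["n_pulses"] = n_pulses);
  if (record_psi) out["psi"] = psi_trace;
  return out;
}
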