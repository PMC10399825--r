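#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-order activation dynamics with excitation held constant per step.
// du/dt = e/tau - lambda(e) * u,  lambda = (beta + (1-beta) e)/tau.
static inline double act_step_rk4(double u, double e, double dt,
                                  double tau, double beta) {
  const double lam = (beta + (1.0 - beta) * e) / tau;
  const double c = e / tau;
  const double k1 = c - lam * u;
  const double k2 = c - lam * (u + 0.5 * dt * k1);
  const double k3 = c - lam * (u + 0.5 * dt * k2);
  const double k4 = c - lam * (u + dt * k3);
  return u + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

static inline double act_step_exact(double u, double e, double dt,
                                    double tau, double beta) {
  const double lam = (beta + (1.0 - beta) * e) / tau;
  const double uss = e / (tau * lam);  // steady state for constant e
  return uss + (u - uss) * std::exp(-lam * dt);
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export]]
NumericVector activation_ode_cpp(NumericVector e, double dt, double tau,
                                 double beta, double u0, bool exact) {
  const int n = e.size();
  NumericVector u(n);
  double ui = clamp01(u0);
  for (int i = 0; i < n; ++i) {
    u[i] = ui;
    ui = exact ? act_step_exact(ui, e[i], dt, tau, beta)
               : act_step_rk4(ui, e[i], dt, tau, beta);
    ui = clamp01(ui);
  }
  return u;
}

static inline double a_model(double u, double A) {
  return std::expm1(A * u) / std::expm1(A);
}

static inline double force_length(double dL, double L0, double w, double c) {
  const double x = std::fabs(dL / (L0 * w));
  return std::exp(c * x * x * x);
}

static inline double force_velocity(double v, double vmax, double Kv,
                                    double N) {
  if (v < 0.0) {
    const double f = (vmax + v) / (vmax - Kv * v);
    return f > 0.0 ? f : 0.0;
  }
  return N + (N - 1.0) * (v - vmax) / (vmax + 7.56 * Kv * v);
}

static inline double passive_force(double LM, double L0, double Kp) {
  if (LM < L0) return 0.0;
  const double s = (LM - L0) / L0;
  return Kp * s * s;
}

// Forward dynamics of the elbow driven by four gained excitation channels.
// e columns: bic_short, bic_long, tric_long, tric_lat (already gain-scaled
// and clamped to [0,1]).  Returns per-sample state, activations and the
// torque decomposition.
// [[Rcpp::export]]
List forward_dynamics_cpp(NumericMatrix e, double dt, List par,
                          double theta0, double omega0,
                          int n_sub, bool exact_act) {
  const int n = e.nrow();
  if (e.ncol() != 4) stop("excitation matrix must have 4 columns");
  if (n_sub < 1) stop("n_sub must be >= 1");

  const double tau = par["tau_act"], beta = par["beta"], A = par["A_shape"];
  const double w = par["w"], cc = par["c"], Necc = par["N_ecc"];
  const double Kv = par["K_v"], vmaxf = par["v_max_factor"], Kp = par["K_p"];
  const double A_bic = par["A_bic"], B_bic = par["B_bic"];
  const double L_T_bic = par["L_T_bic"], L_M0_bic = par["L_M0_bic"];
  const double L_M0_tric = par["L_M0_tric"], Lma_tric = par["Lma_tric"];
  const double L_off = par["L_offset_tric"];
  const double F_max_bic = par["F_max_bic"], F_max_tric = par["F_max_tric"];
  const double m_f = par["m_forearm"], m_h = par["m_hand"];
  const double m_add = par["m_add"], L_cog = par["L_forearm_cog"];
  const double L_palm = par["L_palm"], d = par["d_damp"], g = par["g"];
  const double alpha = par["alpha"], theta_min = par["theta_min"];
  const double th_lo = par["theta_lo"], th_hi = par["theta_hi"];
  const double K_stop = par["K_stop"];

  const double grav_lever = m_f * L_cog + (m_h + m_add) * L_palm;
  const double J = m_f * L_cog * L_cog + (m_h + m_add) * L_palm * L_palm;
  const double vmax_b = vmaxf * L_M0_bic, vmax_t = vmaxf * L_M0_tric;
  const double h = dt / n_sub;

  NumericVector theta(n), omega(n), a_bic(n), a_tric(n);
  NumericVector tq_bic_act(n), tq_tric_act(n), tq_bic_pas(n), tq_tric_pas(n);
  NumericVector tq_grav(n), tq_damp(n), tq_stop(n), tq_net(n);

  double th = theta0, om = omega0;
  double u[4] = {clamp01(e(0, 0)), clamp01(e(0, 1)),
                 clamp01(e(0, 2)), clamp01(e(0, 3))};

  for (int i = 0; i < n; ++i) {
    theta[i] = th;
    omega[i] = om;
    for (int s = 0; s < n_sub; ++s) {
      // activation
      const double u_b = clamp01(u[0] + u[1]);
      const double u_t = clamp01(u[2] + u[3]);
      const double ab = a_model(u_b, A);
      const double at = a_model(u_t, A);

      // biceps geometry
      const double thc = th > theta_min ? th : theta_min;
      const double phi = std::atan2(A_bic * std::sin(thc),
                                    B_bic + A_bic * std::cos(thc));
      const double Lma_b = B_bic * std::sin(phi);
      const double L_MTC = std::sqrt(A_bic * A_bic + B_bic * B_bic +
                                     2.0 * A_bic * B_bic * std::cos(thc));
      const double L_M_b = L_MTC - L_T_bic;
      // dL_MTC/dtheta * omega (chain rule; pulley for the triceps)
      const double v_b = -(A_bic * B_bic * std::sin(thc)) / L_MTC * om;
      const double L_M_t = 0.54 * L_M0_tric + Lma_tric * th + L_off;
      const double v_t = Lma_tric * om;

      // Hill-type forces
      const double FL_b = force_length(L_M_b - L_M0_bic, L_M0_bic, w, cc);
      const double Fv_b = force_velocity(v_b, vmax_b, Kv, Necc);
      const double Fp_b = passive_force(L_M_b, L_M0_bic, Kp);
      const double FL_t = force_length(L_M_t - L_M0_tric, L_M0_tric, w, cc);
      const double Fv_t = force_velocity(v_t, vmax_t, Kv, Necc);
      const double Fp_t = passive_force(L_M_t, L_M0_tric, Kp);

      const double T_b_act = F_max_bic * ab * FL_b * Fv_b * Lma_b;
      const double T_b_pas = F_max_bic * Fp_b * Lma_b;
      const double T_t_act = -F_max_tric * at * FL_t * Fv_t * Lma_tric;
      const double T_t_pas = -F_max_tric * Fp_t * Lma_tric;
      const double T_g = -g * grav_lever * std::sin(alpha + th);
      const double T_d = -d * om;
      double T_s = 0.0;
      if (th > th_hi) T_s = -K_stop * (th - th_hi);
      else if (th < th_lo) T_s = -K_stop * (th - th_lo);
      const double T = T_b_act + T_b_pas + T_t_act + T_t_pas + T_g + T_d + T_s;

      if (s == 0) {  // record the decomposition at the sample instant
        a_bic[i] = ab; a_tric[i] = at;
        tq_bic_act[i] = T_b_act; tq_bic_pas[i] = T_b_pas;
        tq_tric_act[i] = T_t_act; tq_tric_pas[i] = T_t_pas;
        tq_grav[i] = T_g; tq_damp[i] = T_d; tq_stop[i] = T_s; tq_net[i] = T;
      }

      // semi-implicit Euler on the joint, fixed-step on the activations
      om += h * T / J;
      th += h * om;
      for (int j = 0; j < 4; ++j) {
        u[j] = exact_act ? act_step_exact(u[j], e(i, j), h, tau, beta)
                         : act_step_rk4(u[j], e(i, j), h, tau, beta);
        u[j] = clamp01(u[j]);
      }
    }
    if (!std::isfinite(th) || !std::isfinite(om)) {
      stop("forward simulation diverged at step %d (t = %.3f s)", i + 1,
           (i + 1) * dt);
    }
  }

  return List::create(
      _["theta"] = theta, _["omega"] = omega,
      _["a_bic"] = a_bic, _["a_tric"] = a_tric,
      _["torque_bic_active"] = tq_bic_act,
      _["torque_tric_active"] = tq_tric_act,
      _["torque_bic_passive"] = tq_bic_pas,
      _["torque_tric_passive"] = tq_tric_pas,
      _["torque_gravity"] = tq_grav, _["torque_damping"] = tq_damp,
      _["torque_stop"] = tq_stop, _["torque_net"] = tq_net);
}
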