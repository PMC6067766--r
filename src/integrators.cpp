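// Fixed-step RK4 cores for the Kuramoto and Stuart-Landau network models.
//
// The coupling strength K is piecewise constant per step (schedules are
// realised to a per-step vector in R). Controls are evaluated from the
// instantaneous state at every RK4 stage; phases are wrapped to [0, 2*pi)
// after each full step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double TWO_PI = 6.283185307179586476925286766559;

// wrap into [0, 2*pi) without fmod
static inline double wrap_two_pi(double x) {
  x -= TWO_PI * std::floor(x / TWO_PI);
  if (x >= TWO_PI) x -= TWO_PI;   // guard against rounding at the boundary
  if (x < 0) x += TWO_PI;
  return x;
}

// electrode-sampled modified order parameters |Rh_l| for all electrodes.
// ig is the M x M matrix ig(j, l) = 1 / (omega_Ej - omega_El), zero diagonal.
static vec sampled_rh(const vec& phi_el, const mat& ig) {
  const uword m = phi_el.n_elem;
  cx_vec ze(m);
  for (uword j = 0; j < m; ++j) ze(j) = std::polar(1.0, phi_el(j));
  cx_vec s = ig.t() * ze;      // s(l) = sum_j ze(j) / (omega_j - omega_l)
  return abs(s) / double(m);
}

struct KmProblem {
  vec omega;
  mat A;                 // adjacency (unused when meanfield)
  bool meanfield;
  // hamiltonian operational control
  int control;           // 0 none, 1 hamiltonian, 2 pdf
  uvec electrodes;       // 0-based
  mat E;                 // N x M field matrix c_s * exp(-2 r)
  mat ig;                // M x M inverse frequency gaps
  double gamma;
  bool sampled_R;
  // pdf control
  uvec measured, stimulated;
  double P, D;

  vec rhs(const vec& phi, double K) const {
    const uword n = phi.n_elem;
    vec s = sin(phi), c = cos(phi);
    vec v(n);
    if (meanfield) {
      double rc = mean(c), rs = mean(s);
      // K * R * sin(Psi - phi_k) = K * (rs * cos(phi_k) - rc * sin(phi_k))
      v = omega + K * (rs * c - rc * s);
    } else {
      v = omega + (K / double(n)) * (c % (A * s) - s % (A * c));
    }
    if (control == 1) {
      vec phi_el = phi.elem(electrodes);
      vec rh = sampled_rh(phi_el, ig);
      std::complex<double> zg(0.0, 0.0);
      if (sampled_R) {
        for (uword j = 0; j < phi_el.n_elem; ++j)
          zg += std::polar(1.0, phi_el(j));
        zg /= double(phi_el.n_elem);
      } else {
        zg = std::complex<double>(mean(c), mean(s));
      }
      vec hh(phi_el.n_elem);
      for (uword l = 0; l < phi_el.n_elem; ++l) {
        // |zg| * cos(Psi - phi_l) = Re(zg * exp(-i phi_l))
        double proj = std::real(zg * std::polar(1.0, -phi_el(l)));
        hh(l) = -(gamma / 4.0) * K * K * rh(l) * proj;
      }
      v += E * hh;
    } else if (control == 2) {
      double X = 0.0, Xd = 0.0;
      for (uword i = 0; i < measured.n_elem; ++i) {
        uword j = measured(i);
        X  += c(j);
        Xd += -s(j) * v(j);     // analytic derivative from uncontrolled velocities
      }
      X  /= double(measured.n_elem);
      Xd /= double(measured.n_elem);
      // injected force -(P X + D dX/dt) through phase sensitivity -sin(phi)
      double f = P * X + D * Xd;
      for (uword i = 0; i < stimulated.n_elem; ++i) {
        uword j = stimulated(i);
        v(j) += f * s(j);
      }
    }
    return v;
  }
};

// [[Rcpp::export]]
Rcpp::List km_integrate_cpp(const arma::vec& phi0, const arma::vec& omega,
                            const arma::mat& A, bool meanfield,
                            const arma::vec& K_steps, double dt,
                            int record_every, int control,
                            const arma::uvec& electrodes, const arma::mat& E,
                            const arma::mat& ig, double gamma, bool sampled_R,
                            const arma::uvec& measured,
                            const arma::uvec& stimulated,
                            double P, double D, bool record_phases) {
  KmProblem pb{omega, A, meanfield, control, electrodes, E, ig, gamma,
               sampled_R, measured, stimulated, P, D};
  const uword n = phi0.n_elem;
  const uword n_steps = K_steps.n_elem;
  vec phi = phi0;

  std::vector<uword> rec_steps;
  for (uword s = 0; s <= n_steps; s += record_every) rec_steps.push_back(s);
  if (rec_steps.back() != n_steps) rec_steps.push_back(n_steps);
  const uword n_rec = rec_steps.size();

  vec times(n_rec), R(n_rec), Psi(n_rec), Krec(n_rec);
  mat traj;
  if (record_phases) traj.set_size(n_rec, n);

  uword ri = 0;
  auto record = [&](uword step) {
    times(ri) = step * dt;
    double rc = mean(cos(phi)), rs = mean(sin(phi));
    double r = std::sqrt(rc * rc + rs * rs);
    R(ri) = r > 1.0 ? 1.0 : r;
    Psi(ri) = r < 1e-12 ? 0.0 : wrap_two_pi(std::atan2(rs, rc));
    Krec(ri) = K_steps(step < n_steps ? step : n_steps - 1);
    if (record_phases) traj.row(ri) = phi.t();
    if (!phi.is_finite())
      Rcpp::stop("integration blow-up at t = %g", step * dt);
    ++ri;
  };

  record(0);
  for (uword s = 0; s < n_steps; ++s) {
    double K = K_steps(s);
    vec k1 = pb.rhs(phi, K);
    vec k2 = pb.rhs(phi + 0.5 * dt * k1, K);
    vec k3 = pb.rhs(phi + 0.5 * dt * k2, K);
    vec k4 = pb.rhs(phi + dt * k3, K);
    phi += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    for (uword i = 0; i < n; ++i) phi(i) = wrap_two_pi(phi(i));
    if (ri < n_rec && s + 1 == rec_steps[ri]) record(s + 1);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("times") = times, Rcpp::Named("R") = R,
      Rcpp::Named("Psi") = Psi, Rcpp::Named("K") = Krec,
      Rcpp::Named("final_phases") = phi);
  if (record_phases) out["phases"] = traj;
  return out;
}

struct SlProblem {
  vec omega;
  mat A;
  bool meanfield;            // couple through the plain average (K/N) sum z_j
  int control;               // 0 none, 1 operational electrodes, 2 theoretical
  uvec electrodes;
  mat E;
  mat ig;                    // electrode gaps (operational)
  mat ig_full;               // N x N gaps (theoretical)
  double gamma;
  bool sampled_R;

  // per-node stimulation field of the operational control: the induced
  // complex drive is the pure phase torque -i S_k z_k
  vec field(const cx_vec& z, double K) const {
    vec phi_el(electrodes.n_elem);
    for (uword l = 0; l < electrodes.n_elem; ++l)
      phi_el(l) = std::arg(z(electrodes(l)));
    vec rh = sampled_rh(phi_el, ig);
    std::complex<double> zg(0.0, 0.0);
    if (sampled_R) {
      for (uword j = 0; j < phi_el.n_elem; ++j)
        zg += std::polar(1.0, phi_el(j));
      zg /= double(phi_el.n_elem);
    } else {
      for (uword j = 0; j < z.n_elem; ++j)
        zg += std::polar(1.0, std::arg(z(j)));
      zg /= double(z.n_elem);
    }
    vec hh(phi_el.n_elem);
    for (uword l = 0; l < phi_el.n_elem; ++l) {
      double proj = std::real(zg * std::polar(1.0, -phi_el(l)));
      hh(l) = -(gamma / 4.0) * K * K * rh(l) * proj;
    }
    return E * hh;
  }

  cx_vec rhs(const cx_vec& z, double K) const {
    const uword n = z.n_elem;
    const std::complex<double> I(0.0, 1.0);
    cx_vec dz(n);
    for (uword k = 0; k < n; ++k)
      dz(k) = (std::complex<double>(1.0, omega(k)) - std::norm(z(k))) * z(k);
    cx_vec coup(n);
    if (meanfield) {
      std::complex<double> Z = (K / double(n)) * accu(z);
      coup.fill(Z);
    } else {
      coup = (K / double(n)) * (A * z);
    }
    dz += coup;
    // the operational control torque (control == 1) is applied by the
    // integrator through an exact exponential rotation (Strang splitting),
    // not here: the torque can be numerically stiff when an electrode pair
    // is close in frequency, and the exponential map is unconditionally
    // stable for pure rotations.
    if (control == 2) {
      // Z^ctrl_k = -i (K/4) Rt_k Z with Rt_k from all phases
      cx_vec ph(n);
      for (uword j = 0; j < n; ++j) ph(j) = std::polar(1.0, std::arg(z(j)));
      cx_vec s = ig_full.t() * ph;   // sum_j e^{i phi_j} / (omega_j - omega_k)
      std::complex<double> Z = (K / double(n)) * accu(z);
      for (uword k = 0; k < n; ++k)
        dz(k) += -I * (K / 4.0) * (std::abs(s(k)) / double(n)) * Z;
    }
    return dz;
  }
};

// [[Rcpp::export]]
Rcpp::List sl_integrate_cpp(const arma::cx_vec& z0, const arma::vec& omega,
                            const arma::mat& A, bool meanfield,
                            const arma::vec& K_steps, double dt,
                            int record_every, int control,
                            const arma::uvec& electrodes, const arma::mat& E,
                            const arma::mat& ig, const arma::mat& ig_full,
                            double gamma, bool sampled_R, bool record_states) {
  SlProblem pb{omega, A, meanfield, control, electrodes, E, ig, ig_full,
               gamma, sampled_R};
  const uword n = z0.n_elem;
  const uword n_steps = K_steps.n_elem;
  cx_vec z = z0;

  std::vector<uword> rec_steps;
  for (uword s = 0; s <= n_steps; s += record_every) rec_steps.push_back(s);
  if (rec_steps.back() != n_steps) rec_steps.push_back(n_steps);
  const uword n_rec = rec_steps.size();

  vec times(n_rec), R(n_rec), total(n_rec), Krec(n_rec);
  cx_mat traj;
  if (record_states) traj.set_size(n_rec, n);

  uword ri = 0;
  auto record = [&](uword step) {
    times(ri) = step * dt;
    std::complex<double> zg(0.0, 0.0);
    double tot = 0.0;
    for (uword j = 0; j < n; ++j) {
      zg += std::polar(1.0, std::arg(z(j)));
      tot += std::real(z(j));
    }
    R(ri) = std::min(std::abs(zg) / double(n), 1.0);
    total(ri) = tot;
    Krec(ri) = K_steps(step < n_steps ? step : n_steps - 1);
    if (record_states) traj.row(ri) = z.st();
    if (!z.is_finite())
      Rcpp::stop("integration blow-up at t = %g", step * dt);
    ++ri;
  };

  const std::complex<double> I(0.0, 1.0);
  record(0);
  for (uword s = 0; s < n_steps; ++s) {
    double K = K_steps(s);
    if (control == 1) {                       // half-step control rotation
      vec S = pb.field(z, K);
      for (uword k = 0; k < n; ++k) z(k) *= std::exp(-I * (S(k) * dt / 2.0));
    }
    cx_vec k1 = pb.rhs(z, K);
    cx_vec k2 = pb.rhs(z + 0.5 * dt * k1, K);
    cx_vec k3 = pb.rhs(z + 0.5 * dt * k2, K);
    cx_vec k4 = pb.rhs(z + dt * k3, K);
    z += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (control == 1) {
      vec S = pb.field(z, K);
      for (uword k = 0; k < n; ++k) z(k) *= std::exp(-I * (S(k) * dt / 2.0));
    }
    if (ri < n_rec && s + 1 == rec_steps[ri]) record(s + 1);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("times") = times, Rcpp::Named("R") = R,
      Rcpp::Named("total_signal") = total, Rcpp::Named("K") = Krec,
      Rcpp::Named("final_z") = z);
  if (record_states) out["z"] = traj;
  return out;
}
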