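// Core numerics: surrogate potentials, BAOAB Langevin propagation, and
// basin-bounded path generation. Units throughout: kcal/mol, Angstrom, fs,
// amu, K. Force-to-acceleration conversion: 1 kcal/mol/A / amu
// = 4.184e-4 A/fs^2 (exact, since amu * N_A = 1 g).
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB_KCAL = 0.0019872041; // kcal/mol/K
static const double ACC_UNIT = 4.184e-4;    // (A/fs)^2 per kcal/mol/amu

// Deterministic normal deviates: mt19937_64 + Box-Muller (implementation of
// std::normal_distribution varies across stdlibs; this one is fixed).
struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { // in (0, 1)
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

enum SysKind { DOUBLE_WELL = 1, HARMONIC_1D = 2, MIGRATION = 3 };

struct SysSpec {
  int kind;
  int n_coord;
  std::vector<double> masses; // per coordinate
  std::vector<double> params;
  std::vector<double> tethers; // migration mimic env tether points (3 per env)
};

static SysSpec parse_spec(const List& spec) {
  SysSpec s;
  s.kind = as<int>(spec["kind"]);
  s.n_coord = as<int>(spec["n_coord"]);
  s.masses = as<std::vector<double>>(spec["masses_coord"]);
  s.params = as<std::vector<double>>(spec["params"]);
  if (spec.containsElementNamed("tethers"))
    s.tethers = as<std::vector<double>>(spec["tethers"]);
  return s;
}

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// lambda and its gradient (gradient optional: pass nullptr to skip)
static double lambda_of(const SysSpec& s, const double* x, double* dldx) {
  if (s.kind == DOUBLE_WELL || s.kind == HARMONIC_1D) {
    if (dldx) { for (int i = 0; i < s.n_coord; ++i) dldx[i] = 0.0; dldx[0] = 1.0; }
    return x[0];
  }
  // migration mimic: particles D=0, M=1, A=2 (3D); lambda = |rD-rM| - |rM-rA|
  const double* rD = x; const double* rM = x + 3; const double* rA = x + 6;
  double d1 = dist3(rD, rM), d2 = dist3(rM, rA);
  if (dldx) {
    for (int i = 0; i < s.n_coord; ++i) dldx[i] = 0.0;
    for (int k = 0; k < 3; ++k) {
      double u1 = (rD[k] - rM[k]) / d1;   // d d1 / d rD
      double u2 = (rM[k] - rA[k]) / d2;   // d d2 / d rM
      dldx[k] = u1;
      dldx[3 + k] = -u1 - u2;             // d(d1)/drM = -(rD-rM)/d1 ; -d(d2)/drM
      dldx[6 + k] = u2;                   // -d(d2)/drA = (rM-rA)/d2 ... sign below
    }
    // fix signs: lambda = d1 - d2
    // d d1/d rM = (rM-rD)/d1 = -u1 ; d d2/d rM = (rM-rA)/d2 = u2
    // => dl/drM = -u1 - u2  (as set)
    // d d2/d rA = (rA-rM)/d2 = -u2 => dl/drA = +u2 (as set)
  }
  return d1 - d2;
}

// potential energy and gradient (dV/dx); returns V. grad may be nullptr.
static double potential_of(const SysSpec& s, const double* x, double* grad) {
  const std::vector<double>& p = s.params;
  if (grad) for (int i = 0; i < s.n_coord; ++i) grad[i] = 0.0;
  if (s.kind == HARMONIC_1D) {
    double k = p[0], x0 = p[1];
    if (grad) grad[0] = k * (x[0] - x0);
    return 0.5 * k * (x[0] - x0) * (x[0] - x0);
  }
  if (s.kind == DOUBLE_WELL) {
    // params: h, c1, c2, coupling, k_env
    double h = p[0], c1 = p[1], c2 = p[2], cpl = p[3], k_env = p[4];
    double m = 0.5 * (c1 + c2), wd = 0.5 * (c2 - c1);
    double u = (x[0] - m) / wd;
    double V = h * (u * u - 1.0) * (u * u - 1.0);
    if (grad) grad[0] = h * 4.0 * u * (u * u - 1.0) / wd;
    double xdev = x[0] - m;
    for (int j = 1; j < s.n_coord; ++j) {
      V += 0.5 * k_env * x[j] * x[j] + cpl * k_env * xdev * x[j];
      if (grad) {
        grad[j] += k_env * x[j] + cpl * k_env * xdev;
        grad[0] += cpl * k_env * x[j];
      }
    }
    return V;
  }
  // MIGRATION mimic: two-state bond exchange. Each diabatic state is a
  // Morse bond (D-M or M-A) plus an exponential repulsion from the other
  // partner; the adiabatic ground state V = (V1+V2)/2 - sqrt(((V1-V2)/2)^2
  // + C^2) gives a double well along lambda = d(D,M) - d(M,A) with real
  // bond vibrations. A gate environment coordinate lowers the barrier
  // through a bounded switch times a bump at lambda = 0.
  // params: d0, k_tether, k_perp, De, a_morse, r0, eps_rep, rho_rep, C,
  //         gate_strength, d_ref, sigma_g, w_bump, bump_center, k_env,
  //         n_env, gate_k
  double d0 = p[0], kt = p[1], kperp = p[2];
  double De = p[3], am = p[4], r0 = p[5], eps = p[6], rho = p[7], C = p[8];
  double gs = p[9], dref = p[10], sg = p[11], wb = p[12], lb = p[13];
  double kenv = p[14];
  int n_env = static_cast<int>(p[15]);
  double gate_k = p[16];
  double exo = p[17];   // product-state stabilization (exothermicity)
  const double* rD = x; const double* rM = x + 3;
  double V = 0.0;
  // tethers on D and A at (-d0,0,0), (d0,0,0)
  double pD[3] = { -d0, 0.0, 0.0 }, pA[3] = { d0, 0.0, 0.0 };
  for (int k = 0; k < 3; ++k) {
    double dD = x[k] - pD[k], dA = x[6 + k] - pA[k];
    V += 0.5 * kt * (dD * dD + dA * dA);
    if (grad) { grad[k] += kt * dD; grad[6 + k] += kt * dA; }
  }
  // transverse confinement of M
  V += 0.5 * kperp * (rM[1] * rM[1] + rM[2] * rM[2]);
  if (grad) { grad[4] += kperp * rM[1]; grad[5] += kperp * rM[2]; }
  // env particles tethered at supplied points
  for (int j = 0; j < n_env; ++j) {
    const double* rj = x + 3 * (3 + j);
    const double* tj = s.tethers.data() + 3 * j;
    double kj = (j == 0) ? gate_k : kenv;  // the gate tether is softer
    for (int k = 0; k < 3; ++k) {
      double d = rj[k] - tj[k];
      V += 0.5 * kj * d * d;
      if (grad) grad[3 * (3 + j) + k] += kj * d;
    }
  }
  // two-state bond exchange along d1 = d(D,M), d2 = d(M,A)
  const double* rA_ = x + 6;
  double d1 = dist3(rD, rM), d2 = dist3(rM, rA_);
  auto morse = [&](double d, double& dV) {
    double e = std::exp(-am * (d - r0));
    dV = 2.0 * De * (1.0 - e) * am * e;
    return De * (1.0 - e) * (1.0 - e);
  };
  auto repul = [&](double d, double& dV) {
    double v = eps * std::exp(-(d - r0) / rho);
    dV = -v / rho;
    return v;
  };
  double dm1, dm2, dr1, dr2;
  double V1 = morse(d1, dm1) + repul(d2, dr2);
  double V2 = morse(d2, dm2) + repul(d1, dr1) - exo;
  double S = std::sqrt(0.25 * (V1 - V2) * (V1 - V2) + C * C);
  V += 0.5 * (V1 + V2) - S;
  double w1 = 0.5 - 0.25 * (V1 - V2) / S;  // dV/dV1
  double w2 = 0.5 + 0.25 * (V1 - V2) / S;  // dV/dV2
  double dVdd1 = w1 * dm1 + w2 * dr1;
  double dVdd2 = w2 * dm2 + w1 * dr2;
  if (grad) {
    for (int k = 0; k < 3; ++k) {
      double u1 = (rD[k] - rM[k]) / d1;   // d d1/d rD
      double u2 = (rM[k] - rA_[k]) / d2;  // d d2/d rM
      grad[k] += dVdd1 * u1;
      grad[3 + k] += -dVdd1 * u1 + dVdd2 * u2;
      grad[6 + k] += -dVdd2 * u2;
    }
  }
  // gate modulation of the barrier region
  std::vector<double> dldx(s.n_coord);
  double lam = lambda_of(s, x, grad ? dldx.data() : nullptr);
  double dVdlam = 0.0;
  if (gs != 0.0 && n_env >= 1) {
    // a product-side wall felt only by closed gates: open gates (large
    // gate-donor distance) pass freely, closed gates bounce back
    const double* rg = x + 9; // gate = first env particle
    double dgD = dist3(rg, rD);
    double tgate = std::tanh((dgD - dref) / sg);
    double G = gs * 0.5 * (1.0 - tgate);           // wall height in [0, gs]
    double u_l = lam - lb;
    double B = std::exp(-u_l * u_l / (2.0 * wb * wb));
    V += G * B;
    dVdlam += G * B * (-u_l / (wb * wb));
    if (grad) {
      double dGdd = -gs * 0.5 * (1.0 - tgate * tgate) / sg;
      for (int k = 0; k < 3; ++k) {
        double u = (rg[k] - rD[k]) / dgD;
        grad[9 + k] += dGdd * B * u;
        grad[k] += -dGdd * B * u;
      }
    }
  }
  if (grad) for (int i = 0; i < s.n_coord; ++i) grad[i] += dVdlam * dldx[i];
  return V;
}

// add harmonic umbrella bias  k_b * (lambda - c)^2  (no 1/2 by convention)
static double add_bias(const SysSpec& s, const double* x, double bias_k,
                       double bias_c, double* grad, std::vector<double>& scratch) {
  if (bias_k <= 0.0) return 0.0;
  double lam = lambda_of(s, x, grad ? scratch.data() : nullptr);
  double d = lam - bias_c;
  if (grad) {
    double f = 2.0 * bias_k * d;
    for (int i = 0; i < s.n_coord; ++i) grad[i] += f * scratch[i];
  }
  return bias_k * d * d;
}

// [[Rcpp::export]]
double cpp_potential(List spec, NumericVector pos) {
  SysSpec s = parse_spec(spec);
  return potential_of(s, REAL(pos), nullptr);
}

// [[Rcpp::export]]
NumericVector cpp_gradient(List spec, NumericVector pos) {
  SysSpec s = parse_spec(spec);
  NumericVector g(s.n_coord);
  potential_of(s, REAL(pos), REAL(g));
  return g;
}

// [[Rcpp::export]]
double cpp_lambda(List spec, NumericVector pos) {
  SysSpec s = parse_spec(spec);
  return lambda_of(s, REAL(pos), nullptr);
}

struct Baoab {
  const SysSpec& s;
  double dt, c1, kT;
  std::vector<double> c2v, invm_acc; // per-coordinate
  std::vector<double> grad, scratch;
  Baoab(const SysSpec& s_, double dt_, double gamma_invps, double tempK)
      : s(s_), dt(dt_), kT(KB_KCAL * tempK),
        c2v(s_.n_coord), invm_acc(s_.n_coord), grad(s_.n_coord),
        scratch(s_.n_coord) {
    double gamma_fs = gamma_invps * 1e-3;
    c1 = std::exp(-gamma_fs * dt);
    double c2 = std::sqrt(1.0 - c1 * c1);
    for (int i = 0; i < s.n_coord; ++i) {
      c2v[i] = c2 * std::sqrt(kT * ACC_UNIT / s.masses[i]);
      invm_acc[i] = ACC_UNIT / s.masses[i];
    }
  }
  // one BAOAB step; returns potential at the new position
  double step(double* x, double* v, double bias_k, double bias_c, Rng& rng) {
    int n = s.n_coord;
    for (int i = 0; i < n; ++i) v[i] -= 0.5 * dt * grad[i] * invm_acc[i];
    for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * v[i];
    if (c1 < 1.0)
      for (int i = 0; i < n; ++i) v[i] = c1 * v[i] + c2v[i] * rng.norm();
    for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * v[i];
    double V = potential_of(s, x, grad.data());
    V += add_bias(s, x, bias_k, bias_c, grad.data(), scratch);
    for (int i = 0; i < n; ++i) v[i] -= 0.5 * dt * grad[i] * invm_acc[i];
    return V;
  }
  double init_forces(const double* x, double bias_k, double bias_c) {
    double V = potential_of(s, x, grad.data());
    V += add_bias(s, x, bias_k, bias_c, grad.data(), scratch);
    return V;
  }
};

// Fixed-length Langevin run. Returns lambda series (every record_every
// steps, initial state included), final state, mean kinetic energy per dof,
// and optionally all frames.
// [[Rcpp::export]]
List cpp_integrate(List spec, NumericVector pos, NumericVector vel,
                   int n_steps, double dt, double friction, double temperature,
                   double seed, double bias_k = -1.0, double bias_c = 0.0,
                   int record_every = 1, bool save_frames = false) {
  SysSpec s = parse_spec(spec);
  Rng rng(static_cast<uint64_t>(seed));
  Baoab prop(s, dt, friction, temperature);
  int n = s.n_coord;
  std::vector<double> x(REAL(pos), REAL(pos) + n), v(REAL(vel), REAL(vel) + n);
  prop.init_forces(x.data(), bias_k, bias_c);

  int n_rec = n_steps / record_every + 1;
  NumericVector lam_series(n_rec);
  NumericMatrix fpos, fvel;
  if (save_frames) { fpos = NumericMatrix(n_steps + 1, n); fvel = NumericMatrix(n_steps + 1, n); }
  lam_series[0] = lambda_of(s, x.data(), nullptr);
  if (save_frames)
    for (int i = 0; i < n; ++i) { fpos(0, i) = x[i]; fvel(0, i) = v[i]; }

  double ke_sum = 0.0;
  int rec = 1;
  for (int t = 1; t <= n_steps; ++t) {
    double V = prop.step(x.data(), v.data(), bias_k, bias_c, rng);
    if (!std::isfinite(V))
      return List::create(_["error"] = true, _["step"] = t);
    double ke = 0.0;
    for (int i = 0; i < n; ++i) ke += 0.5 * s.masses[i] * v[i] * v[i] / ACC_UNIT;
    ke_sum += ke;
    if (t % record_every == 0)
      lam_series[rec++] = lambda_of(s, x.data(), nullptr);
    if (save_frames)
      for (int i = 0; i < n; ++i) { fpos(t, i) = x[i]; fvel(t, i) = v[i]; }
  }
  List out = List::create(
      _["error"] = false, _["lambda"] = lam_series,
      _["pos"] = NumericVector(x.begin(), x.end()),
      _["vel"] = NumericVector(v.begin(), v.end()),
      _["mean_ke_per_dof"] = ke_sum / (double(n_steps) * n),
      _["record_every"] = record_every);
  if (save_frames) { out["frames_pos"] = fpos; out["frames_vel"] = fvel; }
  return out;
}

// Propagate until lambda < lam_A (outcome 1) or lambda > lam_B (outcome 2),
// or max_steps is hit (outcome 0). Every frame is stored.
// [[Rcpp::export]]
List cpp_propagate_to_basin(List spec, NumericVector pos, NumericVector vel,
                            double lam_A, double lam_B, int max_steps,
                            double dt, double friction, double temperature,
                            double seed, bool save_frames = true) {
  SysSpec s = parse_spec(spec);
  Rng rng(static_cast<uint64_t>(seed));
  Baoab prop(s, dt, friction, temperature);
  int n = s.n_coord;
  std::vector<double> x(REAL(pos), REAL(pos) + n), v(REAL(vel), REAL(vel) + n);
  prop.init_forces(x.data(), -1.0, 0.0);

  std::vector<double> lam_hist, xs, vs;
  double lam = lambda_of(s, x.data(), nullptr);
  lam_hist.push_back(lam);
  if (save_frames) {
    xs.insert(xs.end(), x.begin(), x.end());
    vs.insert(vs.end(), v.begin(), v.end());
  }
  int outcome = (lam < lam_A) ? 1 : (lam > lam_B ? 2 : 0);
  int t = 0;
  while (outcome == 0 && t < max_steps) {
    double V = prop.step(x.data(), v.data(), -1.0, 0.0, rng);
    ++t;
    if (!std::isfinite(V))
      return List::create(_["error"] = true, _["step"] = t);
    lam = lambda_of(s, x.data(), nullptr);
    lam_hist.push_back(lam);
    if (save_frames) {
      xs.insert(xs.end(), x.begin(), x.end());
      vs.insert(vs.end(), v.begin(), v.end());
    }
    if (lam < lam_A) outcome = 1;
    else if (lam > lam_B) outcome = 2;
  }
  int nf = static_cast<int>(lam_hist.size());
  List out = List::create(
      _["error"] = false,
      _["lambda"] = NumericVector(lam_hist.begin(), lam_hist.end()),
      _["outcome"] = outcome, _["n_steps"] = t);
  if (save_frames) {
    NumericMatrix fp(nf, n), fv(nf, n);
    for (int r = 0; r < nf; ++r)
      for (int i = 0; i < n; ++i) {
        fp(r, i) = xs[size_t(r) * n + i];
        fv(r, i) = vs[size_t(r) * n + i];
      }
    out["frames_pos"] = fp;
    out["frames_vel"] = fv;
  }
  return out;
}

// Count effective positive crossings of lam_A in a lambda series: one count
// per excursion out of A (the series must re-enter lambda < lam_A before the
// next crossing can count). Time assigned to B (after first entering
// lambda > lam_B) is excluded; counting resumes on the next return to A.
// Returns crossings and the number of dt intervals assigned to A.
// [[Rcpp::export]]
List cpp_effective_crossings(NumericVector lambda, double lam_A, double lam_B) {
  int n = lambda.size();
  int crossings = 0, ab_transitions = 0;
  long long steps_in_A = 0;
  bool armed = lambda[0] < lam_A;   // must visit A before a crossing counts
  bool in_B = lambda[0] > lam_B;    // history-based state assignment
  for (int i = 1; i < n; ++i) {
    double prev = lambda[i - 1], cur = lambda[i];
    if (in_B) {
      if (cur < lam_A) { in_B = false; armed = true; }
      continue;
    }
    ++steps_in_A;
    if (cur > lam_B) { in_B = true; armed = false; ++ab_transitions; continue; }
    if (cur < lam_A) { armed = true; continue; }
    if (armed && prev < lam_A && cur >= lam_A) { ++crossings; armed = false; }
  }
  return List::create(_["crossings"] = crossings,
                      _["steps_assigned_A"] = double(steps_in_A),
                      _["ab_transitions"] = ab_transitions);
}
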