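// Fixed-step planar rigid-body chain: head + C1..C7 joined by penalty
// bushings above a kinematically driven T1 base. Hill-type line muscles
// with a parallel damping element act between segments; a delayed PD
// controller on head orientation modulates flexor/extensor activation
// about the co-contraction baseline. Velocity-Verlet (kick-drift-kick)
// integration; velocity-dependent forces use the half-step velocity.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Body { double m, I; };

struct Frame { double x, z, th, vx, vz, w; };

inline void anchor_world(const Frame& f, double ax, double az,
                         double& px, double& pz, double& vx, double& vz) {
  double c = std::cos(f.th), s = std::sin(f.th);
  double rx = c * ax - s * az, rz = s * ax + c * az;
  px = f.x + rx;
  pz = f.z + rz;
  // planar angular velocity contribution: w x r = (-w*rz, w*rx)
  vx = f.vx - f.w * rz;
  vz = f.vz + f.w * rx;
}

inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

struct MuscleCurve {
  double sigma_max, fl_width, fv_shape, fv_ecc, v_max, k_p, c_p,
         pde_coeff, cco;
};

inline double fl_factor(double lam, double w) {
  double q = (lam - 1.0) / w;
  double f = 1.0 - q * q;
  return f > 0 ? f : 0.0;
}

inline double fv_factor(double vn, double k, double plateau) {
  if (vn <= 0) {
    if (vn < -1) vn = -1;
    return (1.0 + vn) / (1.0 - vn / k);
  }
  if (plateau <= 1.0) return 1.0;
  double slope0 = 1.0 + 1.0 / k;
  double d = (plateau - 1.0) / slope0;
  return plateau - (plateau - 1.0) * std::exp(-vn / d);
}

inline double passive_sigma(double lam, double k_p, double c_p) {
  return lam > 1 ? k_p * std::expm1(c_p * (lam - 1.0)) : 0.0;
}

} // namespace

// [[Rcpp::export]]
List simulate_chain_cpp(NumericVector mass, NumericVector inertia,
                        NumericMatrix q0, NumericMatrix v0,
                        NumericMatrix anchor_p, NumericMatrix anchor_c,
                        NumericVector kt, NumericVector ct,
                        NumericVector kr, NumericVector cr,
                        NumericVector neutral,
                        IntegerMatrix mus_body, NumericMatrix mus_a,
                        NumericMatrix mus_b, NumericVector mus_pcsa,
                        NumericVector mus_l0, IntegerVector mus_group,
                        List curve, List ctrl, List timing,
                        double gravity, List settle,
                        NumericMatrix t1) {
  const int nb = mass.size();               // bodies, bottom (next to T1) up
  const int nm = mus_pcsa.size();

  MuscleCurve mc;
  mc.sigma_max = as<double>(curve["sigma_max"]);
  mc.fl_width  = as<double>(curve["fl_width"]);
  mc.fv_shape  = as<double>(curve["fv_shape"]);
  mc.fv_ecc    = as<double>(curve["fv_ecc_plateau"]);
  mc.v_max     = as<double>(curve["v_max"]);
  mc.k_p       = as<double>(curve["k_passive"]);
  mc.c_p       = as<double>(curve["c_passive"]);
  mc.pde_coeff = as<double>(curve["pde_coeff"]);
  mc.cco       = as<double>(curve["cco_level"]);

  const bool ctrl_on   = as<bool>(ctrl["enabled"]);
  const double kpa     = as<double>(ctrl["kpa"]);
  const double kda     = as<double>(ctrl["kda"]);
  const double tnda    = as<double>(ctrl["tnda"]);
  const int routing    = as<int>(ctrl["routing"]);   // 0 reciprocal, 1 agonist

  const double t_start = as<double>(timing["t_start"]);
  const double t_end   = as<double>(timing["t_end"]);
  const double dt      = as<double>(timing["dt"]);
  const int out_every  = as<int>(timing["out_every"]);

  const double grav_ramp   = as<double>(settle["grav_ramp"]);
  const double damp_until  = as<double>(settle["damp_until"]);
  const double damp_factor = as<double>(settle["damp_factor"]);

  const int nsteps = (int)std::lround((t_end - t_start) / dt);
  if (t1.nrow() < nsteps + 1)
    stop("T1 trajectory shorter than the simulation span");

  const int head = nb - 1;                  // last body is the head
  std::vector<Frame> st(nb);
  for (int b = 0; b < nb; ++b) {
    st[b].x = q0(b, 0); st[b].z = q0(b, 1); st[b].th = q0(b, 2);
    st[b].vx = v0(b, 0); st[b].vz = v0(b, 1); st[b].w = v0(b, 2);
  }

  // controller error history, recorded each step from t = 0
  std::vector<double> e_hist;
  e_hist.reserve(nsteps + 1);
  double theta_ref = NA_REAL;
  bool ref_captured = false;

  const int nout = nsteps / out_every + 1;
  NumericVector out_t(nout);
  NumericMatrix out_state(nout, nb * 6);
  NumericMatrix out_t1(nout, 6);
  NumericVector out_head_ax(nout), out_u(nout), out_aflex(nout),
                out_aext(nout);
  NumericMatrix out_fmus(nout, nm);

  std::vector<double> ax(nb), az(nb), aw(nb);
  std::vector<double> fmus_now(nm);

  bool ok = true;
  double bad_t = NA_REAL;
  int bad_body = -1;

  // delayed PD command from the recorded error history (e at j*dt)
  auto pd_u = [&](double t) -> double {
    if (!ctrl_on || !ref_captured) return 0.0;
    double tq = t - tnda;
    if (tq < 0 || e_hist.size() < 1) return 0.0;
    int n = (int)e_hist.size();
    double idx = tq / dt;
    int i0 = (int)std::floor(idx);
    double frac = idx - i0;
    auto ge = [&](int i) {
      if (i < 0) i = 0;
      if (i > n - 1) i = n - 1;
      return e_hist[i];
    };
    auto rate = [&](int i) {
      if (n < 2) return 0.0;
      if (i <= 0) return (ge(1) - ge(0)) / dt;
      if (i >= n - 1) return (ge(n - 1) - ge(n - 2)) / dt;
      return (ge(i + 1) - ge(i - 1)) / (2 * dt);
    };
    double e = (1 - frac) * ge(i0) + frac * ge(i0 + 1);
    double de = (1 - frac) * rate(i0) + frac * rate(i0 + 1);
    return kpa * e + kda * de;
  };

  // net accelerations for a given state; t1row indexes the prescribed
  // base motion; u is the controller command (percent contraction)
  auto compute_accel = [&](const std::vector<Frame>& s, int t1row,
                           double t, double u, bool record_fmus) {
    double a_flex, a_ext;
    if (routing == 1) {
      a_flex = clamp01(mc.cco + (u > 0 ? u : 0) / 100.0);
      a_ext  = clamp01(mc.cco + (u < 0 ? -u : 0) / 100.0);
    } else {
      a_flex = clamp01(mc.cco + u / 100.0);
      a_ext  = clamp01(mc.cco - u / 100.0);
    }
    double gf = gravity;
    if (grav_ramp > 0) {
      double r = (t - t_start) / grav_ramp;
      if (r < 0) r = 0;
      if (r < 1) gf *= r;
    }
    double df = (t < damp_until) ? damp_factor : 1.0;

    std::vector<double> fx(nb, 0.0), fz(nb, 0.0), tq(nb, 0.0);
    for (int b = 0; b < nb; ++b) fz[b] -= mass[b] * gf;

    Frame t1f;
    t1f.x = t1(t1row, 0); t1f.z = t1(t1row, 1); t1f.th = t1(t1row, 2);
    t1f.vx = t1(t1row, 3); t1f.vz = t1(t1row, 4); t1f.w = t1(t1row, 5);

    // joints: joint j connects body j (child) to body j-1 (parent; -1 = T1)
    for (int j = 0; j < nb; ++j) {
      const Frame& pf = (j == 0) ? t1f : s[j - 1];
      const Frame& cf = s[j];
      double ppx, ppz, pvx, pvz, cpx, cpz, cvx, cvz;
      anchor_world(pf, anchor_p(j, 0), anchor_p(j, 1), ppx, ppz, pvx, pvz);
      anchor_world(cf, anchor_c(j, 0), anchor_c(j, 1), cpx, cpz, cvx, cvz);
      double dx = cpx - ppx, dz = cpz - ppz;
      double dvx = cvx - pvx, dvz = cvz - pvz;
      double Fx = -kt[j] * dx - df * ct[j] * dvx;
      double Fz = -kt[j] * dz - df * ct[j] * dvz;
      double phi = cf.th - pf.th - neutral[j];
      double tau = -kr[j] * phi - df * cr[j] * (cf.w - pf.w);
      fx[j] += Fx; fz[j] += Fz;
      tq[j] += (cpx - cf.x) * Fz - (cpz - cf.z) * Fx + tau;
      if (j > 0) {
        fx[j - 1] -= Fx; fz[j - 1] -= Fz;
        tq[j - 1] -= (ppx - pf.x) * Fz - (ppz - pf.z) * Fx + tau;
      }
    }

    // muscles
    for (int k = 0; k < nm; ++k) {
      int ba = mus_body(k, 0), bb = mus_body(k, 1);  // -1 = T1
      const Frame& fa = (ba < 0) ? t1f : s[ba];
      const Frame& fb = (bb < 0) ? t1f : s[bb];
      double apx, apz, avx, avz, bpx, bpz, bvx, bvz;
      anchor_world(fa, mus_a(k, 0), mus_a(k, 1), apx, apz, avx, avz);
      anchor_world(fb, mus_b(k, 0), mus_b(k, 1), bpx, bpz, bvx, bvz);
      double dx = bpx - apx, dz = bpz - apz;
      double l = std::sqrt(dx * dx + dz * dz);
      if (l < 1e-9) { if (record_fmus) fmus_now[k] = 0; continue; }
      double ux = dx / l, uz = dz / l;
      double ldot = (bvx - avx) * ux + (bvz - avz) * uz;
      double lam = l / mus_l0[k];
      double act = (mus_group[k] == 0) ? a_flex : a_ext;
      double sig = act * mc.sigma_max * fl_factor(lam, mc.fl_width) *
                     fv_factor(ldot / (mus_l0[k] * mc.v_max),
                               mc.fv_shape, mc.fv_ecc) +
                   passive_sigma(lam, mc.k_p, mc.c_p) +
                   mc.pde_coeff * ldot / mus_l0[k];
      double F = mus_pcsa[k] * sig;
      if (F < 0) F = 0;
      if (record_fmus) fmus_now[k] = F;
      // tension pulls the endpoints toward each other
      double Fax = F * ux, Faz = F * uz;
      if (ba >= 0) {
        fx[ba] += Fax; fz[ba] += Faz;
        tq[ba] += (apx - fa.x) * Faz - (apz - fa.z) * Fax;
      }
      if (bb >= 0) {
        fx[bb] -= Fax; fz[bb] -= Faz;
        tq[bb] -= (bpx - fb.x) * Faz - (bpz - fb.z) * Fax;
      }
    }

    for (int b = 0; b < nb; ++b) {
      ax[b] = fx[b] / mass[b];
      az[b] = fz[b] / mass[b];
      aw[b] = tq[b] / inertia[b];
    }
    return std::make_pair(a_flex, a_ext);
  };

  int orow = 0;
  for (int i = 0; i <= nsteps; ++i) {
    double t = t_start + i * dt;

    if (!ref_captured && t >= -1e-9) {
      theta_ref = st[head].th;
      ref_captured = true;
    }
    if (ref_captured) e_hist.push_back(st[head].th - theta_ref);

    double u = pd_u(t);
    std::pair<double, double> acts =
      compute_accel(st, i, t, u, i % out_every == 0);

    if (i % out_every == 0) {
      out_t[orow] = t;
      for (int b = 0; b < nb; ++b) {
        out_state(orow, b * 6 + 0) = st[b].x;
        out_state(orow, b * 6 + 1) = st[b].z;
        out_state(orow, b * 6 + 2) = st[b].th;
        out_state(orow, b * 6 + 3) = st[b].vx;
        out_state(orow, b * 6 + 4) = st[b].vz;
        out_state(orow, b * 6 + 5) = st[b].w;
      }
      for (int c = 0; c < 6; ++c) out_t1(orow, c) = t1(i, c);
      out_head_ax[orow] = ax[head];
      out_u[orow] = u;
      out_aflex[orow] = acts.first;
      out_aext[orow] = acts.second;
      for (int k = 0; k < nm; ++k) out_fmus(orow, k) = fmus_now[k];
      ++orow;
    }

    if (i == nsteps) break;

    // kick-drift-kick
    std::vector<Frame> half = st;
    for (int b = 0; b < nb; ++b) {
      half[b].vx = st[b].vx + 0.5 * dt * ax[b];
      half[b].vz = st[b].vz + 0.5 * dt * az[b];
      half[b].w  = st[b].w + 0.5 * dt * aw[b];
      half[b].x  = st[b].x + dt * half[b].vx;
      half[b].z  = st[b].z + dt * half[b].vz;
      half[b].th = st[b].th + dt * half[b].w;
    }
    compute_accel(half, i + 1, t + dt, u, false);
    for (int b = 0; b < nb; ++b) {
      st[b] = half[b];
      st[b].vx += 0.5 * dt * ax[b];
      st[b].vz += 0.5 * dt * az[b];
      st[b].w  += 0.5 * dt * aw[b];
    }

    if (i % 50 == 0 || i == nsteps - 1) {
      for (int b = 0; b < nb; ++b) {
        if (!std::isfinite(st[b].x) || !std::isfinite(st[b].z) ||
            !std::isfinite(st[b].th) || !std::isfinite(st[b].vx) ||
            !std::isfinite(st[b].vz) || !std::isfinite(st[b].w)) {
          ok = false; bad_t = t + dt; bad_body = b + 1;
          break;
        }
      }
      if (!ok) break;
    }
  }

  return List::create(
    _["ok"] = ok, _["bad_t"] = bad_t, _["bad_body"] = bad_body,
    _["t"] = out_t, _["state"] = out_state, _["t1"] = out_t1,
    _["head_ax"] = out_head_ax, _["u"] = out_u,
    _["a_flex"] = out_aflex, _["a_ext"] = out_aext,
    _["f_muscle"] = out_fmus, _["theta_ref"] = theta_ref,
    _["n_recorded"] = orow);
}
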