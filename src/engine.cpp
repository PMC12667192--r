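// Planar 9-DOF musculoskeletal forward dynamics for split-belt treadmill
// walking: Hill-type muscles, Hunt-Crossley foot-belt contact with an
// imposed belt surface velocity, reflex controller with delayed feedback
// and a per-leg gait-phase state machine, semi-implicit Euler integration.
//
// Generalized coordinates (all SI, +x anterior, +y up, angles CCW+):
//   0 x_hip, 1 y_hip, 2 pelvis tilt, 3 hip_L, 4 knee_L, 5 ankle_L,
//   6 hip_R, 7 knee_R, 8 ankle_R
// Hip flexion positive (thigh forward), knee flexion positive (shank
// back relative to thigh), ankle dorsiflexion positive. Leg 0 = left
// (fast belt), leg 1 = right (slow belt).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

static const int NQ = 9;
static const int NM = 14;  // 7 per leg: HAM GLU IL VAS GAS SOL TA

// ---------- model ----------
struct Seg { double m, I; };

struct Model {
  // pelvis-trunk
  double m_p, I_p, comx_p, comy_p;
  // thigh / shank (per-side symmetric)
  double m_t, I_t, L_t, c_t;
  double m_s, I_s, L_s, c_s;
  // foot
  double m_f, I_f, comx_f, comy_f, heelx, heely, toex, toey, r_sph;
  // contact
  double ck, cn, cd, mu, vt;
  // joint limits per joint type (hip, knee, ankle): lo hi k w damp
  double jl[3][5];
  double grav;
  double min_exc;
  double basal_W;
  double total_m;
  // muscles
  double Fmax[NM], lopt[NM], lslack[NM], vmax[NM]; // vmax in lopt/s
  double r_hip[NM], r_knee[NM], r_ankle[NM];
  int side[NM];
  double lmt_ref[NM];
  double qref[3]; // hip knee ankle reference angles
};

static Model parse_model(const List& ml) {
  Model M;
  NumericVector s = ml["seg"];
  M.m_p = s["m_pelvis"]; M.I_p = s["I_pelvis"];
  M.comx_p = s["comx_pelvis"]; M.comy_p = s["comy_pelvis"];
  M.m_t = s["m_thigh"]; M.I_t = s["I_thigh"];
  M.L_t = s["L_thigh"]; M.c_t = s["com_thigh"];
  M.m_s = s["m_shank"]; M.I_s = s["I_shank"];
  M.L_s = s["L_shank"]; M.c_s = s["com_shank"];
  M.m_f = s["m_foot"]; M.I_f = s["I_foot"];
  M.comx_f = s["comx_foot"]; M.comy_f = s["comy_foot"];
  M.heelx = s["heelx"]; M.heely = s["heely"];
  M.toex = s["toex"]; M.toey = s["toey"]; M.r_sph = s["r_sphere"];
  NumericVector c = ml["contact"];
  M.ck = c["k"]; M.cn = c["n"]; M.cd = c["c_d"]; M.mu = c["mu"];
  M.vt = c["v_t"];
  NumericMatrix jl = ml["limits"];
  for (int j = 0; j < 3; j++)
    for (int k = 0; k < 5; k++) M.jl[j][k] = jl(j, k);
  M.grav = as<double>(ml["grav"]);
  M.min_exc = as<double>(ml["min_exc"]);
  M.basal_W = as<double>(ml["basal_W"]);
  M.total_m = M.m_p + 2 * (M.m_t + M.m_s + M.m_f);
  NumericMatrix mm = ml["muscles"];
  NumericVector qr = ml["qref"];
  for (int i = 0; i < 3; i++) M.qref[i] = qr[i];
  for (int i = 0; i < NM; i++) {
    M.Fmax[i] = mm(i, 0); M.lopt[i] = mm(i, 1); M.lslack[i] = mm(i, 2);
    M.vmax[i] = mm(i, 3); M.r_hip[i] = mm(i, 4); M.r_knee[i] = mm(i, 5);
    M.r_ankle[i] = mm(i, 6); M.side[i] = (int)mm(i, 7);
    M.lmt_ref[i] = M.lopt[i] + M.lslack[i];
  }
  return M;
}

// ---------- kinematics ----------
struct Kin {
  // points
  double hip[2], knee[2][2], ankle[2][2];
  double heel[2][2], toe[2][2], calcn[2][2];
  // absolute segment angles
  double th_p, th_t[2], th_s[2], th_f[2];
  // COMs
  double com_p[2], com_t[2][2], com_s[2][2], com_f[2][2];
  double com[2]; // whole body
};

static inline void rot(double a, double x, double y, double* ox, double* oy) {
  double ca = std::cos(a), sa = std::sin(a);
  *ox = ca * x - sa * y; *oy = sa * x + ca * y;
}

static void fk(const Model& M, const double* q, Kin& K) {
  K.hip[0] = q[0]; K.hip[1] = q[1];
  K.th_p = q[2];
  double cx, cy;
  rot(K.th_p, M.comx_p, M.comy_p, &cx, &cy);
  K.com_p[0] = K.hip[0] + cx; K.com_p[1] = K.hip[1] + cy;
  double msum = M.m_p;
  K.com[0] = M.m_p * K.com_p[0]; K.com[1] = M.m_p * K.com_p[1];
  for (int lg = 0; lg < 2; lg++) {
    int o = 3 + 3 * lg;
    double th_t = q[2] + q[o];            // thigh absolute
    double th_s = th_t - q[o + 1];        // knee flexion positive
    double th_f = th_s + q[o + 2];        // ankle dorsiflexion positive
    K.th_t[lg] = th_t; K.th_s[lg] = th_s; K.th_f[lg] = th_f;
    double ut[2] = { std::sin(th_t), -std::cos(th_t) };
    double us[2] = { std::sin(th_s), -std::cos(th_s) };
    for (int d = 0; d < 2; d++) {
      K.knee[lg][d] = K.hip[d] + M.L_t * ut[d];
      K.com_t[lg][d] = K.hip[d] + M.c_t * ut[d];
    }
    for (int d = 0; d < 2; d++) {
      K.ankle[lg][d] = K.knee[lg][d] + M.L_s * us[d];
      K.com_s[lg][d] = K.knee[lg][d] + M.c_s * us[d];
    }
    double hx, hy, tx, ty, fx, fy;
    rot(th_f, M.heelx, M.heely, &hx, &hy);
    rot(th_f, M.toex, M.toey, &tx, &ty);
    rot(th_f, M.comx_f, M.comy_f, &fx, &fy);
    K.heel[lg][0] = K.ankle[lg][0] + hx; K.heel[lg][1] = K.ankle[lg][1] + hy;
    K.toe[lg][0] = K.ankle[lg][0] + tx; K.toe[lg][1] = K.ankle[lg][1] + ty;
    K.com_f[lg][0] = K.ankle[lg][0] + fx; K.com_f[lg][1] = K.ankle[lg][1] + fy;
    K.calcn[lg][0] = K.heel[lg][0]; K.calcn[lg][1] = K.heel[lg][1];
    K.com[0] += M.m_t * K.com_t[lg][0] + M.m_s * K.com_s[lg][0] +
                M.m_f * K.com_f[lg][0];
    K.com[1] += M.m_t * K.com_t[lg][1] + M.m_s * K.com_s[lg][1] +
                M.m_f * K.com_f[lg][1];
    msum += M.m_t + M.m_s + M.m_f;
  }
  K.com[0] /= msum; K.com[1] /= msum;
}

// angular-weight rows (which q drive each body's rotation, with sign)
// body ids: 0 pelvis; per leg lg: 1+3*lg thigh, 2+3*lg shank, 3+3*lg foot
static void body_weights(int body, double* w) {
  for (int j = 0; j < NQ; j++) w[j] = 0.0;
  if (body == 0) { w[2] = 1; return; }
  int lg = (body - 1) / 3, part = (body - 1) % 3;
  int o = 3 + 3 * lg;
  w[2] = 1; w[o] = 1;
  if (part >= 1) w[o + 1] = -1;
  if (part >= 2) w[o + 2] = 1;
}

// rotation origin of dof j for a point on body `body` (joint points)
// dof 2 and hip dofs rotate about the hip point, knee dofs about the
// knee, ankle dofs about the ankle.

struct DynWork {
  double Mmat[NQ][NQ];
  double Q[NQ];
};

// velocity of a material point on body `body` located at p, given joint
// point velocities computed alongside.
struct Vel {
  double v_hip[2], v_knee[2][2], v_ankle[2][2];
  double w_p, w_t[2], w_s[2], w_f[2]; // absolute angular velocities
};

static void velocities(const Model& M, const Kin& K, const double* qd,
                       Vel& V) {
  V.v_hip[0] = qd[0]; V.v_hip[1] = qd[1];
  V.w_p = qd[2];
  for (int lg = 0; lg < 2; lg++) {
    int o = 3 + 3 * lg;
    V.w_t[lg] = qd[2] + qd[o];
    V.w_s[lg] = V.w_t[lg] - qd[o + 1];
    V.w_f[lg] = V.w_s[lg] + qd[o + 2];
    // v = v_parent + w x r
    V.v_knee[lg][0] = V.v_hip[0] - V.w_t[lg] * (K.knee[lg][1] - K.hip[1]);
    V.v_knee[lg][1] = V.v_hip[1] + V.w_t[lg] * (K.knee[lg][0] - K.hip[0]);
    V.v_ankle[lg][0] = V.v_knee[lg][0] - V.w_s[lg] * (K.ankle[lg][1] - K.knee[lg][1]);
    V.v_ankle[lg][1] = V.v_knee[lg][1] + V.w_s[lg] * (K.ankle[lg][0] - K.knee[lg][0]);
  }
}

static inline void point_vel(const Vel& V, const Kin& K, int body,
                             const double* p, double* v) {
  if (body == 0) {
    v[0] = V.v_hip[0] - V.w_p * (p[1] - K.hip[1]);
    v[1] = V.v_hip[1] + V.w_p * (p[0] - K.hip[0]);
    return;
  }
  int lg = (body - 1) / 3, part = (body - 1) % 3;
  if (part == 0) {
    v[0] = V.v_hip[0] - V.w_t[lg] * (p[1] - K.hip[1]);
    v[1] = V.v_hip[1] + V.w_t[lg] * (p[0] - K.hip[0]);
  } else if (part == 1) {
    v[0] = V.v_knee[lg][0] - V.w_s[lg] * (p[1] - K.knee[lg][1]);
    v[1] = V.v_knee[lg][1] + V.w_s[lg] * (p[0] - K.knee[lg][0]);
  } else {
    v[0] = V.v_ankle[lg][0] - V.w_f[lg] * (p[1] - K.ankle[lg][1]);
    v[1] = V.v_ankle[lg][1] + V.w_f[lg] * (p[0] - K.ankle[lg][0]);
  }
}

// ---------- muscle mechanics ----------
static inline double act_fl(double ln) {
  double d = ln - 1.0;
  return std::exp(-d * d / 0.10);
}
static inline double f_pe(double ln) {
  if (ln <= 1.0) return 0.0;
  double d = (ln - 1.0) / 0.56;
  return d * d;
}
static inline double f_tendon(double eps) {
  if (eps <= 0.0) return 0.0;
  double f = (eps / 0.04) * (eps / 0.04);
  return f > 10.0 ? 10.0 : f;
}
// inverse force-velocity: given required fv in [0, 1.5), return vtilde
// (fiber velocity in vmax units, shortening negative)
static inline double fv_inv(double f) {
  const double af = 0.25, flen = 1.5, b2 = (flen - 1.0) / 5.0;
  if (f < 0.0) f = 0.0;
  if (f <= 1.0) return (f - 1.0) / (1.0 + f / af);
  if (f > flen - 1e-3) f = flen - 1e-3;
  double v = b2 * (f - 1.0) / (flen - f);
  return v > 1.5 ? 1.5 : v;
}

// one muscle step; returns normalized tendon force, updates a and ln
static inline double muscle_advance(const Model& M, int i, double u,
                                    double* a, double* ln, double lmt,
                                    double dt, double* vtilde_out) {
  double ua = u < M.min_exc ? M.min_exc : (u > 1.0 ? 1.0 : u);
  double tau = (ua > *a) ? 0.01 : 0.04;
  *a += dt * (ua - *a) / tau;
  *a = *a < 0.0 ? 0.0 : (*a > 1.0 ? 1.0 : *a);
  double lce = *ln * M.lopt[i];
  double lt = lmt - lce;
  double eps = lt / M.lslack[i] - 1.0;
  double ft = f_tendon(eps);
  double denom = (*a) * act_fl(*ln);
  if (denom < 0.01) denom = 0.01;
  double fvreq = (ft - f_pe(*ln)) / denom;
  double vt = fv_inv(fvreq);
  *ln += vt * M.vmax[i] * dt;
  *ln = *ln < 0.3 ? 0.3 : (*ln > 1.8 ? 1.8 : *ln);
  if (vtilde_out) *vtilde_out = vt;
  return ft;
}

static inline double mtu_length(const Model& M, int i, const double* q) {
  int o = 3 + 3 * M.side[i];
  return M.lmt_ref[i]
    - M.r_hip[i] * (q[o] - M.qref[0])
    - M.r_knee[i] * (q[o + 1] - M.qref[1])
    - M.r_ankle[i] * (q[o + 2] - M.qref[2]);
}

// metabolic rate of one muscle (Minetti-Alexander style shortening-heat
// curve; lengthening costed at the isometric level)
static inline double muscle_met(const Model& M, int i, double a,
                                double vtilde) {
  double vb = -vtilde;           // shortening positive
  if (vb < 0.0) vb = 0.0;
  if (vb > 0.95) vb = 0.95;
  double num = 0.054 + 0.506 * vb + 2.46 * vb * vb;
  double den = 1.0 - 1.13 * vb + 12.8 * vb * vb - 1.64 * vb * vb * vb;
  double phi = num / den;
  if (phi < 0.0) phi = 0.0;
  return a * M.Fmax[i] * (M.vmax[i] * M.lopt[i]) * phi;
}

// ---------- contact ----------
// returns force on the foot (fx, fy) for one sphere
static inline void sphere_force(const Model& M, double yc, double vx,
                                double vy, double belt_speed,
                                double* fx, double* fy) {
  *fx = 0.0; *fy = 0.0;
  double pen = M.r_sph - yc;
  if (pen <= 0.0) return;
  double pendot = -vy;
  double fn = M.ck * std::pow(pen, M.cn) * (1.0 + 1.5 * M.cd * pendot);
  if (fn < 0.0) fn = 0.0;
  // belt surface moves in -x at belt_speed
  double vrel = vx - (-belt_speed);
  *fy = fn;
  *fx = -M.mu * fn * std::tanh(vrel / M.vt);
}

// ---------- controller ----------
struct Laws {
  std::vector<int> target, kind, source, loadw, dsteps, pmask;
  std::vector<double> gain, offset;
  int n;
};
static Laws parse_laws(const List& ll, double dt) {
  Laws L;
  IntegerVector tg = ll["target"], kd = ll["kind"], sc = ll["source"],
    lw = ll["loadw"], pm = ll["pmask"];
  NumericVector g = ll["gain"], of = ll["offset"], dl = ll["delay"];
  L.n = tg.size();
  for (int i = 0; i < L.n; i++) {
    L.target.push_back(tg[i]); L.kind.push_back(kd[i]);
    L.source.push_back(sc[i]); L.loadw.push_back(lw[i]);
    L.pmask.push_back(pm[i]);
    L.gain.push_back(g[i]); L.offset.push_back(of[i]);
    L.dsteps.push_back((int)std::lround(dl[i] / dt));
  }
  return L;
}

// compute excitations from (already delayed) sensor values
static void excitations(const Laws& L, const int* phase,
                        const double* fnorm, const double* lnorm,
                        double tilt, double tiltvel,
                        const double* load,
                        const double* pd_kp, const double* pd_kd,
                        const double* pd_ref,
                        double min_exc, double* u) {
  for (int m = 0; m < NM; m++) u[m] = min_exc;
  for (int i = 0; i < L.n; i++) {
    int m = L.target[i];
    int lg = m < 7 ? 0 : 1;
    if (!((L.pmask[i] >> phase[lg]) & 1)) continue;
    double c = 0.0;
    switch (L.kind[i]) {
    case 0: { // force feedback from source muscle
      c = L.gain[i] * (fnorm[L.source[i]] - L.offset[i]);
      if (L.gain[i] >= 0 && c < 0) c = 0;
      if (L.gain[i] < 0 && c > 0) c = 0;
      break; }
    case 1: { // length feedback (stretch beyond offset)
      double s = lnorm[L.source[i]] - L.offset[i];
      if (s < 0) s = 0;
      c = L.gain[i] * s;
      break; }
    case 2: c = L.gain[i]; break; // constant
    case 3: { // trunk PD, forward-lean-positive signal, load-weighted
      double spd = pd_kp[lg] * (pd_ref[lg] - tilt) - pd_kd[lg] * tiltvel;
      c = L.gain[i] * spd;
      break; }
    default: Rcpp::stop("unknown reflex law kind");
    }
    if (L.loadw[i]) {
      double w = load[lg];
      w = w < 0 ? 0 : (w > 1 ? 1 : w);
      c *= w;
    }
    u[m] += c;
  }
  for (int m = 0; m < NM; m++) {
    if (u[m] < min_exc) u[m] = min_exc;
    if (u[m] > 1.0) u[m] = 1.0;
  }
}

// phases
enum { ES = 0, MS = 1, PS = 2, SW = 3, LP = 4 };

// ---------- ring buffer ----------
struct Ring {
  std::vector<double> buf;
  int head = 0, cap = 0, filled = 0;
  void init(int capacity, double v) {
    cap = capacity; buf.assign(cap, v); head = 0; filled = cap;
  }
  inline void push(double v) { head = (head + 1) % cap; buf[head] = v; }
  inline double at_delay(int d) const {
    if (d >= cap) d = cap - 1;
    int idx = head - d; if (idx < 0) idx += cap;
    return buf[idx];
  }
};

// ======================================================================
// exported single-operation helpers (the same primitives the loop uses)
// ======================================================================

// [[Rcpp::export]]
List cpp_fk(List model, NumericVector q) {
  Model M = parse_model(model);
  Kin K; fk(M, q.begin(), K);
  auto v2 = [](const double* p) { return NumericVector::create(p[0], p[1]); };
  List legs(2);
  for (int lg = 0; lg < 2; lg++) {
    // limb angle: vertical to (pelvis COM -> calcaneus COM), forward +
    double dx = K.calcn[lg][0] - K.com_p[0];
    double dy = K.calcn[lg][1] - K.com_p[1];
    double limb = std::atan2(dx, -dy);
    legs[lg] = List::create(
      _["knee"] = v2(K.knee[lg]), _["ankle"] = v2(K.ankle[lg]),
      _["heel"] = v2(K.heel[lg]), _["toe"] = v2(K.toe[lg]),
      _["calcn"] = v2(K.calcn[lg]), _["limb_angle"] = limb);
  }
  return List::create(_["hip"] = v2(K.hip), _["com"] = v2(K.com),
                      _["com_pelvis"] = v2(K.com_p), _["legs"] = legs);
}

// [[Rcpp::export]]
NumericVector cpp_mtu_lengths(List model, NumericVector q) {
  Model M = parse_model(model);
  NumericVector out(NM);
  for (int i = 0; i < NM; i++) out[i] = mtu_length(M, i, q.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_muscle_step(List model, int i, double excitation, double a,
                     double lce_norm, double lmt, double dt) {
  Model M = parse_model(model);
  if (!std::isfinite(excitation) || !std::isfinite(lmt) ||
      !std::isfinite(lce_norm))
    Rcpp::stop("muscle_step: non-finite input");
  if (dt <= 0) Rcpp::stop("muscle_step: dt must be > 0");
  double vt;
  double ft = muscle_advance(M, i - 1, excitation, &a, &lce_norm, lmt,
                             dt, &vt);
  return List::create(_["a"] = a, _["lce_norm"] = lce_norm,
                      _["f_tendon"] = ft * M.Fmax[i - 1],
                      _["vtilde"] = vt);
}

// isometric fiber equilibrium: solve f_t(lmt - lce) = a fl(ln) + fpe(ln)
// by bisection on ln
// [[Rcpp::export]]
double cpp_muscle_equilibrium(List model, int i, double a, double lmt) {
  Model M = parse_model(model);
  int k = i - 1;
  auto resid = [&](double ln) {
    double eps = (lmt - ln * M.lopt[k]) / M.lslack[k] - 1.0;
    return f_tendon(eps) - (a * act_fl(ln) + f_pe(ln));
  };
  double lo = 0.3, hi = 1.8;
  double flo = resid(lo), fhi = resid(hi);
  if (flo <= 0.0) return lo;      // even shortest fiber leaves tendon slack
  if (fhi >= 0.0) return hi;
  for (int it = 0; it < 200; it++) {
    double mid = 0.5 * (lo + hi);
    double fm = resid(mid);
    if (fm > 0) lo = mid; else hi = mid;
    if (hi - lo < 1e-12) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
NumericVector cpp_sphere_force(List model, double yc, double vx, double vy,
                               double belt_speed) {
  Model M = parse_model(model);
  double fx, fy;
  sphere_force(M, yc, vx, vy, belt_speed, &fx, &fy);
  return NumericVector::create(_["fx"] = fx, _["fy"] = fy);
}

// [[Rcpp::export]]
NumericVector cpp_excitations(List model, List laws, IntegerVector phase,
                              NumericVector fnorm, NumericVector lnorm,
                              double tilt, double tiltvel,
                              NumericVector load,
                              NumericVector pd_kp, NumericVector pd_kd,
                              NumericVector pd_ref) {
  Model M = parse_model(model);
  Laws L = parse_laws(laws, 1.0);
  double u[NM];
  int ph[2] = { phase[0], phase[1] };
  excitations(L, ph, fnorm.begin(), lnorm.begin(), tilt, tiltvel,
              load.begin(), pd_kp.begin(), pd_kd.begin(), pd_ref.begin(),
              M.min_exc, u);
  return NumericVector(u, u + NM);
}

// [[Rcpp::export]]
int cpp_update_phase(int phase, double elapsed, double t_threshold,
                     double load_ipsi, double load_contra,
                     double limb_angle, NumericVector smp,
                     bool heel_strike) {
  // smp: load_es_ms, load_ps_sw, sw_lp_angle
  if (heel_strike) return ES;
  switch (phase) {
  case ES: if (load_contra < smp[0]) return MS; break;
  case MS:
    if (elapsed >= t_threshold) return PS;
    // fallback: the foot has already unloaded well into stance (prevents
    // deadlock when t is never reached before lift-off conditions)
    if (elapsed > 0.25 && load_ipsi < smp[1] * 0.5) return PS;
    break;
  case PS: if (load_ipsi < smp[1]) return SW; break;
  case SW: if (limb_angle > smp[2]) return LP; break;
  case LP: break;
  }
  return phase;
}

// [[Rcpp::export]]
double cpp_metabolic_rate(List model, NumericVector a,
                          NumericVector vtilde) {
  Model M = parse_model(model);
  double E = M.basal_W;
  for (int i = 0; i < NM; i++) E += muscle_met(M, i, a[i], vtilde[i]);
  return E;
}

// ======================================================================
// main simulation loop
// ======================================================================

// assemble mass matrix and generalized forces, solve for qdd
static void solve_dynamics(const Model& M, const double* q, const double* qd,
                           const double tau[NQ],
                           const double contactF[2][2][2], // [leg][sphere]{fx,fy}
                           const Kin& K, const Vel& V,
                           const std::vector<int>& free_idx,
                           double* qdd) {
  double A[NQ][NQ]; double b[NQ];
  for (int i = 0; i < NQ; i++) { b[i] = tau[i];
    for (int j = 0; j < NQ; j++) A[i][j] = 0.0; }

  struct BodyDef { int body; double m, I; const double* p; };
  BodyDef bodies[7] = {
    {0, M.m_p, M.I_p, K.com_p},
    {1, M.m_t, M.I_t, K.com_t[0]}, {2, M.m_s, M.I_s, K.com_s[0]},
    {3, M.m_f, M.I_f, K.com_f[0]},
    {4, M.m_t, M.I_t, K.com_t[1]}, {5, M.m_s, M.I_s, K.com_s[1]},
    {6, M.m_f, M.I_f, K.com_f[1]}
  };

  for (int bI = 0; bI < 7; bI++) {
    const BodyDef& B = bodies[bI];
    double w[NQ]; body_weights(B.body, w);
    // Jacobian of the COM point + convective acceleration
    double J[2][NQ]; double aconv[2] = {0, 0};
    for (int j = 0; j < NQ; j++) { J[0][j] = 0; J[1][j] = 0; }
    J[0][0] = 1; J[1][1] = 1;
    // origins and their velocities per dof
    double pv[2]; point_vel(V, K, B.body, B.p, pv);
    for (int j = 2; j < NQ; j++) {
      if (w[j] == 0.0) continue;
      const double* o; double ov[2];
      if (j == 2) { o = K.hip; ov[0] = V.v_hip[0]; ov[1] = V.v_hip[1]; }
      else {
        int lg = (j - 3) / 3, part = (j - 3) % 3;
        if (part == 0) { o = K.hip; ov[0] = V.v_hip[0]; ov[1] = V.v_hip[1]; }
        else if (part == 1) { o = K.knee[lg]; ov[0] = V.v_knee[lg][0]; ov[1] = V.v_knee[lg][1]; }
        else { o = K.ankle[lg]; ov[0] = V.v_ankle[lg][0]; ov[1] = V.v_ankle[lg][1]; }
      }
      double rx = B.p[0] - o[0], ry = B.p[1] - o[1];
      J[0][j] = -w[j] * ry;
      J[1][j] = w[j] * rx;
      double drx = pv[0] - ov[0], dry = pv[1] - ov[1];
      aconv[0] += qd[j] * (-w[j] * dry);
      aconv[1] += qd[j] * (w[j] * drx);
    }
    // mass matrix
    for (int i = 0; i < NQ; i++) {
      if (J[0][i] == 0 && J[1][i] == 0 && w[i] == 0) continue;
      for (int j = i; j < NQ; j++) {
        double v = B.m * (J[0][i] * J[0][j] + J[1][i] * J[1][j]) +
                   B.I * w[i] * w[j];
        A[i][j] += v;
      }
    }
    // forces: gravity and bias
    double Fx = 0.0, Fy = -B.m * M.grav;
    for (int i = 0; i < NQ; i++) {
      b[i] += J[0][i] * (Fx - B.m * aconv[0]) +
              J[1][i] * (Fy - B.m * aconv[1]);
    }
  }
  // contact forces at sphere centers (foot bodies)
  for (int lg = 0; lg < 2; lg++) {
    int body = 3 + 3 * lg;
    double w[NQ]; body_weights(body, w);
    const double* pts[2] = { K.heel[lg], K.toe[lg] };
    for (int s = 0; s < 2; s++) {
      double fx = contactF[lg][s][0], fy = contactF[lg][s][1];
      if (fx == 0.0 && fy == 0.0) continue;
      const double* p = pts[s];
      b[0] += fx; b[1] += fy;
      for (int j = 2; j < NQ; j++) {
        if (w[j] == 0.0) continue;
        const double* o;
        if (j == 2) o = K.hip;
        else {
          int l2 = (j - 3) / 3, part = (j - 3) % 3;
          if (part == 0) o = K.hip;
          else if (part == 1) o = K.knee[l2];
          else o = K.ankle[l2];
        }
        double rx = p[0] - o[0], ry = p[1] - o[1];
        b[j] += fx * (-w[j] * ry) + fy * (w[j] * rx);
      }
    }
  }
  // symmetrize
  for (int i = 0; i < NQ; i++)
    for (int j = 0; j < i; j++) A[i][j] = A[j][i];

  // Cholesky solve on the free dofs
  int n = (int)free_idx.size();
  double L[NQ][NQ]; double y[NQ];
  for (int i = 0; i < n; i++) {
    for (int j = 0; j <= i; j++) {
      double s = A[free_idx[i]][free_idx[j]];
      for (int k = 0; k < j; k++) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 1e-12) s = 1e-12;
        L[i][i] = std::sqrt(s);
      } else L[i][j] = s / L[j][j];
    }
  }
  for (int i = 0; i < n; i++) {
    double s = b[free_idx[i]];
    for (int k = 0; k < i; k++) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  double xs[NQ];
  for (int i = n - 1; i >= 0; i--) {
    double s = y[i];
    for (int k = i + 1; k < n; k++) s -= L[k][i] * xs[k];
    xs[i] = s / L[i][i];
  }
  for (int i = 0; i < NQ; i++) qdd[i] = 0.0;
  for (int i = 0; i < n; i++) qdd[free_idx[i]] = xs[i];
}

// passive joint torques; returns knee limit torque magnitude via out
static inline double joint_passive(const Model& M, int jtype, double q,
                                   double qd, double* limit_mag) {
  const double* p = M.jl[jtype];
  double lo = p[0], hi = p[1], k = p[2], w = p[3], d = p[4];
  double tl = k * (std::exp((lo - q) / w) - std::exp((q - hi) / w));
  // cap to avoid overflow in pathological states
  tl = tl > 1e4 ? 1e4 : (tl < -1e4 ? -1e4 : tl);
  if (limit_mag) *limit_mag = std::fabs(tl);
  return tl - d * qd;
}

// [[Rcpp::export]]
List cpp_simulate(List model, List laws, NumericVector sm_left,
                  NumericVector sm_right, NumericVector pd_kp,
                  NumericVector pd_kd, NumericVector pd_ref,
                  NumericVector t_thresholds, // (left, right)
                  double duration, NumericVector belt_speeds, // (left,right)
                  List numcfg,
                  NumericVector q0, NumericVector qd0,
                  NumericVector a0, NumericVector lce0,
                  IntegerVector phase0, NumericVector elapsed0,
                  Nullable<Function> hs_callback) {
  Model M = parse_model(model);
  double dt = as<double>(numcfg["dt"]);
  double out_dt = as<double>(numcfg["out_dt"]);
  double hs_thresh = as<double>(numcfg["hs_threshold"]);
  double refractory = as<double>(numcfg["refractory"]);
  double com_frac = as<double>(numcfg["com_frac"]);
  double drift_max = as<double>(numcfg["drift_max"]);
  bool record = as<bool>(numcfg["record"]);
  IntegerVector fixed = numcfg.containsElementNamed("fixed_dofs") ?
    as<IntegerVector>(numcfg["fixed_dofs"]) : IntegerVector(0);
  Laws L = parse_laws(laws, dt);

  std::vector<int> free_idx;
  for (int i = 0; i < NQ; i++) {
    bool isfix = false;
    for (int k = 0; k < fixed.size(); k++)
      if (fixed[k] - 1 == i) isfix = true;
    if (!isfix) free_idx.push_back(i);
  }

  double q[NQ], qd[NQ];
  for (int i = 0; i < NQ; i++) { q[i] = q0[i]; qd[i] = qd0[i]; }
  double a[NM], ln[NM], vt[NM];
  for (int i = 0; i < NM; i++) { a[i] = a0[i]; ln[i] = lce0[i]; vt[i] = 0; }
  int phase[2] = { phase0[0], phase0[1] };
  double t_thr[2] = { t_thresholds[0], t_thresholds[1] };
  double t_hs[2] = { -elapsed0[0], -elapsed0[1] };  // last HS time per leg
  double last_hs_any[2] = { -1e9, -1e9 };

  Kin K; fk(M, q, K);
  double com0x = K.com[0], com0y = K.com[1];
  // body-weight normalization for leg loads (gravity-free test models
  // fall back to standard gravity to keep the ratio finite)
  double weight_norm = M.total_m * (M.grav > 1e-6 ? M.grav : 9.81);

  // delay buffers
  int maxd = 1;
  for (int i = 0; i < L.n; i++) if (L.dsteps[i] > maxd) maxd = L.dsteps[i];
  maxd += 1;
  std::vector<Ring> rF(NM), rL(NM);
  Ring rTilt, rTiltV, rLoad[2];
  {
    // initial sensor values
    for (int i = 0; i < NM; i++) {
      double eps = (mtu_length(M, i, q) - ln[i] * M.lopt[i]) / M.lslack[i] - 1.0;
      rF[i].init(maxd, f_tendon(eps));
      rL[i].init(maxd, ln[i]);
    }
    rTilt.init(maxd, q[2]); rTiltV.init(maxd, qd[2]);
    rLoad[0].init(maxd, phase[0] <= PS ? 1.0 : 0.0);
    rLoad[1].init(maxd, phase[1] <= PS ? 1.0 : 0.0);
  }

  int nsteps = (int)std::llround(duration / dt);
  int out_every = (int)std::llround(out_dt / dt);
  if (out_every < 1) out_every = 1;
  int nout = nsteps / out_every + 2;

  NumericVector o_time(record ? nout : 0);
  NumericMatrix o_q(record ? nout : 0, NQ), o_qd(record ? nout : 0, NQ);
  NumericMatrix o_act(record ? nout : 0, NM);
  NumericMatrix o_grf(record ? nout : 0, 4); // fyL fxL fyR fxR
  NumericMatrix o_calcn(record ? nout : 0, 2); // x positions
  NumericMatrix o_limb(record ? nout : 0, 2);
  IntegerMatrix o_phase(record ? nout : 0, 2);
  NumericMatrix o_exc(record ? nout : 0, NM);
  int iout = 0;

  std::vector<double> ev_time; std::vector<int> ev_leg, ev_type;
  std::vector<double> st_time, st_l, st_d; std::vector<int> st_leg;
  std::vector<double> comx_hs[2];

  double E_int = 0.0, act3_int = 0.0, ub_time = 0.0;
  double ankle_int = 0.0, kneeT_int = 0.0;

  int stop_reason = 0; // 0 completed 1 fell 2 drifted 3 nonfinite
  double t = 0.0;
  double grf_now[4] = {0, 0, 0, 0};
  double heel_prev[2] = {1e9, 1e9}, tot_prev[2] = {1e9, 1e9};

  bool has_cb = hs_callback.isNotNull();
  Function cb = has_cb ? Function(hs_callback.get())
                       : Function(Rf_findFun(Rf_install("identity"),
                                             R_BaseEnv));

  for (int step = 0; step <= nsteps; step++) {
    t = step * dt;
    fk(M, q, K);
    Vel V; velocities(M, K, qd, V);

    // ---- contact ----
    double contactF[2][2][2];
    double legload[2];
    for (int lg = 0; lg < 2; lg++) {
      const double* pts[2] = { K.heel[lg], K.toe[lg] };
      double tot = 0.0;
      for (int s = 0; s < 2; s++) {
        double pv[2]; point_vel(V, K, 3 + 3 * lg, pts[s], pv);
        double fx, fy;
        sphere_force(M, pts[s][1], pv[0], pv[1], belt_speeds[lg], &fx, &fy);
        contactF[lg][s][0] = fx; contactF[lg][s][1] = fy;
        tot += fy;
      }
      legload[lg] = tot / weight_norm;
    }
    grf_now[0] = contactF[0][0][1] + contactF[0][1][1];
    grf_now[1] = contactF[0][0][0] + contactF[0][1][0];
    grf_now[2] = contactF[1][0][1] + contactF[1][1][1];
    grf_now[3] = contactF[1][0][0] + contactF[1][1][0];

    // ---- events: heel strike / toe off ----
    for (int lg = 0; lg < 2; lg++) {
      double heel_f = contactF[lg][0][1];
      double tot_f = contactF[lg][0][1] + contactF[lg][1][1];
      // rising heel force across threshold with refractory, only after
      // the leg has actually been airborne-ish (swing or late phases)
      bool rising = heel_f > hs_thresh && heel_prev[lg] <= hs_thresh;
      if (rising && t - last_hs_any[lg] > refractory &&
          (phase[lg] == SW || phase[lg] == LP ||
           t - last_hs_any[lg] > 0.4)) {
        // heel strike
        ev_time.push_back(t); ev_leg.push_back(lg); ev_type.push_back(0);
        int other = 1 - lg;
        double l = K.calcn[lg][0] - K.calcn[other][0];
        double d = t - last_hs_any[other];
        bool valid = last_hs_any[other] > -1e8 && d > 0;
        last_hs_any[lg] = t;
        t_hs[lg] = t;
        phase[lg] = ES;
        comx_hs[lg].push_back(K.com[0]);
        if (valid) {
          st_time.push_back(t); st_leg.push_back(lg);
          st_l.push_back(l); st_d.push_back(d);
          if (has_cb && l > 0 && d > 0.1) {
            NumericVector thr = cb(lg, l, d);
            t_thr[0] = thr[0]; t_thr[1] = thr[1];
          }
        }
      }
      // toe off: total foot force falls through the threshold
      if (tot_f < hs_thresh && tot_prev[lg] >= hs_thresh &&
          t - last_hs_any[lg] > refractory) {
        ev_time.push_back(t); ev_leg.push_back(lg); ev_type.push_back(1);
      }
      heel_prev[lg] = heel_f; tot_prev[lg] = tot_f;
    }

    // ---- phase machine ----
    for (int lg = 0; lg < 2; lg++) {
      double limb = std::atan2(K.calcn[lg][0] - K.com_p[0],
                               -(K.calcn[lg][1] - K.com_p[1]));
      NumericVector smp = lg == 0 ? sm_left : sm_right;
      phase[lg] = cpp_update_phase(phase[lg], t - t_hs[lg], t_thr[lg],
                                   legload[lg], legload[1 - lg], limb, smp,
                                   false);
    }

    // ---- controller (delayed sensors) ----
    double u[NM];
    {
      // evaluate laws directly with per-law delayed sensor reads
      for (int m = 0; m < NM; m++) u[m] = M.min_exc;
      for (int i = 0; i < L.n; i++) {
        int m = L.target[i];
        int lg = m < 7 ? 0 : 1;
        if (!((L.pmask[i] >> phase[lg]) & 1)) continue;
        double c = 0.0;
        int dstep = L.dsteps[i];
        switch (L.kind[i]) {
        case 0: {
          double f = rF[L.source[i]].at_delay(dstep);
          c = L.gain[i] * (f - L.offset[i]);
          if (L.gain[i] >= 0 && c < 0) c = 0;
          if (L.gain[i] < 0 && c > 0) c = 0;
          break; }
        case 1: {
          double s = rL[L.source[i]].at_delay(dstep) - L.offset[i];
          if (s < 0) s = 0;
          c = L.gain[i] * s;
          break; }
        case 2: c = L.gain[i]; break;
        case 3: {
          double tilt = rTilt.at_delay(dstep);
          double tv = rTiltV.at_delay(dstep);
          double spd = pd_kp[lg] * (pd_ref[lg] - tilt) - pd_kd[lg] * tv;
          c = L.gain[i] * spd;
          break; }
        }
        if (L.loadw[i]) {
          double w = rLoad[lg].at_delay(dstep);
          w = w < 0 ? 0 : (w > 1 ? 1 : w);
          c *= w;
        }
        u[m] += c;
      }
      for (int m = 0; m < NM; m++) {
        if (u[m] < M.min_exc) u[m] = M.min_exc;
        if (u[m] > 1.0) u[m] = 1.0;
      }
    }

    // ---- muscles ----
    double tau[NQ];
    for (int i = 0; i < NQ; i++) tau[i] = 0.0;
    double met_now = M.basal_W, act3_now = 0.0;
    for (int i = 0; i < NM; i++) {
      double lmt = mtu_length(M, i, q);
      double ft = muscle_advance(M, i, u[i], &a[i], &ln[i], lmt, dt, &vt[i]);
      double F = ft * M.Fmax[i];
      int o = 3 + 3 * M.side[i];
      tau[o] += M.r_hip[i] * F;
      tau[o + 1] += M.r_knee[i] * F;
      tau[o + 2] += M.r_ankle[i] * F;
      met_now += muscle_met(M, i, a[i], vt[i]);
      act3_now += a[i] * a[i] * a[i];
      // sensor buffers (current values; delays applied on read)
      rF[i].push(ft);
      rL[i].push(ln[i]);
    }
    rTilt.push(q[2]); rTiltV.push(qd[2]);
    rLoad[0].push(legload[0]); rLoad[1].push(legload[1]);

    // ---- passive joint torques ----
    double kneeT_now = 0.0, ankle_now = 0.0;
    for (int lg = 0; lg < 2; lg++) {
      int o = 3 + 3 * lg;
      double lim;
      tau[o] += joint_passive(M, 0, q[o], qd[o], &lim);
      tau[o + 1] += joint_passive(M, 1, q[o + 1], qd[o + 1], &lim);
      kneeT_now += lim;
      tau[o + 2] += joint_passive(M, 2, q[o + 2], qd[o + 2], &lim);
      double adeg = q[o + 2] * 180.0 / M_PI;
      double P = adeg < -60 ? (-60 - adeg) : (adeg > 60 ? adeg - 60 : 0.0);
      ankle_now += P * P;
    }

    // ---- integrals ----
    E_int += met_now * dt;
    act3_int += act3_now * dt;
    if (std::fabs(qd[2]) > 10.0 * M_PI / 180.0) ub_time += dt;
    ankle_int += ankle_now * dt;
    kneeT_int += kneeT_now * dt;

    // ---- record ----
    if (record && step % out_every == 0 && iout < nout) {
      o_time[iout] = t;
      for (int i = 0; i < NQ; i++) { o_q(iout, i) = q[i]; o_qd(iout, i) = qd[i]; }
      for (int i = 0; i < NM; i++) o_act(iout, i) = a[i];
      for (int i = 0; i < 4; i++) o_grf(iout, i) = grf_now[i];
      o_calcn(iout, 0) = K.calcn[0][0]; o_calcn(iout, 1) = K.calcn[1][0];
      for (int lg = 0; lg < 2; lg++) {
        o_limb(iout, lg) = std::atan2(K.calcn[lg][0] - K.com_p[0],
                                      -(K.calcn[lg][1] - K.com_p[1])) *
          180.0 / M_PI;
        o_phase(iout, lg) = phase[lg];
      }
      for (int i = 0; i < NM; i++) o_exc(iout, i) = u[i];
      iout++;
    }

    // ---- early stopping ----
    if (K.com[1] < com_frac * com0y) { stop_reason = 1; break; }
    if (std::fabs(K.com[0] - com0x) > drift_max) { stop_reason = 2; break; }
    bool bad = false;
    for (int i = 0; i < NQ; i++)
      if (!std::isfinite(q[i]) || !std::isfinite(qd[i])) bad = true;
    if (bad) { stop_reason = 3; break; }
    if (step == nsteps) break;

    // ---- dynamics & integration ----
    double qdd[NQ];
    solve_dynamics(M, q, qd, tau, contactF, K, V, free_idx, qdd);
    for (int i = 0; i < NQ; i++) {
      qd[i] += qdd[i] * dt;
      q[i] += qd[i] * dt;
    }
  }

  double t_end = t > 1e-9 ? t : dt;
  if (record) {
    o_time = o_time[Range(0, iout - 1)];
    o_q = o_q(Range(0, iout - 1), _); o_qd = o_qd(Range(0, iout - 1), _);
    o_act = o_act(Range(0, iout - 1), _);
    o_grf = o_grf(Range(0, iout - 1), _);
    o_calcn = o_calcn(Range(0, iout - 1), _);
    o_limb = o_limb(Range(0, iout - 1), _);
    o_phase = o_phase(Range(0, iout - 1), _);
    o_exc = o_exc(Range(0, iout - 1), _);
  }
  return List::create(
    _["t_end"] = t_end,
    _["stop_reason"] = stop_reason,
    _["time"] = o_time, _["q"] = o_q, _["qd"] = o_qd, _["act"] = o_act,
    _["grf"] = o_grf, _["calcn_x"] = o_calcn, _["limb_deg"] = o_limb,
    _["phase"] = o_phase, _["exc"] = o_exc,
    _["ev_time"] = wrap(ev_time), _["ev_leg"] = wrap(ev_leg),
    _["ev_type"] = wrap(ev_type),
    _["st_time"] = wrap(st_time), _["st_leg"] = wrap(st_leg),
    _["st_l"] = wrap(st_l), _["st_d"] = wrap(st_d),
    _["comx_hs_left"] = wrap(comx_hs[0]),
    _["comx_hs_right"] = wrap(comx_hs[1]),
    _["met_rate_mean"] = E_int / t_end,
    _["act3_int"] = act3_int,
    _["ub_time_over"] = ub_time,
    _["ankle_P2_int"] = ankle_int,
    _["knee_T_int"] = kneeT_int,
    _["thresholds"] = NumericVector::create(t_thr[0], t_thr[1]),
    _["final_q"] = NumericVector(q, q + NQ),
    _["final_qd"] = NumericVector(qd, qd + NQ),
    _["final_a"] = NumericVector(a, a + NM),
    _["final_lce"] = NumericVector(ln, ln + NM),
    _["final_phase"] = IntegerVector::create(phase[0], phase[1]),
    _["final_elapsed"] = NumericVector::create(t - t_hs[0], t - t_hs[1]));
}
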