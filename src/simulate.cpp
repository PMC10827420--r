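#include "fibrenet.h"
using namespace Rcpp;

namespace {

struct Params {
  double l_fib, r_fib, a_rep, a_rest, a_align, blend;
  double d_max, d_eq, nu_link, nu_unlink, mu;
};

Params unpack_params(const List& p) {
  Params q;
  q.l_fib     = as<double>(p["l_fib"]);
  q.r_fib     = as<double>(p["r_fib"]);
  q.a_rep     = as<double>(p["alpha_rep"]);
  q.a_rest    = as<double>(p["alpha_rest"]);
  q.a_align   = as<double>(p["alpha_align"]);
  q.blend     = as<double>(p["align_blend"]);
  q.d_max     = as<double>(p["d_link_max"]);
  q.d_eq      = as<double>(p["d_link_eq"]);
  q.nu_link   = as<double>(p["nu_link"]);
  q.nu_unlink = as<double>(p["nu_unlink"]);
  q.mu        = as<double>(p["mu_fib"]);
  return q;
}

struct PairRec { int i, j; double s1, s2, d; double u[3]; };

// all pairs with segment distance <= cutoff (centre-distance prefiltered)
void pair_pass(int n, const double* X, const double* W, double h,
               double cutoff, const double* box, std::vector<PairRec>& out) {
  out.clear();
  double reach = cutoff + 2.0 * h;
  double reach2 = reach * reach;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d12[3];
      mi3(X + 3 * i, X + 3 * j, box, d12);
      if (dot3(d12, d12) > reach2) continue;
      SegClosest r = seg_closest(X + 3 * i, W + 3 * i, X + 3 * j, W + 3 * j,
                                 h, box);
      if (r.d <= cutoff) {
        PairRec pr; pr.i = i; pr.j = j; pr.s1 = r.s1; pr.s2 = r.s2; pr.d = r.d;
        pr.u[0] = r.u[0]; pr.u[1] = r.u[1]; pr.u[2] = r.u[2];
        out.push_back(pr);
      }
    }
  }
}

// Verlet candidate list: pairs within cutoff + skin.  As long as the
// accumulated endpoint motion since the rebuild stays below skin/2 per
// fibre, no pair outside the list can come within cutoff, so refreshing
// distances on the list alone reproduces the exact pair set.
struct VerletList {
  std::vector<std::pair<int,int>> cand;
  double acc = 0.0;     // accumulated max endpoint motion since rebuild
  double skin;
  bool valid = false;
  explicit VerletList(double skin_) : skin(skin_) {}

  void rebuild(int n, const double* X, const double* W, double h,
               double cutoff, const double* box) {
    cand.clear();
    double reach = cutoff + skin + 2.0 * h;
    double reach2 = reach * reach;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double d12[3];
        mi3(X + 3 * i, X + 3 * j, box, d12);
        if (dot3(d12, d12) > reach2) continue;
        SegClosest r = seg_closest(X + 3 * i, W + 3 * i,
                                   X + 3 * j, W + 3 * j, h, box);
        if (r.d <= cutoff + skin) cand.emplace_back(i, j);
      }
    }
    acc = 0.0;
    valid = true;
  }

  void pass(int n, const double* X, const double* W, double h,
            double cutoff, const double* box, std::vector<PairRec>& out) {
    if (!valid || acc >= 0.5 * skin) rebuild(n, X, W, h, cutoff, box);
    out.clear();
    for (const auto& c : cand) {
      SegClosest r = seg_closest(X + 3 * c.first, W + 3 * c.first,
                                 X + 3 * c.second, W + 3 * c.second, h, box);
      if (r.d <= cutoff) {
        PairRec pr; pr.i = c.first; pr.j = c.second;
        pr.s1 = r.s1; pr.s2 = r.s2; pr.d = r.d;
        pr.u[0] = r.u[0]; pr.u[1] = r.u[1]; pr.u[2] = r.u[2];
        out.push_back(pr);
      }
    }
  }
};

// Sum elementary forces and torques: Hertz-type repulsion over contacts,
// linear spring plus nematic alignment torque over crosslinks.
void accumulate(int n, const double* X, const double* W,
                const std::vector<PairRec>& pairs,
                const std::vector<int>& la, const std::vector<int>& lb,
                const std::vector<double>& sa, const std::vector<double>& sb,
                const Params& P, const double* box,
                double* F, double* T) {
  std::fill(F, F + 3 * n, 0.0);
  std::fill(T, T + 3 * n, 0.0);
  double two_r = 2.0 * P.r_fib;
  double sq2r = std::sqrt(two_r);

  if (P.a_rep > 0.0) {
    for (const PairRec& pr : pairs) {
      if (pr.d >= two_r) continue;
      double fmag = P.a_rep * sq2r * std::pow(two_r - pr.d, 1.5);
      double dir[3];
      if (pr.d > 1e-12) {
        for (int k = 0; k < 3; ++k) dir[k] = pr.u[k] / pr.d;
      } else {
        fallback_dir(pr.i, pr.j, dir);
      }
      // dir points from fibre i towards fibre j: push apart
      double f1[3], f2[3];
      for (int k = 0; k < 3; ++k) { f1[k] = -fmag * dir[k]; f2[k] = fmag * dir[k]; }
      double t1[3], t2[3];
      cross3(W + 3 * pr.i, f1, t1);
      cross3(W + 3 * pr.j, f2, t2);
      for (int k = 0; k < 3; ++k) {
        F[3 * pr.i + k] += f1[k];
        F[3 * pr.j + k] += f2[k];
        T[3 * pr.i + k] += pr.s1 * t1[k];
        T[3 * pr.j + k] += pr.s2 * t2[k];
      }
    }
  }

  int nl = (int)la.size();
  for (int l = 0; l < nl; ++l) {
    int a = la[l], b = lb[l];
    const double* wa = W + 3 * a;
    const double* wb = W + 3 * b;
    if (P.a_rest > 0.0) {
      double p1[3], p2[3], disp[3];
      for (int k = 0; k < 3; ++k) {
        p1[k] = X[3 * a + k] + sa[l] * wa[k];
        p2[k] = X[3 * b + k] + sb[l] * wb[k];
      }
      mi3(p1, p2, box, disp);
      double len = norm3(disp);
      double fmag = P.a_rest * (len - P.d_eq);
      double dir[3];
      if (len > 1e-12) {
        for (int k = 0; k < 3; ++k) dir[k] = disp[k] / len;
      } else {
        fallback_dir(a, b, dir);
      }
      // fmag > 0 (stretched): force on a towards b
      double f1[3], f2[3], t1[3], t2[3];
      for (int k = 0; k < 3; ++k) { f1[k] = fmag * dir[k]; f2[k] = -f1[k]; }
      cross3(wa, f1, t1);
      cross3(wb, f2, t2);
      for (int k = 0; k < 3; ++k) {
        F[3 * a + k] += f1[k];
        F[3 * b + k] += f2[k];
        T[3 * a + k] += sa[l] * t1[k];
        T[3 * b + k] += sb[l] * t2[k];
      }
    }
    if (P.a_align > 0.0) {
      double c = dot3(wa, wb);
      double sg = (c >= 0.0) ? 1.0 : -1.0;
      double g = P.a_align / (1.0 + P.blend) * (c + P.blend * sg);
      double nv[3];
      cross3(wa, wb, nv);
      for (int k = 0; k < 3; ++k) {
        T[3 * a + k] += g * nv[k];
        T[3 * b + k] -= g * nv[k];
      }
    }
  }
}

inline std::int64_t pair_key(int a, int b, int n) {
  return (std::int64_t)a * n + b;
}

} // namespace

// Per-fibre total force and torque for a full state + link table (1-based
// link indices).  Same elementary interactions as the integrator uses.
// [[Rcpp::export]]
List forces_cpp(NumericMatrix X, NumericMatrix W,
                IntegerVector la, IntegerVector lb,
                NumericVector sa, NumericVector sb,
                List params, NumericVector box) {
  Params P = unpack_params(params);
  int n = X.nrow();
  std::vector<double> Xc(3 * n), Wc(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { Xc[3*i+k] = X(i,k); Wc[3*i+k] = W(i,k); }
  std::vector<PairRec> pairs;
  double cutoff = std::max(2.0 * P.r_fib, P.d_max);
  pair_pass(n, Xc.data(), Wc.data(), 0.5 * P.l_fib, cutoff, REAL(box), pairs);
  std::vector<int> lav(la.begin(), la.end()), lbv(lb.begin(), lb.end());
  for (size_t l = 0; l < lav.size(); ++l) { --lav[l]; --lbv[l]; }
  std::vector<double> sav(sa.begin(), sa.end()), sbv(sb.begin(), sb.end());
  std::vector<double> F(3 * n), T(3 * n);
  accumulate(n, Xc.data(), Wc.data(), pairs, lav, lbv, sav, sbv, P,
             REAL(box), F.data(), T.data());
  NumericMatrix Fm(n, 3), Tm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { Fm(i, k) = F[3*i+k]; Tm(i, k) = T[3*i+k]; }
  return List::create(_["force"] = Fm, _["torque"] = Tm);
}

// Advance the coupled overdamped/jump system until t reaches t_target or
// max_steps accepted steps.  Per step: one pair pass; forces; adaptive dt
// capped so no fibre moves more than dx_max or turns more than dtheta_max;
// explicit Euler move with renormalised directions; then Bernoulli-thinned
// Poisson link/unlink events using the pre-move pair geometry.
// [[Rcpp::export]]
List advance_cpp(NumericMatrix X0, NumericMatrix W0,
                 IntegerVector la0, IntegerVector lb0,
                 NumericVector sa0, NumericVector sb0, NumericVector tc0,
                 double t0, double t_target, int max_steps,
                 List params, List ctrl, NumericVector box,
                 bool do_events, bool log_events) {
  Params P = unpack_params(params);
  int n = X0.nrow();
  double h = 0.5 * P.l_fib;
  double dx_max  = as<double>(ctrl["dx_max"]);
  double dth_max = as<double>(ctrl["dtheta_max"]);
  double dt_min  = as<double>(ctrl["dt_min"]);
  double dt_max  = as<double>(ctrl["dt_max"]);
  const double* bx = REAL(box);

  std::vector<double> X(3 * n), W(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { X[3*i+k] = X0(i,k); W[3*i+k] = W0(i,k); }
  std::vector<int> la(la0.begin(), la0.end()), lb(lb0.begin(), lb0.end());
  for (size_t l = 0; l < la.size(); ++l) { --la[l]; --lb[l]; }
  std::vector<double> sa(sa0.begin(), sa0.end()), sb(sb0.begin(), sb0.end());
  std::vector<double> tc(tc0.begin(), tc0.end());

  std::unordered_set<std::int64_t> linked;
  for (size_t l = 0; l < la.size(); ++l) linked.insert(pair_key(la[l], lb[l], n));

  std::vector<PairRec> pairs;
  std::vector<double> F(3 * n), T(3 * n);
  double cutoff = std::max(2.0 * P.r_fib, P.d_max);
  VerletList vlist(std::max(2.0 * P.r_fib, 1.0));

  std::vector<double> ev_t; std::vector<int> ev_type, ev_a, ev_b;
  double t = t0, dt_last = NA_REAL;
  double max_disp = 0.0, max_rot = 0.0;
  int steps = 0;
  RNGScope rngscope;

  while (t < t_target && steps < max_steps) {
    vlist.pass(n, X.data(), W.data(), h, cutoff, bx, pairs);
    accumulate(n, X.data(), W.data(), pairs, la, lb, sa, sb, P, bx,
               F.data(), T.data());

    // velocities and rotation rates from the overdamped law
    double inv_mL = 1.0 / (P.mu * P.l_fib);
    double inv_mL3 = 1.0 / (P.mu * P.l_fib * P.l_fib * P.l_fib);
    double vmax = 0.0, wmax = 0.0;
    std::vector<double> V(3 * n), DW(3 * n);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k) V[3*i+k] = F[3*i+k] * inv_mL;
      double tw[3];
      cross3(T.data() + 3 * i, W.data() + 3 * i, tw);
      for (int k = 0; k < 3; ++k) DW[3*i+k] = tw[k] * inv_mL3;
      double v = norm3(V.data() + 3 * i);
      double w = norm3(DW.data() + 3 * i);
      if (v > vmax) vmax = v;
      if (w > wmax) wmax = w;
    }
    double dt = dt_max;
    if (vmax > 0.0) dt = std::min(dt, dx_max / vmax);
    if (wmax > 0.0) dt = std::min(dt, dth_max / wmax);
    if (dt < dt_min)
      stop("adaptive time step fell below dt_min (%g < %g): configuration too stiff",
           dt, dt_min);
    if (R_finite(t_target)) dt = std::min(dt, t_target - t);

    double step_disp = 0.0, step_rot = 0.0;
    for (int i = 0; i < n; ++i) {
      double disp = dt * norm3(V.data() + 3 * i);
      double rot  = dt * norm3(DW.data() + 3 * i);
      if (disp > step_disp) step_disp = disp;
      if (rot > step_rot) step_rot = rot;
      for (int k = 0; k < 3; ++k) X[3*i+k] += dt * V[3*i+k];
      wrap3(X.data() + 3 * i, bx);
      for (int k = 0; k < 3; ++k) W[3*i+k] += dt * DW[3*i+k];
      double nrm = norm3(W.data() + 3 * i);
      for (int k = 0; k < 3; ++k) W[3*i+k] /= nrm;
    }
    if (step_disp > max_disp) max_disp = step_disp;
    if (step_rot > max_rot) max_rot = step_rot;
    vlist.acc += step_disp + h * step_rot;
    t += dt;
    dt_last = dt;
    ++steps;

    if (do_events) {
      if (P.nu_link > 0.0) {
        double p_link = 1.0 - std::exp(-P.nu_link * dt);
        for (const PairRec& pr : pairs) {
          if (pr.d > P.d_max) continue;
          if (linked.count(pair_key(pr.i, pr.j, n))) continue;
          if (unif_rand() < p_link) {
            la.push_back(pr.i); lb.push_back(pr.j);
            sa.push_back(pr.s1); sb.push_back(pr.s2); tc.push_back(t);
            linked.insert(pair_key(pr.i, pr.j, n));
            if (log_events) {
              ev_t.push_back(t); ev_type.push_back(1);
              ev_a.push_back(pr.i + 1); ev_b.push_back(pr.j + 1);
            }
          }
        }
      }
      if (P.nu_unlink > 0.0 && !la.empty()) {
        double p_unlink = 1.0 - std::exp(-P.nu_unlink * dt);
        size_t keep = 0;
        for (size_t l = 0; l < la.size(); ++l) {
          if (unif_rand() < p_unlink) {
            linked.erase(pair_key(la[l], lb[l], n));
            if (log_events) {
              ev_t.push_back(t); ev_type.push_back(-1);
              ev_a.push_back(la[l] + 1); ev_b.push_back(lb[l] + 1);
            }
          } else {
            la[keep] = la[l]; lb[keep] = lb[l];
            sa[keep] = sa[l]; sb[keep] = sb[l]; tc[keep] = tc[l];
            ++keep;
          }
        }
        la.resize(keep); lb.resize(keep);
        sa.resize(keep); sb.resize(keep); tc.resize(keep);
      }
    }
  }

  NumericMatrix Xo(n, 3), Wo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { Xo(i, k) = X[3*i+k]; Wo(i, k) = W[3*i+k]; }
  IntegerVector lao(la.size()), lbo(lb.size());
  for (size_t l = 0; l < la.size(); ++l) { lao[l] = la[l] + 1; lbo[l] = lb[l] + 1; }
  return List::create(
    _["X"] = Xo, _["W"] = Wo,
    _["fibre_a"] = lao, _["fibre_b"] = lbo,
    _["s_a"] = wrap(sa), _["s_b"] = wrap(sb), _["t_created"] = wrap(tc),
    _["t"] = t, _["steps"] = steps, _["dt_last"] = dt_last,
    _["max_step_displacement"] = max_disp, _["max_step_rotation"] = max_rot,
    _["event_t"] = wrap(ev_t), _["event_type"] = wrap(ev_type),
    _["event_a"] = wrap(ev_a), _["event_b"] = wrap(ev_b));
}
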