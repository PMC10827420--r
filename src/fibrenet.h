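#pragma once

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

// ---- periodic geometry -----------------------------------------------------

// wrap a coordinate into the half-open interval [-L/2, L/2)
inline double wrap1(double x, double L) {
  double y = x - L * std::floor(x / L + 0.5);
  if (y >= 0.5 * L) y -= L;   // floating-point edge guard
  if (y < -0.5 * L) y += L;
  return y;
}

inline void wrap3(double* x, const double* box) {
  for (int a = 0; a < 3; ++a) x[a] = wrap1(x[a], box[a]);
}

// minimum-image displacement from a to b (componentwise in [-L/2, L/2))
inline void mi3(const double* a, const double* b, const double* box, double* out) {
  for (int k = 0; k < 3; ++k) out[k] = wrap1(b[k] - a[k], box[k]);
}

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---- segment-segment closest points ---------------------------------------

struct SegClosest {
  double s1, s2;   // abscissae in [-h, h] along each fibre axis
  double d;        // distance between the closest points
  double u[3];     // minimum-image vector from closest point on 1 to on 2
};

// Closest points between two centred segments P1(s1) = X1 + s1 W1,
// P2(s2) = X2 + s2 W2, s in [-h, h], under the minimum-image convention
// applied to the centre displacement (valid while segments are short
// relative to the box).  Exactly parallel overlap uses the midpoint
// tie-break so the result is deterministic.
inline SegClosest seg_closest(const double* X1, const double* W1,
                              const double* X2, const double* W2,
                              double h, const double* box) {
  double d12[3];
  mi3(X1, X2, box, d12);
  double b  = dot3(W1, W2);
  double c1 = dot3(W1, d12);
  double c2 = dot3(W2, d12);
  double denom = 1.0 - b * b;

  SegClosest best;
  best.d = R_PosInf;
  best.s1 = best.s2 = 0.0;

  auto eval = [&](double s1, double s2) {
    double v[3];
    for (int k = 0; k < 3; ++k) v[k] = d12[k] + s2 * W2[k] - s1 * W1[k];
    double dd = norm3(v);
    if (dd < best.d) {
      best.d = dd; best.s1 = s1; best.s2 = s2;
      best.u[0] = v[0]; best.u[1] = v[1]; best.u[2] = v[2];
    }
  };

  if (denom < 1e-12) {
    // parallel: minimisers form a segment; take its midpoint
    double sg = (b >= 0.0) ? 1.0 : -1.0;
    double c1cl = clampd(c1, -2.0 * h, 2.0 * h);
    eval(0.5 * c1cl, -sg * 0.5 * c1cl);
    return best;
  }

  // interior stationary point, if feasible
  double s1u = (c1 - b * c2) / denom;
  double s2u = b * s1u - c2;
  if (std::fabs(s1u) <= h && std::fabs(s2u) <= h) eval(s1u, s2u);
  // boundary candidates: fix one abscissa at an end, optimise the other
  for (int e = -1; e <= 1; e += 2) {
    double s1f = e * h;
    eval(s1f, clampd(s1f * b - c2, -h, h));
    double s2f = e * h;
    eval(clampd(c1 + s2f * b, -h, h), s2f);
  }
  return best;
}

// ---- deterministic fallback direction -------------------------------------

inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Reproducible pseudo-random unit vector for a fibre index pair; used when a
// separation direction is geometrically undefined (coincident points).
// Consumes no R random numbers, so runs stay reproducible.
inline void fallback_dir(int i, int j, double* out) {
  std::uint64_t s = splitmix64((std::uint64_t)(i + 1) * 0x100000001b3ULL ^
                               (std::uint64_t)(j + 1));
  double z  = 2.0 * (splitmix64(s)     >> 11) * (1.0 / 9007199254740992.0) - 1.0;
  double ph = 2.0 * M_PI * (splitmix64(s + 1) >> 11) * (1.0 / 9007199254740992.0);
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  out[0] = r * std::cos(ph);
  out[1] = r * std::sin(ph);
  out[2] = z;
}
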