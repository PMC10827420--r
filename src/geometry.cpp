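#include "fibrenet.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix wrap_position_cpp(NumericMatrix x, NumericVector box) {
  int n = x.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      out(i, k) = wrap1(x(i, k), box[k]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix periodic_displacement_cpp(NumericMatrix a, NumericMatrix b,
                                        NumericVector box) {
  int n = a.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      out(i, k) = wrap1(b(i, k) - a(i, k), box[k]);
  return out;
}

// [[Rcpp::export]]
List segment_closest_cpp(NumericVector x1, NumericVector w1,
                         NumericVector x2, NumericVector w2,
                         double l_fib, NumericVector box) {
  SegClosest r = seg_closest(REAL(x1), REAL(w1), REAL(x2), REAL(w2),
                             0.5 * l_fib, REAL(box));
  return List::create(_["s1"] = r.s1, _["s2"] = r.s2, _["distance"] = r.d,
                      _["u"] = NumericVector::create(r.u[0], r.u[1], r.u[2]));
}

// [[Rcpp::export]]
NumericVector fallback_dir_cpp(int i, int j) {
  double u[3];
  fallback_dir(i - 1, j - 1, u);  // R passes 1-based fibre indices
  return NumericVector::create(u[0], u[1], u[2]);
}

// All fibre pairs whose segment-segment minimum-image distance is <= cutoff.
// Plain double loop with a cheap centre-distance prefilter; the result is
// identical to an all-pairs scan.
// [[Rcpp::export]]
List neighbour_pairs_cpp(NumericMatrix X, NumericMatrix W,
                         double l_fib, double cutoff, NumericVector box) {
  int n = X.nrow();
  double h = 0.5 * l_fib;
  double reach = cutoff + l_fib;        // centre distance bound
  double reach2 = reach * reach;
  std::vector<int> vi, vj;
  std::vector<double> vs1, vs2, vd;
  double const* bx = REAL(box);
  std::vector<double> Xc(3 * n), Wc(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { Xc[3*i+k] = X(i,k); Wc[3*i+k] = W(i,k); }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d12[3];
      mi3(&Xc[3*i], &Xc[3*j], bx, d12);
      if (dot3(d12, d12) > reach2) continue;
      SegClosest r = seg_closest(&Xc[3*i], &Wc[3*i], &Xc[3*j], &Wc[3*j], h, bx);
      if (r.d <= cutoff) {
        vi.push_back(i + 1); vj.push_back(j + 1);
        vs1.push_back(r.s1); vs2.push_back(r.s2); vd.push_back(r.d);
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["s1"] = wrap(vs1), _["s2"] = wrap(vs2),
                      _["distance"] = wrap(vd));
}
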