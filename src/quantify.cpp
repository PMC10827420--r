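#include "fibrenet.h"
using namespace Rcpp;

// Per-fibre second-moment (nematic) tensor of the neighbourhood directions.
// Neighbours are fibres within segment distance <= cutoff; the fibre's own
// direction is included.  Returns the six unique tensor entries per fibre
// (xx, yy, zz, xy, xz, yz) and the neighbour count (self excluded).
// [[Rcpp::export]]
List local_moment_cpp(NumericMatrix X, NumericMatrix W,
                      double l_fib, double cutoff, NumericVector box) {
  int n = X.nrow();
  double h = 0.5 * l_fib;
  double reach = cutoff + l_fib, reach2 = reach * reach;
  const double* bx = REAL(box);
  std::vector<double> Xc(3 * n), Wc(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { Xc[3*i+k] = X(i,k); Wc[3*i+k] = W(i,k); }

  NumericMatrix M(n, 6);
  IntegerVector cnt(n);
  // start from the fibre's own direction
  for (int i = 0; i < n; ++i) {
    const double* w = &Wc[3 * i];
    M(i, 0) = w[0]*w[0]; M(i, 1) = w[1]*w[1]; M(i, 2) = w[2]*w[2];
    M(i, 3) = w[0]*w[1]; M(i, 4) = w[0]*w[2]; M(i, 5) = w[1]*w[2];
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d12[3];
      mi3(&Xc[3*i], &Xc[3*j], bx, d12);
      if (dot3(d12, d12) > reach2) continue;
      SegClosest r = seg_closest(&Xc[3*i], &Wc[3*i], &Xc[3*j], &Wc[3*j], h, bx);
      if (r.d > cutoff) continue;
      const double* wi = &Wc[3 * i];
      const double* wj = &Wc[3 * j];
      M(i, 0) += wj[0]*wj[0]; M(i, 1) += wj[1]*wj[1]; M(i, 2) += wj[2]*wj[2];
      M(i, 3) += wj[0]*wj[1]; M(i, 4) += wj[0]*wj[2]; M(i, 5) += wj[1]*wj[2];
      M(j, 0) += wi[0]*wi[0]; M(j, 1) += wi[1]*wi[1]; M(j, 2) += wi[2]*wi[2];
      M(j, 3) += wi[0]*wi[1]; M(j, 4) += wi[0]*wi[2]; M(j, 5) += wi[1]*wi[2];
      ++cnt[i]; ++cnt[j];
    }
  }
  for (int i = 0; i < n; ++i) {
    double m = 1.0 + cnt[i];
    for (int k = 0; k < 6; ++k) M(i, k) /= m;
  }
  return List::create(_["moment"] = M, _["n_neighbours"] = cnt);
}
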