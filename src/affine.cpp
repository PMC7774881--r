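// Inverse-mapped affine resampling used by the paired augmentation module.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample `img` at output pixel (r, c) mapped back into source coordinates by
// the 2x3 matrix M (row-major: sr = M0*r + M1*c + M2; sc = M3*r + M4*c + M5;
// all coordinates 0-based). `bilinear = false` gives nearest-neighbour.
// Out-of-field samples take `fill`.
// [[Rcpp::export(name = ".affine_sample")]]
NumericMatrix affine_sample(NumericMatrix img, NumericVector M, bool bilinear,
                            double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double sr = M[0] * r + M[1] * c + M[2];
      const double sc = M[3] * r + M[4] * c + M[5];
      double v;
      if (!bilinear) {
        const int ir = (int)std::lround(sr), ic = (int)std::lround(sc);
        v = (ir < 0 || ir >= nr || ic < 0 || ic >= nc) ? fill : img(ir, ic);
      } else {
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        const double fr = sr - r0, fc = sc - c0;
        double acc = 0.0;
        const double w[4] = {(1 - fr) * (1 - fc), fr * (1 - fc),
                             (1 - fr) * fc, fr * fc};
        const int rr[4] = {r0, r0 + 1, r0, r0 + 1};
        const int cc[4] = {c0, c0, c0 + 1, c0 + 1};
        for (int k = 0; k < 4; ++k) {
          const double pv = (rr[k] < 0 || rr[k] >= nr || cc[k] < 0 ||
                             cc[k] >= nc)
                                ? fill
                                : img(rr[k], cc[k]);
          acc += w[k] * pv;
        }
        v = acc;
      }
      out(r, c) = v;
    }
  }
  return out;
}
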