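// Minimal CPU convolution stack for the encoder-decoder network.
// im2col + BLAS GEMM forward, exact analytic backward. Single sample
// (H x W x C arrays); batching is handled by the R caller.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

arma::cube as_cube(const NumericVector& x) {
  const IntegerVector d = x.attr("dim");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false);
}

NumericVector wrap_cube(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// Patch matrix: rows index pixels (r + c*H), columns index (ci, dr, dc) as
// ci * k * k + dr * k + dc. Same padding with zeros, offset p = (k-1)/2.
arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  arma::mat X2(H * W, k * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int dr = 0; dr < k; ++dr)
      for (int dc = 0; dc < k; ++dc) {
        const int j = ci * k * k + dr * k + dc;
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc - p;
          if (sc < 0 || sc >= W) continue;
          for (int r = 0; r < H; ++r) {
            const int sr = r + dr - p;
            if (sr < 0 || sr >= H) continue;
            X2(r + c * H, j) = x(sr, sc, ci);
          }
        }
      }
  return X2;
}

}  // namespace

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericMatrix w, NumericVector b,
                        int k) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols;
  const arma::mat Wm(const_cast<double*>(w.begin()), w.nrow(), w.ncol(), false);
  arma::mat Y = im2col(xc, k) * Wm;
  Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), b.size(), false);
  arma::cube yc(Y.memptr(), H, W, Wm.n_cols);
  return wrap_cube(yc);
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericMatrix w, NumericVector dy, int k) {
  arma::cube xc = as_cube(x);
  arma::cube dyc = as_cube(dy);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices, p = (k - 1) / 2;
  const int Cout = dyc.n_slices;
  const arma::mat Wm(const_cast<double*>(w.begin()), w.nrow(), w.ncol(), false);
  arma::mat dYm(dyc.memptr(), H * W, Cout, false);

  arma::mat X2 = im2col(xc, k);
  arma::mat dW = X2.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dX2 = dYm * Wm.t();

  // col2im scatter-add.
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int dr = 0; dr < k; ++dr)
      for (int dc = 0; dc < k; ++dc) {
        const int j = ci * k * k + dr * k + dc;
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc - p;
          if (sc < 0 || sc >= W) continue;
          for (int r = 0; r < H; ++r) {
            const int sr = r + dr - p;
            if (sr < 0 || sr >= H) continue;
            dx(sr, sc, ci) += dX2(r + c * H, j);
          }
        }
      }

  return List::create(_["dx"] = wrap_cube(dx),
                      _["dw"] = wrap(arma::mat(dW)),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector amax(Ho * Wo * C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        double best = -1e300;
        int bidx = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            const int rr = 2 * r + dr, cc = 2 * c + dc;
            const double v = xc(rr, cc, ci);
            if (v > best) {
              best = v;
              bidx = rr + cc * H + ci * H * W;
            }
          }
        y(r, c, ci) = best;
        amax[r + c * Ho + ci * Ho * Wo] = bidx;
      }
  return List::create(_["y"] = wrap_cube(y), _["amax"] = amax,
                      _["H"] = H, _["W"] = W);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector amax, int H, int W) {
  arma::cube dyc = as_cube(dy);
  const int C = dyc.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const int n = dyc.n_elem;
  for (int i = 0; i < n; ++i) dx[amax[i]] += dyc[i];
  return wrap_cube(dx);
}

// [[Rcpp::export(name = ".upsample2_fw")]]
NumericVector upsample2_fw(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < 2 * W; ++c)
      for (int r = 0; r < 2 * H; ++r)
        y(r, c, ci) = xc(r / 2, c / 2, ci);
  return wrap_cube(y);
}

// [[Rcpp::export(name = ".upsample2_bw")]]
NumericVector upsample2_bw(NumericVector dy) {
  arma::cube dyc = as_cube(dy);
  const int H2 = dyc.n_rows, W2 = dyc.n_cols, C = dyc.n_slices;
  arma::cube dx(H2 / 2, W2 / 2, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r)
        dx(r / 2, c / 2, ci) += dyc(r, c, ci);
  return wrap_cube(dx);
}
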