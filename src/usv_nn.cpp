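// Compute kernels for the hybrid detector: 2-D convolution (same-frequency /
// valid-time) and a batched LSTM step loop. These are the inner loops of
// training; everything else stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// X: (F, T, cin) cube; W: (kf, kt, cin, cout) as vector with dims; b: cout.
// Frequency axis zero-padded ("same"), time axis valid.
// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& X, const arma::vec& Wv,
                          const arma::ivec& wdim, const arma::vec& b) {
  const int kf = wdim[0], kt = wdim[1], cin = wdim[2], cout = wdim[3];
  const int F = X.n_rows, T = X.n_cols;
  const int Tout = T - kt + 1;
  const int of = (kf + 1) / 2;  // 1-based center
  cube Y(F, Tout, cout);
  for (int co = 0; co < cout; ++co) Y.slice(co).fill(b[co]);
  for (int co = 0; co < cout; ++co) {
    mat& Yc = Y.slice(co);
    for (int ci = 0; ci < cin; ++ci) {
      const mat& Xc = X.slice(ci);
      for (int u = 0; u < kt; ++u) {
        for (int j = 0; j < kf; ++j) {
          const double w = Wv[j + kf * (u + kt * (ci + cin * co))];
          if (w == 0.0) continue;
          const int s = (j + 1) - of;  // row shift: Y(f) += w * X(f + s)
          const int f0 = std::max(0, -s), f1 = std::min(F - 1, F - 1 - s);
          if (f1 < f0) continue;
          for (int t = 0; t < Tout; ++t) {
            const double* xp = Xc.colptr(t + u) + f0 + s;
            double* yp = Yc.colptr(t) + f0;
            for (int f = f0; f <= f1; ++f) *yp++ += w * *xp++;
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& X, const arma::vec& Wv,
                          const arma::ivec& wdim, const arma::cube& dY,
                          const bool need_dx) {
  const int kf = wdim[0], kt = wdim[1], cin = wdim[2], cout = wdim[3];
  const int F = X.n_rows, T = X.n_cols;
  const int Tout = T - kt + 1;
  const int of = (kf + 1) / 2;
  vec dW(kf * kt * cin * cout, fill::zeros);
  vec db(cout, fill::zeros);
  cube dX;
  if (need_dx) dX.zeros(F, T, cin);
  for (int co = 0; co < cout; ++co) {
    const mat& dYc = dY.slice(co);
    db[co] = accu(dYc);
    for (int ci = 0; ci < cin; ++ci) {
      const mat& Xc = X.slice(ci);
      for (int u = 0; u < kt; ++u) {
        for (int j = 0; j < kf; ++j) {
          const int widx = j + kf * (u + kt * (ci + cin * co));
          const double w = Wv[widx];
          const int s = (j + 1) - of;
          const int f0 = std::max(0, -s), f1 = std::min(F - 1, F - 1 - s);
          if (f1 < f0) continue;
          double acc = 0.0;
          for (int t = 0; t < Tout; ++t) {
            const double* xp = Xc.colptr(t + u) + f0 + s;
            const double* dp = dYc.colptr(t) + f0;
            for (int f = f0; f <= f1; ++f) acc += *dp++ * *xp++;
          }
          dW[widx] = acc;
          if (need_dx) {
            mat& dXc = dX.slice(ci);
            for (int t = 0; t < Tout; ++t) {
              double* xp = dXc.colptr(t + u) + f0 + s;
              const double* dp = dYc.colptr(t) + f0;
              for (int f = f0; f <= f1; ++f) *xp++ += w * *dp++;
            }
          }
        }
      }
    }
  }
  List out = List::create(Named("dW") = dW, Named("db") = db);
  if (need_dx) out["dX"] = dX;
  return out;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// X: (B, I, T) cube. Gate layout [i | f | g | o]. Returns H, gates, C.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_fwd(const arma::cube& X, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::vec& b,
                        const bool reverse) {
  const int B = X.n_rows, T = X.n_slices;
  const int hid = Wh.n_rows;
  cube H(B, hid, T), C(B, hid, T), G(B, 4 * hid, T);
  mat h(B, hid, fill::zeros), c(B, hid, fill::zeros);
  const rowvec br = b.t();
  for (int k = 0; k < T; ++k) {
    const int t = reverse ? (T - 1 - k) : k;
    mat Z = X.slice(t) * Wx + h * Wh;
    Z.each_row() += br;
    mat ig = sigm(Z.cols(0, hid - 1));
    mat fg = sigm(Z.cols(hid, 2 * hid - 1));
    mat gg = tanh(Z.cols(2 * hid, 3 * hid - 1));
    mat og = sigm(Z.cols(3 * hid, 4 * hid - 1));
    c = fg % c + ig % gg;
    h = og % tanh(c);
    G.slice(t) = join_rows(ig, fg, gg, og);
    C.slice(t) = c;
    H.slice(t) = h;
  }
  return List::create(Named("H") = H, Named("gates") = G, Named("C") = C);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_bwd(const arma::cube& X, const arma::cube& H,
                        const arma::cube& G, const arma::cube& C,
                        const arma::mat& Wx, const arma::mat& Wh,
                        const arma::cube& dH, const bool reverse) {
  const int B = X.n_rows, I = X.n_cols, T = X.n_slices;
  const int hid = Wh.n_rows;
  mat dWx(I, 4 * hid, fill::zeros), dWh(hid, 4 * hid, fill::zeros);
  vec db(4 * hid, fill::zeros);
  cube dX(B, I, T);
  mat dh_next(B, hid, fill::zeros), dc_next(B, hid, fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    const int t = reverse ? (T - 1 - k) : k;
    const int tprev = reverse ? (t + 1) : (t - 1);
    const bool has_prev = k > 0;
    const mat& g = G.slice(t);
    mat ig = g.cols(0, hid - 1), fg = g.cols(hid, 2 * hid - 1);
    mat gg = g.cols(2 * hid, 3 * hid - 1), og = g.cols(3 * hid, 4 * hid - 1);
    mat ct = C.slice(t);
    mat c_prev = has_prev ? mat(C.slice(tprev)) : mat(B, hid, fill::zeros);
    mat h_prev = has_prev ? mat(H.slice(tprev)) : mat(B, hid, fill::zeros);
    mat tc = tanh(ct);
    mat dh = dH.slice(t) + dh_next;
    mat do_ = dh % tc;
    mat dc = dh % og % (1.0 - tc % tc) + dc_next;
    mat di = dc % gg, dg = dc % ig, df = dc % c_prev;
    dc_next = dc % fg;
    mat dZ = join_rows(di % ig % (1.0 - ig), df % fg % (1.0 - fg),
                       dg % (1.0 - gg % gg), do_ % og % (1.0 - og));
    dWx += X.slice(t).t() * dZ;
    dWh += h_prev.t() * dZ;
    db += sum(dZ, 0).t();
    dX.slice(t) = dZ * Wx.t();
    dh_next = dZ * Wh.t();
  }
  return List::create(Named("dWx") = dWx, Named("dWh") = dWh,
                      Named("db") = db, Named("dX") = dX);
}
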