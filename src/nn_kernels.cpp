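// Hot-path kernels of the neural-network engine. Layouts mirror the R side:
// conv stage cubes are (channels C, intra-frame time T, frames N); matrix
// stages are (features, samples). The pure-R reference implementations in
// R/nn.R are kept and cross-checked against these kernels in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- layer norm over rows (features) of each column ----------------------
// [[Rcpp::export]]
List cpp_ln_fwd(const arma::mat& x, const arma::vec& gamma,
                const arma::vec& beta, double eps) {
  arma::rowvec m = arma::mean(x, 0);
  arma::rowvec v = arma::mean(arma::square(x), 0) - arma::square(m);
  v.transform([](double z) { return z > 0.0 ? z : 0.0; });
  arma::rowvec inv = 1.0 / arma::sqrt(v + eps);
  arma::mat xhat = x;
  xhat.each_row() -= m;
  xhat.each_row() %= inv;
  arma::mat out = xhat;
  out.each_col() %= gamma;
  out.each_col() += beta;
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_ln_bwd(const arma::mat& dy, const arma::vec& gamma,
                const arma::mat& xhat, const arma::rowvec& inv) {
  const double C = (double)dy.n_rows;
  arma::vec dgamma = arma::sum(dy % xhat, 1);
  arma::vec dbeta = arma::sum(dy, 1);
  arma::mat dxhat = dy;
  dxhat.each_col() %= gamma;
  arma::rowvec s1 = arma::sum(dxhat, 0) / C;
  arma::rowvec s2 = arma::sum(dxhat % xhat, 0) / C;
  arma::mat dx = dxhat;
  dx.each_row() -= s1;
  arma::mat t2 = xhat;
  t2.each_row() %= s2;
  dx -= t2;
  dx.each_row() %= inv;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- channel-preserving 1-D convolution via im2col ------------------------
static arma::mat im2col_1d(const arma::cube& x, int k, int pad, int L) {
  const int C = x.n_rows, T = x.n_cols, N = x.n_slices;
  arma::mat xcol(C * k, (size_t)L * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const arma::mat& sl = x.slice(n);
    for (int j = 0; j < k; ++j) {
      // padded column j + l maps to input column j + l - pad
      for (int l = 0; l < L; ++l) {
        int src = j + l - pad;
        if (src < 0 || src >= T) continue;
        std::memcpy(xcol.colptr((size_t)n * L + l) + (size_t)j * C,
                    sl.colptr(src), C * sizeof(double));
      }
    }
  }
  return xcol;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, int pad) {
  const int T = x.n_cols, N = x.n_slices;
  const int L = T + 2 * pad - k + 1;
  arma::mat y = W * im2col_1d(x, k, pad, L);
  y.each_col() += b;
  return arma::cube(y.memptr(), W.n_rows, L, N);
}

// The im2col matrix is recomputed here rather than cached across the R
// boundary; rebuilding it is far cheaper than shipping it back and forth.
// [[Rcpp::export]]
List cpp_conv1d_bwd(const arma::cube& dy, const arma::mat& W,
                    const arma::cube& x, int k, int pad) {
  const int C = x.n_rows, T = x.n_cols, N = x.n_slices;
  const int L = dy.n_cols;
  arma::mat xcol = im2col_1d(x, k, pad, L);
  arma::mat dym((double*)dy.memptr(), dy.n_rows, (size_t)L * N);
  arma::mat dW = dym * xcol.t();
  arma::vec db = arma::sum(dym, 1);
  arma::mat dxcol = W.t() * dym;
  arma::cube dx(C, T, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat& sl = dx.slice(n);
    for (int j = 0; j < k; ++j) {
      for (int l = 0; l < L; ++l) {
        int src = j + l - pad;
        if (src < 0 || src >= T) continue;
        sl.col(src) += dxcol.submat((size_t)j * C, (size_t)n * L + l,
                                    (size_t)(j + 1) * C - 1,
                                    (size_t)n * L + l);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---- blur pooling (depthwise (1,2,1)/4, stride 2, padding 1) --------------
// [[Rcpp::export]]
List cpp_blurpool_fwd(const arma::cube& x) {
  const int C = x.n_rows, T = x.n_cols, N = x.n_slices;
  const int L = (T + 2 - 3) / 2 + 1;
  arma::cube y(C, L, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const arma::mat& sl = x.slice(n);
    arma::mat& out = y.slice(n);
    for (int l = 0; l < L; ++l) {
      // padded window start 2l covers padded cols 2l..2l+2 -> input 2l-1..2l+1
      for (int j = 0; j < 3; ++j) {
        int src = 2 * l + j - 1;
        if (src < 0 || src >= T) continue;
        out.col(l) += sl.col(src) * (j == 1 ? 0.5 : 0.25);
      }
    }
  }
  return List::create(_["out"] = y, _["T"] = T);
}

// [[Rcpp::export]]
arma::cube cpp_blurpool_bwd(const arma::cube& dy, int T) {
  const int C = dy.n_rows, L = dy.n_cols, N = dy.n_slices;
  arma::cube dx(C, T, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const arma::mat& g = dy.slice(n);
    arma::mat& sl = dx.slice(n);
    for (int l = 0; l < L; ++l) {
      for (int j = 0; j < 3; ++j) {
        int src = 2 * l + j - 1;
        if (src < 0 || src >= T) continue;
        sl.col(src) += g.col(l) * (j == 1 ? 0.5 : 0.25);
      }
    }
  }
  return dx;
}

// ---- global average pooling over the intra-frame time axis ----------------
// [[Rcpp::export]]
arma::mat cpp_gap_fwd(const arma::cube& x) {
  arma::mat out(x.n_rows, x.n_slices);
  for (arma::uword n = 0; n < x.n_slices; ++n)
    out.col(n) = arma::mean(x.slice(n), 1);
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_gap_bwd(const arma::mat& dy, int T) {
  arma::cube dx(dy.n_rows, T, dy.n_cols);
  for (arma::uword n = 0; n < dy.n_cols; ++n) {
    arma::vec v = dy.col(n) / (double)T;
    dx.slice(n) = arma::repmat(v, 1, T);
  }
  return dx;
}

// ---- LSTM -----------------------------------------------------------------
// x: (D, F, B); Wx: (4H, D); Wh: (4H, H); b: 4H. Gate order: input, forget,
// cell candidate, output. Gates and cell states are cached as (4H/H, F, B)
// cubes for the backward pass.
// [[Rcpp::export]]
List cpp_lstm_fwd(const arma::cube& x, const arma::mat& Wx,
                  const arma::mat& Wh, const arma::vec& b) {
  const int D = x.n_rows, F = x.n_cols, B = x.n_slices;
  const int H = Wh.n_cols;
  arma::cube out(H, F, B), gates(4 * H, F, B), cst(H, F, B);
  arma::mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  arma::mat xt(D, B);
  for (int t = 0; t < F; ++t) {
    for (int n = 0; n < B; ++n) xt.col(n) = x.slice(n).col(t);
    arma::mat z = Wx * xt + Wh * h;
    z.each_col() += b;
    arma::mat i = 1.0 / (1.0 + arma::exp(-z.rows(0, H - 1)));
    arma::mat f = 1.0 / (1.0 + arma::exp(-z.rows(H, 2 * H - 1)));
    arma::mat g = arma::tanh(z.rows(2 * H, 3 * H - 1));
    arma::mat o = 1.0 / (1.0 + arma::exp(-z.rows(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    for (int n = 0; n < B; ++n) {
      out.slice(n).col(t) = h.col(n);
      cst.slice(n).col(t) = c.col(n);
      gates.slice(n).col(t) = arma::join_cols(arma::join_cols(i.col(n), f.col(n)),
                                              arma::join_cols(g.col(n), o.col(n)));
    }
  }
  return List::create(_["out"] = out, _["gates"] = gates, _["cst"] = cst);
}

// [[Rcpp::export]]
List cpp_lstm_bwd(const arma::cube& dy, const arma::cube& x,
                  const arma::mat& Wx, const arma::mat& Wh,
                  const arma::cube& gates, const arma::cube& cst) {
  const int D = x.n_rows, F = x.n_cols, B = x.n_slices;
  const int H = Wh.n_cols;
  arma::mat dWx(4 * H, D, arma::fill::zeros), dWh(4 * H, H, arma::fill::zeros);
  arma::vec db(4 * H, arma::fill::zeros);
  arma::cube dx(D, F, B);
  arma::mat dh_next(H, B, arma::fill::zeros), dc_next(H, B, arma::fill::zeros);
  arma::mat xt(D, B), dht(H, B), i(H, B), f(H, B), g(H, B), o(H, B),
      c(H, B), c_prev(H, B);
  for (int t = F - 1; t >= 0; --t) {
    for (int n = 0; n < B; ++n) {
      xt.col(n) = x.slice(n).col(t);
      dht.col(n) = dy.slice(n).col(t);
      const arma::vec gt = gates.slice(n).col(t);
      i.col(n) = gt.subvec(0, H - 1);
      f.col(n) = gt.subvec(H, 2 * H - 1);
      g.col(n) = gt.subvec(2 * H, 3 * H - 1);
      o.col(n) = gt.subvec(3 * H, 4 * H - 1);
      c.col(n) = cst.slice(n).col(t);
      if (t > 0) c_prev.col(n) = cst.slice(n).col(t - 1);
    }
    arma::mat tc = arma::tanh(c);
    arma::mat dh = dht + dh_next;
    arma::mat do_ = dh % tc;
    arma::mat dc = dh % o % (1.0 - arma::square(tc)) + dc_next;
    if (t == 0) c_prev.zeros();
    arma::mat di = dc % g, df = dc % c_prev, dg = dc % i;
    dc_next = dc % f;
    arma::mat dz = arma::join_cols(
        arma::join_cols(di % i % (1.0 - i), df % f % (1.0 - f)),
        arma::join_cols(dg % (1.0 - arma::square(g)), do_ % o % (1.0 - o)));
    if (t > 0) {
      arma::mat hp(H, B);
      for (int n = 0; n < B; ++n) {
        arma::vec gp = gates.slice(n).col(t - 1);
        arma::vec op = gp.subvec(3 * H, 4 * H - 1);
        hp.col(n) = op % arma::tanh(cst.slice(n).col(t - 1));
      }
      dWh += dz * hp.t();
    }
    dWx += dz * xt.t();
    db += arma::sum(dz, 1);
    arma::mat dxt = Wx.t() * dz;
    for (int n = 0; n < B; ++n) dx.slice(n).col(t) = dxt.col(n);
    dh_next = Wh.t() * dz;
  }
  return List::create(_["dx"] = dx, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db);
}
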