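// Low-level array kernels for the CPU deep-learning core.
//
// Array conventions (R column-major): feature maps are (H, W, C, N),
// convolution weights are (kh, kw, Cin, Cout). Convolutions use zero
// padding and an integer stride; im2col rows are ordered i + kh*(j + kw*c)
// so that matrix(w, kh*kw*Cin, Cout) lines up without copies.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col(const double* x, int H, int W, int Cin,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::mat& M) {
  const int L = Ho * Wo;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double* Mrow = M.memptr() + r; // stride K between columns
        const int K = M.n_rows;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + j - pad;
          const bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + i - pad;
            const int l = ho + Ho * wo;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wi];
            Mrow[(size_t)K * l] = v;
          }
        }
      }
    }
  }
}

static inline void col2im_acc(const arma::mat& M, double* dx,
                              int H, int W, int Cin,
                              int kh, int kw, int stride, int pad,
                              int Ho, int Wo) {
  const int K = M.n_rows;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double* Mrow = M.memptr() + r;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + i - pad;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += Mrow[(size_t)K * (ho + Ho * wo)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * Cin, L = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat M(K, L);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    im2col(xn, H, W, Cin, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat yt(y.begin() + (size_t)L * Cout * n, L, Cout, false, true);
    yt = M.t() * Wm;
    for (int co = 0; co < Cout; ++co) yt.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * Cin, L = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)kh * kw * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat M(K, L);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    im2col(xn, H, W, Cin, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat dyt(const_cast<double*>(dy.begin()) + (size_t)L * Cout * n,
                  L, Cout, false, true);
    dWm += M * dyt;
    dbv += arma::sum(dyt, 0).t();
    arma::mat dM = Wm * dyt.t(); // K x L
    col2im_acc(dM, dx.begin() + (size_t)H * W * Cin * n,
               H, W, Cin, kh, kw, stride, pad, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling with stride 2; returns pooled map and the flat (h + H*w)
// index of each selected pixel so the backward pass can scatter gradients.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = 2 * ho, w0 = 2 * wo;
          int best = h0 + H * w0;
          double bv = xc[best];
          const int cand[3] = { h0 + 1 + H * w0, h0 + H * (w0 + 1),
                                h0 + 1 + H * (w0 + 1) };
          for (int k = 0; k < 3; ++k)
            if (xc[cand[k]] > bv) { bv = xc[cand[k]]; best = cand[k]; }
          y[o] = bv;
          idx[o] = best;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int l = 0; l < Ho * Wo; ++l, ++o) xc[idx[o]] += dy[o];
    }
  }
  return dx;
}

// Connected-component labeling of a binary array: 8-connectivity for 2D
// inputs, 26-connectivity for 3D, via breadth-first search.
// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector mask) {
  IntegerVector d = mask.attr("dim");
  int d1 = d[0], d2 = d[1], d3 = (d.size() > 2) ? d[2] : 1;
  const size_t n = (size_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t p = q.front(); q.pop();
      int i = p % d1, j = (p / d1) % d2, k = p / ((size_t)d1 * d2);
      for (int dk = -1; dk <= 1; ++dk) {
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 ||
                kk < 0 || kk >= d3) continue;
            size_t pp = ii + (size_t)d1 * (jj + (size_t)d2 * kk);
            if (mask[pp] != 0 && lab[pp] == 0) { lab[pp] = next; q.push(pp); }
          }
        }
      }
    }
  }
  return lab;
}
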