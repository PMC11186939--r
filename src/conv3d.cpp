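// Spatio-temporal convolution primitives.
//
// Feature tensors cross the R/C++ boundary as numeric vectors in
// column-major order with dimensions (W, H, T, C, N): width fastest, then
// height, time, channel, batch. Convolution weights have dimensions
// (KW, KH, KT, Cin, Cout). Forward and backward passes are implemented as
// vol2col / col2vol plus dense GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

static void vol2col(const double* x, int W, int H, int T, int C,
                    int KW, int KH, int KT,
                    int sw, int sh, int st,
                    int pw, int ph, int pt,
                    int Wo, int Ho, int To, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int kt = 0; kt < KT; ++kt) {
      for (int kh = 0; kh < KH; ++kh) {
        for (int kw = 0; kw < KW; ++kw) {
          const int row = kw + KW * (kh + KH * (kt + KT * c));
          for (int to = 0; to < To; ++to) {
            const int ti = to * st + kt - pt;
            const bool tok = ti >= 0 && ti < T;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * sh + kh - ph;
              const bool hok = hi >= 0 && hi < H;
              for (int wo = 0; wo < Wo; ++wo) {
                const int wi = wo * sw + kw - pw;
                double v = 0.0;
                if (tok && hok && wi >= 0 && wi < W)
                  v = x[wi + (size_t)W * (hi + (size_t)H * (ti + (size_t)T * c))];
                col(row, wo + (size_t)Wo * (ho + (size_t)Ho * to)) = v;
              }
            }
          }
        }
      }
    }
  }
}

static void col2vol(const arma::mat& col, double* dx,
                    int W, int H, int T, int C,
                    int KW, int KH, int KT,
                    int sw, int sh, int st,
                    int pw, int ph, int pt,
                    int Wo, int Ho, int To) {
  for (int c = 0; c < C; ++c) {
    for (int kt = 0; kt < KT; ++kt) {
      for (int kh = 0; kh < KH; ++kh) {
        for (int kw = 0; kw < KW; ++kw) {
          const int row = kw + KW * (kh + KH * (kt + KT * c));
          for (int to = 0; to < To; ++to) {
            const int ti = to * st + kt - pt;
            if (ti < 0 || ti >= T) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * sh + kh - ph;
              if (hi < 0 || hi >= H) continue;
              for (int wo = 0; wo < Wo; ++wo) {
                const int wi = wo * sw + kw - pw;
                if (wi < 0 || wi >= W) continue;
                dx[wi + (size_t)W * (hi + (size_t)H * (ti + (size_t)T * c))] +=
                  col(row, wo + (size_t)Wo * (ho + (size_t)Ho * to));
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv3d_fw(NumericVector x, IntegerVector xdim,
               NumericVector w, IntegerVector wdim,
               NumericVector b,
               IntegerVector stride, IntegerVector pad) {
  const int W = xdim[0], H = xdim[1], T = xdim[2], C = xdim[3], N = xdim[4];
  const int KW = wdim[0], KH = wdim[1], KT = wdim[2], Cout = wdim[4];
  const int sw = stride[0], sh = stride[1], st = stride[2];
  const int pw = pad[0], ph = pad[1], pt = pad[2];
  const int Wo = out_size(W, KW, sw, pw);
  const int Ho = out_size(H, KH, sh, ph);
  const int To = out_size(T, KT, st, pt);
  const size_t sample_in = (size_t)W * H * T * C;
  const size_t sample_out = (size_t)Wo * Ho * To * Cout;

  arma::mat Wm(const_cast<double*>(w.begin()), KW * KH * KT * C, Cout, false);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false);
  NumericVector y((R_xlen_t)(sample_out * N));
  arma::mat col(KW * KH * KT * C, (size_t)Wo * Ho * To);

  for (int n = 0; n < N; ++n) {
    vol2col(x.begin() + n * sample_in, W, H, T, C, KW, KH, KT,
            sw, sh, st, pw, ph, pt, Wo, Ho, To, col);
    arma::mat ycol = col.t() * Wm;               // (WoHoTo) x Cout
    ycol.each_row() += bv.t();
    std::copy(ycol.begin(), ycol.end(), y.begin() + n * sample_out);
  }
  return List::create(_["y"] = y,
                      _["ydim"] = IntegerVector::create(Wo, Ho, To, Cout, N));
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, IntegerVector xdim,
               NumericVector w, IntegerVector wdim,
               NumericVector dy,
               IntegerVector stride, IntegerVector pad) {
  const int W = xdim[0], H = xdim[1], T = xdim[2], C = xdim[3], N = xdim[4];
  const int KW = wdim[0], KH = wdim[1], KT = wdim[2], Cout = wdim[4];
  const int sw = stride[0], sh = stride[1], st = stride[2];
  const int pw = pad[0], ph = pad[1], pt = pad[2];
  const int Wo = out_size(W, KW, sw, pw);
  const int Ho = out_size(H, KH, sh, ph);
  const int To = out_size(T, KT, st, pt);
  const size_t sample_in = (size_t)W * H * T * C;
  const size_t sample_out = (size_t)Wo * Ho * To * Cout;
  const int K = KW * KH * KT * C;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false);
  NumericVector dx((R_xlen_t)(sample_in * N));
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(K, (size_t)Wo * Ho * To);

  for (int n = 0; n < N; ++n) {
    arma::mat D(const_cast<double*>(dy.begin()) + n * sample_out,
                (size_t)Wo * Ho * To, Cout, false);
    vol2col(x.begin() + n * sample_in, W, H, T, C, KW, KH, KT,
            sw, sh, st, pw, ph, pt, Wo, Ho, To, col);
    dW += col * D;
    db += arma::sum(D, 0).t();
    arma::mat dcol = Wm * D.t();                  // K x (WoHoTo)
    col2vol(dcol, dx.begin() + n * sample_in, W, H, T, C, KW, KH, KT,
            sw, sh, st, pw, ph, pt, Wo, Ho, To);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericVector(dW.begin(), dW.end()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
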