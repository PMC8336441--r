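#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Layout conventions: activation arrays are column-major (N, H, W, C);
// im2col rows run (n, h, w) with n fastest, columns are 9 offset blocks
// ((di, dj) row-major) of C channels each. Only 3x3 kernels, stride 1.

// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector xp, int N, int Hp, int Wp, int C,
                      int Ho, int Wo) {
  const double* x = xp.begin();
  const size_t M = (size_t)N * Ho * Wo;
  NumericMatrix cols(M, 9 * C);
  double* out = cols.begin();
  for (int k = 0; k < 9; ++k) {
    const int di = k / 3, dj = k % 3;
    for (int c = 0; c < C; ++c) {
      double* dst = out + ((size_t)k * C + c) * M;
      const double* src_c = x + (size_t)c * N * Hp * Wp;
      for (int w = 0; w < Wo; ++w) {
        const double* src_w = src_c + (size_t)(w + dj) * N * Hp;
        for (int h = 0; h < Ho; ++h) {
          std::memcpy(dst, src_w + (size_t)(h + di) * N, N * sizeof(double));
          dst += N;
        }
      }
    }
  }
  return cols;
}

// Scatter-add of column gradients back onto the (padded) input array.
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix dcols, int N, int Hp, int Wp, int C,
                      int Ho, int Wo) {
  NumericVector dxp((size_t)N * Hp * Wp * C);   // dims restored on the R side
  double* dx = dxp.begin();
  const double* dc = dcols.begin();
  const size_t M = (size_t)N * Ho * Wo;
  for (int k = 0; k < 9; ++k) {
    const int di = k / 3, dj = k % 3;
    for (int c = 0; c < C; ++c) {
      const double* src = dc + ((size_t)k * C + c) * M;
      double* dst_c = dx + (size_t)c * N * Hp * Wp;
      for (int w = 0; w < Wo; ++w) {
        double* dst_w = dst_c + (size_t)(w + dj) * N * Hp;
        for (int h = 0; h < Ho; ++h) {
          double* dst = dst_w + (size_t)(h + di) * N;
          const double* s = src + ((size_t)w * Ho + h) * N;
          for (int n = 0; n < N; ++n) dst[n] += s[n];
        }
      }
    }
  }
  return dxp;
}

// Valid/floor max pooling; argmax indices (1-based, into the input array)
// are returned for the backward pass.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int N, int H, int W, int C,
                 int ph, int pw) {
  const int Hp = H / ph, Wp = W / pw;
  NumericVector out((size_t)N * Hp * Wp * C);   // dims restored on the R side
  IntegerVector arg((size_t)N * Hp * Wp * C);
  const double* xv = x.begin();
  double* ov = out.begin();
  int* av = arg.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c) {
    const size_t base_c = (size_t)c * N * H * W;
    for (int wp = 0; wp < Wp; ++wp) {
      for (int hp = 0; hp < Hp; ++hp) {
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          size_t best_i = 0;
          for (int b = 0; b < pw; ++b) {
            for (int a = 0; a < ph; ++a) {
              const size_t i = base_c + (size_t)(wp * pw + b) * N * H +
                               (size_t)(hp * ph + a) * N + n;
              if (xv[i] > best) { best = xv[i]; best_i = i; }
            }
          }
          ov[o] = best;
          av[o] = (int)(best_i + 1);
          ++o;
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector argmax,
                          int in_len) {
  NumericVector dx(in_len);
  double* dv = dx.begin();
  const double* dov = dout.begin();
  const int* av = argmax.begin();
  const size_t m = dout.size();
  for (size_t i = 0; i < m; ++i) dv[av[i] - 1] += dov[i];
  return dx;
}
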