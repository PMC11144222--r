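// im2col / col2im for 3-D 3x3x3 convolutions (padding 1, stride 1 or 2).
// Feature maps are stored as C x nvox matrices with the voxel index linear
// over (d, h, w), d fastest; the column matrix has 27*C rows ordered kernel
// offset-major, channel-minor, so that a convolution is the single GEMM
//   out = W %*% col,  W of shape C_out x (27*C_in).

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_size(int n, int stride) {
  return (n + stride - 1) / stride;  // ceil(n / stride), pad = 1, kernel 3
}

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericMatrix x, IntegerVector dims, int stride) {
  const int C = x.nrow();
  const int d = dims[0], h = dims[1], w = dims[2];
  const int od = out_size(d, stride), oh = out_size(h, stride),
            ow = out_size(w, stride);
  const R_xlen_t nout = (R_xlen_t)od * oh * ow;
  NumericMatrix col(27 * C, nout);
  const double* X = REAL(x);
  double* Cl = REAL(col);
  const int nrow = 27 * C;

  for (int kw = -1; kw <= 1; ++kw) {
    for (int kh = -1; kh <= 1; ++kh) {
      for (int kd = -1; kd <= 1; ++kd) {
        const int ko = (kd + 1) + 3 * (kh + 1) + 9 * (kw + 1);
        for (int iw = 0; iw < ow; ++iw) {
          const int sw = iw * stride + kw;
          for (int ih = 0; ih < oh; ++ih) {
            const int sh = ih * stride + kh;
            for (int id = 0; id < od; ++id) {
              const int sd = id * stride + kd;
              const R_xlen_t oidx = id + (R_xlen_t)od * ih +
                                    (R_xlen_t)od * oh * iw;
              double* dst = Cl + (R_xlen_t)nrow * oidx + (R_xlen_t)ko * C;
              if (sd < 0 || sd >= d || sh < 0 || sh >= h ||
                  sw < 0 || sw >= w) {
                for (int c = 0; c < C; ++c) dst[c] = 0.0;
              } else {
                const R_xlen_t iidx = sd + (R_xlen_t)d * sh +
                                      (R_xlen_t)d * h * sw;
                const double* src = X + (R_xlen_t)C * iidx;
                for (int c = 0; c < C; ++c) dst[c] = src[c];
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// adjoint of im2col3: scatter-add column gradients back to the input grid
// [[Rcpp::export]]
NumericMatrix col2im3_cpp(NumericMatrix gcol, int C, IntegerVector dims,
                          int stride) {
  const int d = dims[0], h = dims[1], w = dims[2];
  const int od = out_size(d, stride), oh = out_size(h, stride),
            ow = out_size(w, stride);
  NumericMatrix gx(C, (R_xlen_t)d * h * w);
  const double* G = REAL(gcol);
  double* X = REAL(gx);
  const int nrow = 27 * C;

  for (int kw = -1; kw <= 1; ++kw) {
    for (int kh = -1; kh <= 1; ++kh) {
      for (int kd = -1; kd <= 1; ++kd) {
        const int ko = (kd + 1) + 3 * (kh + 1) + 9 * (kw + 1);
        for (int iw = 0; iw < ow; ++iw) {
          const int sw = iw * stride + kw;
          if (sw < 0 || sw >= w) continue;
          for (int ih = 0; ih < oh; ++ih) {
            const int sh = ih * stride + kh;
            if (sh < 0 || sh >= h) continue;
            for (int id = 0; id < od; ++id) {
              const int sd = id * stride + kd;
              if (sd < 0 || sd >= d) continue;
              const R_xlen_t oidx = id + (R_xlen_t)od * ih +
                                    (R_xlen_t)od * oh * iw;
              const double* src = G + (R_xlen_t)nrow * oidx +
                                  (R_xlen_t)ko * C;
              const R_xlen_t iidx = sd + (R_xlen_t)d * sh +
                                    (R_xlen_t)d * h * sw;
              double* dst = X + (R_xlen_t)C * iidx;
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
  return gx;
}
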