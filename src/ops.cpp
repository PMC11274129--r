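// Low-level CPU kernels for the layer engine: grouped/dilated 2-D
// convolution (im2col + GEMM) and max pooling, forward and backward.
// Tensor layout everywhere: R array dim c(H, W, C, N), column-major,
// so H varies fastest. Weight layout: dim c(kh, kw, cin_per_group, cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

// Fill the im2col matrix for one (sample, group): rows kh*kw*cg, cols Ho*Wo.
// Row order matches the R weight array flattening: i (kh) fastest, then j
// (kw), then input channel within the group.
static void im2col(const double* x, int H, int W, int cg, int c0,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo, arma::mat& col) {
  const long planeHW = (long)H * W;
  for (int c = 0; c < cg; ++c) {
    const double* xc = x + (long)(c0 + c) * planeHW;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * j + kh * kw * c;
        double* dst = col.memptr() + (long)r; // col is rows x (Ho*Wo)
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * sw - pw + j * dw;
          bool wok = (iw >= 0 && iw < W);
          const double* xcol = xc + (long)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * sh - ph + i * dh;
            double v = 0.0;
            if (wok && ih >= 0 && ih < H) v = xcol[ih];
            col.at(r, (long)ow * Ho + oh) = v;
          }
        }
        (void)dst;
      }
    }
  }
}

// Scatter-add a column-gradient matrix back into the input gradient.
static void col2im(const arma::mat& col, double* dx, int H, int W, int cg,
                   int c0, int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo) {
  const long planeHW = (long)H * W;
  for (int c = 0; c < cg; ++c) {
    double* xc = dx + (long)(c0 + c) * planeHW;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * j + kh * kw * c;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * sw - pw + j * dw;
          if (iw < 0 || iw >= W) continue;
          double* xcol = xc + (long)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * sh - ph + i * dh;
            if (ih < 0 || ih >= H) continue;
            xcol[ih] += col.at(r, (long)ow * Ho + oh);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w,
                        Nullable<NumericVector> bias,
                        int sh, int sw, int ph, int pw,
                        int dh, int dw, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cg = wd[2], cout = wd[3];
  if (C != cg * groups) stop("conv2d: input channels %d != %d x %d groups", C, cg, groups);
  if (cout % groups != 0) stop("conv2d: out channels not divisible by groups");
  int og = cout / groups;
  int Ho = out_dim(H, kh, sh, ph, dh), Wo = out_dim(W, kw, sw, pw, dw);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  NumericVector y((long)Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  arma::mat col(kh * kw * cg, (long)Ho * Wo);
  const double* bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bptr = bv.begin(); }
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long)n * H * W * C;
    double* yn = y.begin() + (long)n * Ho * Wo * cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, cg, g * cg, kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, col);
      // weight matrix for this group: og x (kh*kw*cg)
      arma::mat Wm(const_cast<double*>(w.begin()) + (long)g * og * kh * kw * cg,
                   kh * kw * cg, og, false, true);
      arma::mat out = Wm.t() * col; // og x Ho*Wo
      for (int o = 0; o < og; ++o) {
        double* dst = yn + (long)(g * og + o) * Ho * Wo;
        const double* src = out.memptr() + (long)o; // row o
        for (long p = 0; p < (long)Ho * Wo; ++p) dst[p] = out.at(o, p);
        (void)src;
        if (bptr) {
          double b = bptr[g * og + o];
          for (long p = 0; p < (long)Ho * Wo; ++p) dst[p] += b;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               bool has_bias, int sh, int sw, int ph, int pw,
               int dh, int dw, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cg = wd[2], cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int og = cout / groups;
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw_out((long)kh * kw * cg * cout);
  dw_out.attr("dim") = wd;
  NumericVector db(has_bias ? cout : 0);
  arma::mat col(kh * kw * cg, (long)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long)n * H * W * C;
    double* dxn = dx.begin() + (long)n * H * W * C;
    const double* dyn = dy.begin() + (long)n * Ho * Wo * cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, cg, g * cg, kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, col);
      // gather dY for this group: og x Ho*Wo
      arma::mat dyg(og, (long)Ho * Wo);
      for (int o = 0; o < og; ++o) {
        const double* src = dyn + (long)(g * og + o) * Ho * Wo;
        for (long p = 0; p < (long)Ho * Wo; ++p) dyg.at(o, p) = src[p];
        if (has_bias) {
          double s = 0.0;
          for (long p = 0; p < (long)Ho * Wo; ++p) s += src[p];
          db[g * og + o] += s;
        }
      }
      arma::mat dWm = col * dyg.t(); // (kh*kw*cg) x og
      double* dwg = dw_out.begin() + (long)g * og * kh * kw * cg;
      for (int o = 0; o < og; ++o)
        for (int r = 0; r < kh * kw * cg; ++r)
          dwg[(long)o * kh * kw * cg + r] += dWm.at(r, o);
      arma::mat Wm(const_cast<double*>(w.begin()) + (long)g * og * kh * kw * cg,
                   kh * kw * cg, og, false, true);
      arma::mat dcol = Wm * dyg; // rows x Ho*Wo
      col2im(dcol, dxn, H, W, cg, g * cg, kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo);
    }
  }
  List out = List::create(_["dx"] = dx, _["dw"] = dw_out);
  if (has_bias) out["db"] = db;
  return out;
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_dim(H, k, s, p, 1), Wo = out_dim(W, k, s, p, 1);
  if (Ho <= 0 || Wo <= 0) stop("maxpool: non-positive output size");
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((long)Ho * Wo * C * N); // linear index into the input plane
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((long)n * C + c) * H * W;
      double* yc = y.begin() + ((long)n * C + c) * Ho * Wo;
      int* ic = idx.begin() + ((long)n * C + c) * Ho * Wo;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            int iw = ow * s - p + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < k; ++i) {
              int ih = oh * s - p + i;
              if (ih < 0 || ih >= H) continue;
              double v = xc[(long)iw * H + ih];
              if (v > best) { best = v; besti = iw * H + ih; }
            }
          }
          yc[(long)ow * Ho + oh] = best;
          ic[(long)ow * Ho + oh] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector idx, IntegerVector in_dim) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = in_dim[0], W = in_dim[1];
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dyc = dy.begin() + ((long)n * C + c) * Ho * Wo;
      const int* ic = idx.begin() + ((long)n * C + c) * Ho * Wo;
      double* dxc = dx.begin() + ((long)n * C + c) * H * W;
      for (long p = 0; p < (long)Ho * Wo; ++p)
        if (ic[p] >= 0) dxc[ic[p]] += dyc[p];
    }
  }
  return dx;
}
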