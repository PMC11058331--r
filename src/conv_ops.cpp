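// Minimal 2D CNN kernels for the segmentation backbone.
// Tensor layout everywhere: R arrays with dim (H, W, C, N), column-major,
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).
// Convolutions are stride-1 with "same" zero padding; kernels are square.

#include <RcppArmadillo.h>
using namespace Rcpp;


static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static inline void get_dim4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample, transposed layout: col is (H*W) x (C*k*k),
// column q = c*k*k + di*k + dj, row s = h + H*w (contiguous in h).
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        double* dst = col.colptr(c * k * k + di * k + dj);
        for (int w = 0; w < W; ++w) {
          int wi = w + dj - pad;
          double* d = dst + (size_t)H * w;
          if (wi < 0 || wi >= W) {
            std::fill(d, d + H, 0.0);
          } else {
            const double* src = xc + (size_t)H * wi;
            int h0 = std::max(0, pad - di), h1 = std::min(H, H + pad - di);
            for (int h = 0; h < h0; ++h) d[h] = 0.0;
            for (int h = h0; h < h1; ++h) d[h] = src[h + di - pad];
            for (int h = h1; h < H; ++h) d[h] = 0.0;
          }
        }
      }
  }
}

// scatter-add transpose of im2col (same layout)
static void col2im_add(const arma::mat& col, int H, int W, int C, int k, int pad,
                       double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)H * W * c;
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const double* src0 = col.colptr(c * k * k + di * k + dj);
        for (int w = 0; w < W; ++w) {
          int wi = w + dj - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = xc + (size_t)H * wi;
          const double* src = src0 + (size_t)H * w;
          int h0 = std::max(0, pad - di), h1 = std::min(H, H + pad - di);
          for (int h = h0; h < h1; ++h) dst[h + di - pad] += src[h];
        }
      }
  }
}

// weights come in as an R array (k, k, Cin, F); flatten to (Cin*k*k x F)
// with the row layout im2col expects.
static arma::mat weight_mat(const NumericVector& w, int k, int C, int F) {
  arma::mat Wm(C * k * k, F);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          Wm(c * k * k + di * k + dj, f) =
            w[di + k * ((size_t)dj + k * ((size_t)c + (size_t)C * f))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != wd[1] || wd[2] != C)
    stop("weight dim must be (k,k,Cin,F) with Cin matching input");
  int k = wd[0], F = wd[3], pad = (k - 1) / 2;
  arma::mat Wm = weight_mat(w, k, C, F);
  arma::rowvec bv(b.begin(), F, false);

  NumericVector y = alloc4(H, W, F, N);
  arma::mat col((size_t)H * W, C * k * k);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad, col);
    // output slab of sample n is exactly an (H*W) x F column-major block
    arma::mat Y(y.begin() + (size_t)H * W * F * n, (size_t)H * W, F, false, true);
    Y = col * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], F = wd[3], pad = (k - 1) / 2;
  arma::mat Wm = weight_mat(w, k, C, F);

  arma::mat Gw(C * k * k, F, arma::fill::zeros);
  arma::rowvec Gb(F, arma::fill::zeros);
  NumericVector gx = alloc4(H, W, C, N);
  arma::mat col((size_t)H * W, C * k * k);

  for (int n = 0; n < N; ++n) {
    const arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)H * W * F * n,
                       (size_t)H * W, F, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad, col);
    Gw += col.t() * Gy;
    Gb += arma::sum(Gy, 0);
    arma::mat Gcol = Gy * Wm.t();      // (H*W) x (C*k*k)
    col2im_add(Gcol, H, W, C, k, pad, gx.begin() + (size_t)H * W * C * n);
  }

  NumericVector gw = alloc4(k, k, C, F);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          gw[di + k * ((size_t)dj + k * ((size_t)c + (size_t)C * f))] =
            Gw(c * k * k + di * k + dj, f);
  NumericVector gb(F);
  std::copy(Gb.begin(), Gb.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and 0-based argmax
// flat indices into the input array (for the backward scatter).
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t ii = base + (size_t)(2 * ho + di) + (size_t)H * (2 * wo + dj);
              if (x[ii] > best) { best = x[ii]; bidx = ii; }
            }
          y[obase + ho + (size_t)Ho * wo] = best;
          idx[obase + ho + (size_t)Ho * wo] = (int)bidx;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  NumericVector gx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// Bilinear 2x upsampling (align_corners = FALSE convention:
// input coordinate of output pixel o is (o + 0.5)/2 - 0.5, edges clamped).
static void up2_weights(int o, int Hin, int& lo, int& hi, double& wlo, double& whi) {
  double pos = (o + 0.5) / 2.0 - 0.5;
  if (pos < 0) pos = 0;
  if (pos > Hin - 1) pos = Hin - 1;
  lo = (int)std::floor(pos);
  hi = std::min(lo + 1, Hin - 1);
  whi = pos - lo; wlo = 1.0 - whi;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, C, N);
  std::vector<int> hlo(Ho), hhi(Ho), wlo(Wo), whi(Wo);
  std::vector<double> hwl(Ho), hwh(Ho), wwl(Wo), wwh(Wo);
  for (int o = 0; o < Ho; ++o) up2_weights(o, H, hlo[o], hhi[o], hwl[o], hwh[o]);
  for (int o = 0; o < Wo; ++o) up2_weights(o, W, wlo[o], whi[o], wwl[o], wwh[o]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double v = wwl[ow] * (hwl[oh] * xc[hlo[oh] + (size_t)H * wlo[ow]] +
                                hwh[oh] * xc[hhi[oh] + (size_t)H * wlo[ow]]) +
                     wwh[ow] * (hwl[oh] * xc[hlo[oh] + (size_t)H * whi[ow]] +
                                hwh[oh] * xc[hhi[oh] + (size_t)H * whi[ow]]);
          yc[oh + (size_t)Ho * ow] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx = alloc4(H, W, C, N);
  std::vector<int> hlo(Ho), hhi(Ho), wlo(Wo), whi(Wo);
  std::vector<double> hwl(Ho), hwh(Ho), wwl(Wo), wwh(Wo);
  for (int o = 0; o < Ho; ++o) up2_weights(o, H, hlo[o], hhi[o], hwl[o], hwh[o]);
  for (int o = 0; o < Wo; ++o) up2_weights(o, W, wlo[o], whi[o], wwl[o], wwh[o]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* yc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double g = yc[oh + (size_t)Ho * ow];
          xc[hlo[oh] + (size_t)H * wlo[ow]] += wwl[ow] * hwl[oh] * g;
          xc[hhi[oh] + (size_t)H * wlo[ow]] += wwl[ow] * hwh[oh] * g;
          xc[hlo[oh] + (size_t)H * whi[ow]] += wwh[ow] * hwl[oh] * g;
          xc[hhi[oh] + (size_t)H * whi[ow]] += wwh[ow] * hwh[oh] * g;
        }
    }
  return gx;
}

// ---- batch normalization over (H,W,N) per channel ----

// per-channel biased mean and variance of an (H,W,C,N) array
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  NumericVector mu(C), var(C);
  double m = (double)H * W * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)H * W; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    mu[c] = s / m;
    var[c] = s2 / m - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// normalize with given per-channel mean/var; returns y and xhat
// [[Rcpp::export]]
List bn_apply_cpp(NumericVector x, NumericVector g, NumericVector b,
                  NumericVector mu, NumericVector var, double eps) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  NumericVector y = alloc4(H, W, C, N), xhat = alloc4(H, W, C, N), ivar(C);
  for (int c = 0; c < C; ++c) ivar[c] = 1.0 / std::sqrt(var[c] + eps);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* py = y.begin() + off;
      double m0 = mu[c], iv = ivar[c], gg = g[c], bb = b[c];
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        ph[i] = (p[i] - m0) * iv;
        py[i] = gg * ph[i] + bb;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["ivar"] = ivar);
}

// backward; train=TRUE uses the batch-statistics chain rule
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector xhat, NumericVector ivar, NumericVector g,
                NumericVector gy, bool train) {
  int H, W, C, N; get_dim4(xhat, H, W, C, N);
  NumericVector gg(C), gb(C);
  NumericVector gx = alloc4(H, W, C, N);
  double m = (double)H * W * N;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* ph = xhat.begin() + off;
      const double* pg = gy.begin() + off;
      for (size_t i = 0; i < (size_t)H * W; ++i) {
        sg += pg[i];
        sgx += pg[i] * ph[i];
      }
    }
    gg[c] = sgx; gb[c] = sg;
    double c1 = train ? sg / m : 0.0, c2 = train ? sgx / m : 0.0;
    double k = ivar[c] * g[c];
    for (int n = 0; n < N; ++n) {
      size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double* ph = xhat.begin() + off;
      const double* pg = gy.begin() + off;
      double* px = gx.begin() + off;
      for (size_t i = 0; i < (size_t)H * W; ++i)
        px[i] = k * (pg[i] - c1 - ph[i] * c2);
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}
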