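#include <Rcpp.h>
using namespace Rcpp;

// Activations use an NHWC-flattened layout: a (B*H*W) x C matrix whose row
// index is b*H*W + y*W + x (0-based). Patch columns are ordered kernel-position
// major, channel minor: col = (ky*kw + kx)*C + c.

// [[Rcpp::export]]
NumericMatrix nn_im2col(const NumericMatrix& X, int B, int H, int W,
                        int kh, int kw, int sh, int sw,
                        int padT, int padL, int Ho, int Wo) {
  const int C = X.ncol();
  NumericMatrix out((R_xlen_t)B * Ho * Wo, (R_xlen_t)kh * kw * C);
  const double* Xp = REAL(X);
  double* Op = REAL(out);
  const R_xlen_t orows = (R_xlen_t)B * Ho * Wo;
  // column-outer loops so both matrices are written/read down columns
  for (int ky = 0; ky < kh; ++ky) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int c = 0; c < C; ++c) {
        double* ocol = Op + (((R_xlen_t)ky * kw + kx) * C + c) * orows;
        const double* xcol = Xp + (R_xlen_t)c * B * H * W;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t xb = (R_xlen_t)b * H * W;
          for (int oy = 0; oy < Ho; ++oy) {
            const int y = oy * sh - padT + ky;
            double* orow = ocol + (R_xlen_t)b * Ho * Wo + (R_xlen_t)oy * Wo;
            if (y < 0 || y >= H) continue; // zero pad (matrix starts zeroed)
            const double* xrow = xcol + xb + (R_xlen_t)y * W;
            for (int ox = 0; ox < Wo; ++ox) {
              const int x = ox * sw - padL + kx;
              if (x >= 0 && x < W) orow[ox] = xrow[x];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix nn_col2im(const NumericMatrix& cols, int B, int H, int W, int C,
                        int kh, int kw, int sh, int sw,
                        int padT, int padL, int Ho, int Wo) {
  NumericMatrix dX((R_xlen_t)B * H * W, C);
  const double* Cp = REAL(cols);
  double* Dp = REAL(dX);
  const R_xlen_t orows = (R_xlen_t)B * Ho * Wo;
  for (int ky = 0; ky < kh; ++ky) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int c = 0; c < C; ++c) {
        const double* ocol = Cp + (((R_xlen_t)ky * kw + kx) * C + c) * orows;
        double* dcol = Dp + (R_xlen_t)c * B * H * W;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t xb = (R_xlen_t)b * H * W;
          for (int oy = 0; oy < Ho; ++oy) {
            const int y = oy * sh - padT + ky;
            if (y < 0 || y >= H) continue;
            const double* orow = ocol + (R_xlen_t)b * Ho * Wo + (R_xlen_t)oy * Wo;
            double* drow = dcol + xb + (R_xlen_t)y * W;
            for (int ox = 0; ox < Wo; ++ox) {
              const int x = ox * sw - padL + kx;
              if (x >= 0 && x < W) drow[x] += orow[ox];
            }
          }
        }
      }
    }
  }
  return dX;
}

// direct convolution for small output-channel counts (the stem), where the
// im2col buffer would dwarf the arithmetic
// [[Rcpp::export]]
NumericMatrix nn_conv_direct_fw(const NumericMatrix& X, const NumericMatrix& Wm,
                                int B, int H, int W,
                                int kh, int kw, int sh, int sw,
                                int padT, int padL, int Ho, int Wo) {
  const int C = X.ncol();
  const int K = Wm.ncol();
  NumericMatrix out((R_xlen_t)B * Ho * Wo, K);
  const double* Xp = REAL(X);
  const double* Wp = REAL(Wm);
  double* Op = REAL(out);
  const R_xlen_t orows = (R_xlen_t)B * Ho * Wo;
  const R_xlen_t xrows = (R_xlen_t)B * H * W;
  std::vector<double> acc(K);
  for (int b = 0; b < B; ++b) {
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int ky = 0; ky < kh; ++ky) {
          const int y = oy * sh - padT + ky;
          if (y < 0 || y >= H) continue;
          for (int kx = 0; kx < kw; ++kx) {
            const int x = ox * sw - padL + kx;
            if (x < 0 || x >= W) continue;
            const R_xlen_t irow = (R_xlen_t)b * H * W + (R_xlen_t)y * W + x;
            const R_xlen_t wrow0 = ((R_xlen_t)ky * kw + kx) * C;
            for (int c = 0; c < C; ++c) {
              const double xv = Xp[irow + (R_xlen_t)c * xrows];
              const double* wr = Wp + wrow0 + c;
              for (int k = 0; k < K; ++k) acc[k] += xv * wr[(R_xlen_t)k * Wm.nrow()];
            }
          }
        }
        const R_xlen_t orow = (R_xlen_t)b * Ho * Wo + (R_xlen_t)oy * Wo + ox;
        for (int k = 0; k < K; ++k) Op[orow + (R_xlen_t)k * orows] = acc[k];
      }
    }
  }
  return out;
}

// weight gradient for the direct path (input gradient is never needed: the
// direct path is only taken by the first layer)
// [[Rcpp::export]]
NumericMatrix nn_conv_direct_dw(const NumericMatrix& X, const NumericMatrix& dY,
                                int B, int H, int W,
                                int kh, int kw, int sh, int sw,
                                int padT, int padL, int Ho, int Wo) {
  const int C = X.ncol();
  const int K = dY.ncol();
  NumericMatrix dW((R_xlen_t)kh * kw * C, K);
  const double* Xp = REAL(X);
  const double* Yp = REAL(dY);
  double* Dp = REAL(dW);
  const R_xlen_t orows = (R_xlen_t)B * Ho * Wo;
  const R_xlen_t xrows = (R_xlen_t)B * H * W;
  for (int b = 0; b < B; ++b) {
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        const R_xlen_t orow = (R_xlen_t)b * Ho * Wo + (R_xlen_t)oy * Wo + ox;
        for (int ky = 0; ky < kh; ++ky) {
          const int y = oy * sh - padT + ky;
          if (y < 0 || y >= H) continue;
          for (int kx = 0; kx < kw; ++kx) {
            const int x = ox * sw - padL + kx;
            if (x < 0 || x >= W) continue;
            const R_xlen_t irow = (R_xlen_t)b * H * W + (R_xlen_t)y * W + x;
            const R_xlen_t wrow0 = ((R_xlen_t)ky * kw + kx) * C;
            for (int c = 0; c < C; ++c) {
              const double xv = Xp[irow + (R_xlen_t)c * xrows];
              for (int k = 0; k < K; ++k)
                Dp[wrow0 + c + (R_xlen_t)k * dW.nrow()] +=
                  xv * Yp[orow + (R_xlen_t)k * orows];
            }
          }
        }
      }
    }
  }
  return dW;
}

// batch-norm forward: per-column standardize and scale-shift in one pass,
// returning both the normalized activations (backward cache) and the output
// [[Rcpp::export]]
List bn_apply(const NumericMatrix& X, const NumericVector& mu,
              const NumericVector& inv_std, const NumericVector& gamma,
              const NumericVector& beta) {
  const R_xlen_t n = X.nrow();
  const int C = X.ncol();
  NumericMatrix xhat(n, C), out(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = inv_std[c], g = gamma[c], b = beta[c];
    const double* xc = &X(0, c);
    double* hc = &xhat(0, c);
    double* oc = &out(0, c);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * is;
      hc[i] = h;
      oc[i] = h * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// per-column mean and biased variance in one pass
// [[Rcpp::export]]
List bn_stats(const NumericMatrix& X) {
  const R_xlen_t n = X.nrow();
  const int C = X.ncol();
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    mu[c] = s / n;
    double v = s2 / n - mu[c] * mu[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// batch-norm backward: standard whitened-statistics gradient
// [[Rcpp::export]]
List bn_backward(const NumericMatrix& dY, const NumericMatrix& xhat,
                 const NumericVector& inv_std, const NumericVector& gamma) {
  const R_xlen_t n = dY.nrow();
  const int C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dY(0, c);
    const double* hc = &xhat(0, c);
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < n; ++i) { sg += dyc[i] * hc[i]; sb += dyc[i]; }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], is = inv_std[c];
    const double mean_dxhat = g * sb / n, mean_dxhat_xhat = g * sg / n;
    double* dxc = &dX(0, c);
    for (R_xlen_t i = 0; i < n; ++i)
      dxc[i] = (g * dyc[i] - mean_dxhat - hc[i] * mean_dxhat_xhat) * is;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List nn_maxpool_fw(const NumericMatrix& X, int B, int H, int W,
                   int kh, int kw, int sh, int sw,
                   int padT, int padL, int Ho, int Wo) {
  const int C = X.ncol();
  NumericMatrix out((R_xlen_t)B * Ho * Wo, C);
  IntegerMatrix idx((R_xlen_t)B * Ho * Wo, C);
  for (int b = 0; b < B; ++b) {
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        const R_xlen_t orow = (R_xlen_t)b * Ho * Wo + (R_xlen_t)oy * Wo + ox;
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          int best_row = -1;
          for (int ky = 0; ky < kh; ++ky) {
            const int y = oy * sh - padT + ky;
            if (y < 0 || y >= H) continue;
            for (int kx = 0; kx < kw; ++kx) {
              const int x = ox * sw - padL + kx;
              if (x < 0 || x >= W) continue;
              const R_xlen_t irow = (R_xlen_t)b * H * W + (R_xlen_t)y * W + x;
              const double v = X(irow, c);
              if (v > best) { best = v; best_row = (int)irow; }
            }
          }
          out(orow, c) = best;
          idx(orow, c) = best_row;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix nn_maxpool_bw(const NumericMatrix& dY, const IntegerMatrix& idx,
                            int n_rows_in) {
  const int C = dY.ncol();
  NumericMatrix dX(n_rows_in, C);
  for (R_xlen_t r = 0; r < dY.nrow(); ++r)
    for (int c = 0; c < C; ++c)
      if (idx(r, c) >= 0) dX(idx(r, c), c) += dY(r, c);
  return dX;
}

// Bilinear resampling of an H x W x C array (R column-major layout) to
// outH x outW. Sampling uses the half-pixel centre convention
// src = (dst + 0.5) * (in/out) - 0.5, clamped at the borders.
// [[Rcpp::export]]
NumericVector resize_bilinear(const NumericVector& img, int H, int W, int C,
                              int outH, int outW) {
  NumericVector out((R_xlen_t)outH * outW * C);
  const double sy = (double)H / outH, sx = (double)W / outW;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t ioff = (R_xlen_t)c * H * W, ooff = (R_xlen_t)c * outH * outW;
    for (int oy = 0; oy < outH; ++oy) {
      double fy = (oy + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0; if (fy > H - 1) fy = H - 1;
      const int y0 = (int)fy, y1 = y0 + 1 < H ? y0 + 1 : y0;
      const double wy = fy - y0;
      for (int ox = 0; ox < outW; ++ox) {
        double fx = (ox + 0.5) * sx - 0.5;
        if (fx < 0) fx = 0; if (fx > W - 1) fx = W - 1;
        const int x0 = (int)fx, x1 = x0 + 1 < W ? x0 + 1 : x0;
        const double wx = fx - x0;
        const double v00 = img[ioff + y0 + (R_xlen_t)H * x0];
        const double v01 = img[ioff + y0 + (R_xlen_t)H * x1];
        const double v10 = img[ioff + y1 + (R_xlen_t)H * x0];
        const double v11 = img[ioff + y1 + (R_xlen_t)H * x1];
        out[ooff + oy + (R_xlen_t)outH * ox] =
          (1 - wy) * ((1 - wx) * v00 + wx * v01) +
          wy * ((1 - wx) * v10 + wx * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(outH, outW, C);
  return out;
}
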