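// Convolution and pooling primitives for the ghostherd network engine.
//
// Tensor layout (column-major, matching R arrays):
//   activations: dim (H, W, C, N)  -- H fastest
//   conv weight: dim (k, k, C_in/groups, C_out)
//
// Three execution paths keep training fast on one CPU core:
//   * pointwise (1x1, groups = 1): per-sample GEMM on channel views,
//   * depthwise (groups = C_in): direct tap loops,
//   * general: im2col batched over the whole minibatch, one GEMM per group.
// im2col row order is (kh, kw, c_in) so a flattened weight slice multiplies
// the patch matrix directly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Fill columns [n*Ho*Wo, (n+1)*Ho*Wo) of `col` ((k*k*cpg) x (Ho*Wo*N)) with
// patches of channels [c0, c0+cpg) of sample n.
static void im2col(const double* x, int H, int W,
                   int k, int stride, int pad, int dil,
                   int c0, int cpg, int Ho, int Wo,
                   arma::mat& col, std::size_t col0) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      double* dst = col.colptr(col0 + oh + (std::size_t)Ho * ow);
      for (int ci = 0; ci < cpg; ++ci) {
        const double* xc = x + (std::size_t)(c0 + ci) * H * W;
        for (int iw = 0; iw < k; ++iw) {
          int wpos = ow * stride - pad + iw * dil;
          bool win = wpos >= 0 && wpos < W;
          for (int ih = 0; ih < k; ++ih) {
            int hpos = oh * stride - pad + ih * dil;
            double v = 0.0;
            if (win && hpos >= 0 && hpos < H)
              v = xc[hpos + (std::size_t)H * wpos];
            dst[ih + k * (iw + k * ci)] = v;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, std::size_t col0, double* gx,
                   int H, int W, int k, int stride, int pad, int dil,
                   int c0, int cpg, int Ho, int Wo) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const double* src = col.colptr(col0 + oh + (std::size_t)Ho * ow);
      for (int ci = 0; ci < cpg; ++ci) {
        double* gc = gx + (std::size_t)(c0 + ci) * H * W;
        for (int iw = 0; iw < k; ++iw) {
          int wpos = ow * stride - pad + iw * dil;
          if (wpos < 0 || wpos >= W) continue;
          for (int ih = 0; ih < k; ++ih) {
            int hpos = oh * stride - pad + ih * dil;
            if (hpos < 0 || hpos >= H) continue;
            gc[hpos + (std::size_t)H * wpos] += src[ih + k * (iw + k * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, int k, int cout,
                             int stride, int pad, int dil, int groups,
                             Nullable<NumericVector> bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int cpg = C / groups, coutg = cout / groups;
  int Ho = out_extent(H, k, stride, pad, dil);
  int Wo = out_extent(W, k, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0)
    stop("convolution output would be empty (input %dx%d, kernel %d)", H, W, k);
  std::size_t kkc = (std::size_t)k * k * cpg;
  std::size_t plane = (std::size_t)Ho * Wo;
  std::size_t iplane = (std::size_t)H * W;

  NumericVector y(plane * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);

  if (k == 1 && dil == 1 && groups == 1 && stride == 1) {
    // pointwise: per-sample GEMM on the (plane x C) channel view
    arma::mat Wm(const_cast<double*>(w.begin()), C, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (std::size_t)n * iplane * C,
                   iplane, C, false, true);
      arma::mat Yn(y.begin() + (std::size_t)n * plane * cout,
                   plane, cout, false, true);
      Yn = Xn * Wm;
    }
  } else if (groups == C && cpg == 1) {
    // depthwise: direct tap loops
    for (int n = 0; n < N; ++n) {
      const double* xn = x.begin() + (std::size_t)n * iplane * C;
      for (int c = 0; c < C; ++c) {
        const double* xc = xn + (std::size_t)c * iplane;
        for (int m = 0; m < coutg; ++m) {
          const double* wk = w.begin() + (std::size_t)(c * coutg + m) * k * k;
          double* yc = y.begin() + ((std::size_t)n * cout + c * coutg + m) * plane;
          for (int ow = 0; ow < Wo; ++ow)
            for (int oh = 0; oh < Ho; ++oh) {
              double acc = 0.0;
              for (int iw = 0; iw < k; ++iw) {
                int wpos = ow * stride - pad + iw * dil;
                if (wpos < 0 || wpos >= W) continue;
                for (int ih = 0; ih < k; ++ih) {
                  int hpos = oh * stride - pad + ih * dil;
                  if (hpos < 0 || hpos >= H) continue;
                  acc += wk[ih + k * iw] * xc[hpos + (std::size_t)H * wpos];
                }
              }
              yc[oh + (std::size_t)Ho * ow] = acc;
            }
        }
      }
    }
  } else {
    // general: batch the whole minibatch into one GEMM per group
    arma::mat col(kkc, plane * N);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n)
        im2col(x.begin() + (std::size_t)n * iplane * C, H, W, k, stride, pad,
               dil, g * cpg, cpg, Ho, Wo, col, (std::size_t)n * plane);
      arma::mat Wm(const_cast<double*>(w.begin()) + kkc * coutg * g,
                   kkc, coutg, false, true);
      arma::mat Y = col.t() * Wm;  // (plane*N) x coutg
      for (int oc = 0; oc < coutg; ++oc) {
        const double* src = Y.colptr(oc);
        for (int n = 0; n < N; ++n)
          std::memcpy(y.begin() + plane * (g * coutg + oc) +
                          (std::size_t)n * plane * cout,
                      src + (std::size_t)n * plane, plane * sizeof(double));
      }
    }
  }

  if (bias.isNotNull()) {
    NumericVector b(bias.get());
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        double bv = b[c];
        double* yc = y.begin() + ((std::size_t)n * cout + c) * plane;
        for (std::size_t i = 0; i < plane; ++i) yc[i] += bv;
      }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, int k, int cout,
                    NumericVector gy,
                    int stride, int pad, int dil, int groups,
                    bool has_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int cpg = C / groups, coutg = cout / groups;
  int Ho = out_extent(H, k, stride, pad, dil);
  int Wo = out_extent(W, k, stride, pad, dil);
  std::size_t kkc = (std::size_t)k * k * cpg;
  std::size_t plane = (std::size_t)Ho * Wo;
  std::size_t iplane = (std::size_t)H * W;

  NumericVector gx(x.size());
  gx.attr("dim") = xdim;
  NumericVector gw(w.size());
  gw.attr("dim") = IntegerVector::create(k, k, cpg, cout);
  NumericVector gb(has_bias ? cout : 0);

  if (k == 1 && dil == 1 && groups == 1 && stride == 1) {
    arma::mat Wm(const_cast<double*>(w.begin()), C, cout, false, true);
    arma::mat gWm(gw.begin(), C, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (std::size_t)n * iplane * C,
                   iplane, C, false, true);
      arma::mat Gy(const_cast<double*>(gy.begin()) + (std::size_t)n * plane * cout,
                   plane, cout, false, true);
      arma::mat Gx(gx.begin() + (std::size_t)n * iplane * C,
                   iplane, C, false, true);
      gWm += Xn.t() * Gy;
      Gx = Gy * Wm.t();
    }
  } else if (groups == C && cpg == 1) {
    for (int n = 0; n < N; ++n) {
      const double* xn = x.begin() + (std::size_t)n * iplane * C;
      double* gxn = gx.begin() + (std::size_t)n * iplane * C;
      for (int c = 0; c < C; ++c) {
        const double* xc = xn + (std::size_t)c * iplane;
        double* gxc = gxn + (std::size_t)c * iplane;
        for (int m = 0; m < coutg; ++m) {
          const double* wk = w.begin() + (std::size_t)(c * coutg + m) * k * k;
          double* gwk = gw.begin() + (std::size_t)(c * coutg + m) * k * k;
          const double* gyc = gy.begin() +
            ((std::size_t)n * cout + c * coutg + m) * plane;
          for (int ow = 0; ow < Wo; ++ow)
            for (int oh = 0; oh < Ho; ++oh) {
              double g = gyc[oh + (std::size_t)Ho * ow];
              if (g == 0.0) continue;
              for (int iw = 0; iw < k; ++iw) {
                int wpos = ow * stride - pad + iw * dil;
                if (wpos < 0 || wpos >= W) continue;
                for (int ih = 0; ih < k; ++ih) {
                  int hpos = oh * stride - pad + ih * dil;
                  if (hpos < 0 || hpos >= H) continue;
                  double xv = xc[hpos + (std::size_t)H * wpos];
                  gwk[ih + k * iw] += g * xv;
                  gxc[hpos + (std::size_t)H * wpos] += g * wk[ih + k * iw];
                }
              }
            }
        }
      }
    }
  } else {
    arma::mat col(kkc, plane * N);
    arma::mat gyv(plane * N, coutg);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        im2col(x.begin() + (std::size_t)n * iplane * C, H, W, k, stride, pad,
               dil, g * cpg, cpg, Ho, Wo, col, (std::size_t)n * plane);
        for (int oc = 0; oc < coutg; ++oc)
          std::memcpy(gyv.colptr(oc) + (std::size_t)n * plane,
                      gy.begin() + plane * (g * coutg + oc) +
                          (std::size_t)n * plane * cout,
                      plane * sizeof(double));
      }
      arma::mat gWm(gw.begin() + kkc * coutg * g, kkc, coutg, false, true);
      gWm += col * gyv;
      arma::mat Wm(const_cast<double*>(w.begin()) + kkc * coutg * g,
                   kkc, coutg, false, true);
      arma::mat gcol = Wm * gyv.t();  // kkc x (plane*N)
      for (int n = 0; n < N; ++n)
        col2im(gcol, (std::size_t)n * plane,
               gx.begin() + (std::size_t)n * iplane * C,
               H, W, k, stride, pad, dil, g * cpg, cpg, Ho, Wo);
    }
  }

  if (has_bias)
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        const double* gyc = gy.begin() + ((std::size_t)n * cout + c) * plane;
        double s = 0.0;
        for (std::size_t i = 0; i < plane; ++i) s += gyc[i];
        gb[c] += s;
      }
  if (has_bias) return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Batch-norm forward over (H, W, C, N): per-channel standardization with
// affine transform; returns y and, when training, xhat for the backward pass.
// [[Rcpp::export]]
List batchnorm_fwd_cpp(NumericVector x, IntegerVector xdim,
                       NumericVector mu, NumericVector ivar,
                       NumericVector gamma, NumericVector beta,
                       bool keep_xhat) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  std::size_t plane = (std::size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xdim;
  NumericVector xhat(keep_xhat ? x.size() : 0);
  if (keep_xhat) xhat.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      std::size_t off = ((std::size_t)n * C + c) * plane;
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      double m = mu[c], iv = ivar[c], g = gamma[c], b = beta[c];
      if (keep_xhat) {
        double* hc = xhat.begin() + off;
        for (std::size_t i = 0; i < plane; ++i) {
          double h = (xc[i] - m) * iv;
          hc[i] = h;
          yc[i] = g * h + b;
        }
      } else {
        for (std::size_t i = 0; i < plane; ++i)
          yc[i] = g * (xc[i] - m) * iv + b;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// per-channel moments over (H, W, N); returns mean and biased variance
// [[Rcpp::export]]
List channel_moments_cpp(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  std::size_t plane = (std::size_t)H * W;
  NumericVector mu(C), var(C);
  double M = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * plane;
      for (std::size_t i = 0; i < plane; ++i) {
        s += xc[i];
        s2 += xc[i] * xc[i];
      }
    }
    mu[c] = s / M;
    double v = s2 / M - mu[c] * mu[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// batch-norm backward given xhat; returns gx, ggamma, gbeta
// [[Rcpp::export]]
List batchnorm_bwd_cpp(NumericVector gy, NumericVector xhat,
                       IntegerVector xdim, NumericVector gamma,
                       NumericVector ivar) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  std::size_t plane = (std::size_t)H * W;
  double M = (double)plane * N;
  NumericVector gx(gy.size());
  gx.attr("dim") = xdim;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgh = 0.0;
    for (int n = 0; n < N; ++n) {
      std::size_t off = ((std::size_t)n * C + c) * plane;
      const double* g = gy.begin() + off;
      const double* h = xhat.begin() + off;
      for (std::size_t i = 0; i < plane; ++i) {
        sg += g[i];
        sgh += g[i] * h[i];
      }
    }
    ggamma[c] = sgh;
    gbeta[c] = sg;
    double a = gamma[c] * ivar[c];
    double t1 = sg / M, t2 = sgh / M;
    for (int n = 0; n < N; ++n) {
      std::size_t off = ((std::size_t)n * C + c) * plane;
      const double* g = gy.begin() + off;
      const double* h = xhat.begin() + off;
      double* gxc = gx.begin() + off;
      for (std::size_t i = 0; i < plane; ++i)
        gxc[i] = a * (g[i] - t1 - h[i] * t2);
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector xdim,
                     int k, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = out_extent(H, k, stride, pad, 1);
  int Wo = out_extent(W, k, stride, pad, 1);
  std::size_t plane = (std::size_t)Ho * Wo;
  NumericVector y(plane * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // argmax as 0-based index into the H*W plane

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((std::size_t)n * C + c) * H * W;
      double* yc = y.begin() + ((std::size_t)n * C + c) * plane;
      int* ic = idx.begin() + ((std::size_t)n * C + c) * plane;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int iw = 0; iw < k; ++iw) {
            int wpos = ow * stride - pad + iw;
            if (wpos < 0 || wpos >= W) continue;
            for (int ih = 0; ih < k; ++ih) {
              int hpos = oh * stride - pad + ih;
              if (hpos < 0 || hpos >= H) continue;
              double v = xc[hpos + (std::size_t)H * wpos];
              if (v > best) { best = v; bi = hpos + H * wpos; }
            }
          }
          yc[oh + (std::size_t)Ho * ow] = best;
          ic[oh + (std::size_t)Ho * ow] = bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector gy, IntegerVector idx,
                              IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  std::size_t plane = gy.size() / ((std::size_t)C * N);
  for (std::size_t cn = 0; cn < (std::size_t)C * N; ++cn) {
    double* g = gx.begin() + cn * H * W;
    const double* gyc = gy.begin() + cn * plane;
    const int* ic = idx.begin() + cn * plane;
    for (std::size_t i = 0; i < plane; ++i)
      if (ic[i] >= 0) g[ic[i]] += gyc[i];
  }
  return gx;
}

// fused ReLU forward; backward masks on the cached output
// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yi = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yi[i] = xi[i] > 0 ? xi[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector gy, NumericVector y) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* g = gy.begin();
  const double* yi = y.begin();
  double* o = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) o[i] = yi[i] > 0 ? g[i] : 0;
  return gx;
}
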