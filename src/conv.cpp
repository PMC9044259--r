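#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are (H*W*N) x C matrices, column-major planes:
// row index r = h + H*(w + W*n), column = channel.
// Weights are (k, k, Cin/groups, Cout) arrays; pad = k/2 ("same" for stride 1,
// exact halving for even H, W with stride 2).

static inline int out_size(int H, int k, int stride) {
  int pad = k / 2;
  return (H + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix conv2d_fwd_cpp(const NumericMatrix& x, int H, int W, int N,
                             const NumericVector& weight, int k, int Cpg,
                             int Cout, int stride, int groups) {
  const int Cin = x.ncol();
  const int pad = k / 2;
  const int Ho = out_size(H, k, stride), Wo = out_size(W, k, stride);
  const int copg = Cout / groups;
  NumericMatrix y(Ho * Wo * N, Cout);
  const double* xp = x.begin();
  const double* wp = weight.begin();
  double* yp = y.begin();
  const R_xlen_t planeIn = (R_xlen_t)H * W, rowsIn = planeIn * N;
  const R_xlen_t planeOut = (R_xlen_t)Ho * Wo, rowsOut = planeOut * N;

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / copg;
      double* O = yp + (R_xlen_t)co * rowsOut + (R_xlen_t)n * planeOut;
      for (int cig = 0; cig < Cpg; ++cig) {
        const int ci = g * Cpg + cig;
        const double* P = xp + (R_xlen_t)ci * rowsIn + (R_xlen_t)n * planeIn;
        for (int kw = 0; kw < k; ++kw) {
          for (int kh = 0; kh < k; ++kh) {
            const double wgt =
                wp[kh + k * (kw + k * (cig + (R_xlen_t)Cpg * co))];
            if (wgt == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride + kw - pad;
              if (wi < 0 || wi >= W) continue;
              const double* Pc = P + (R_xlen_t)H * wi;
              double* Oc = O + (R_xlen_t)Ho * wo;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride + kh - pad;
                if (hi < 0 || hi >= H) continue;
                Oc[ho] += wgt * Pc[hi];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix conv2d_bwd_input_cpp(const NumericMatrix& dy, int H, int W,
                                   int N, const NumericVector& weight, int k,
                                   int Cpg, int Cin, int stride, int groups) {
  const int Cout = dy.ncol();
  const int pad = k / 2;
  const int Ho = out_size(H, k, stride), Wo = out_size(W, k, stride);
  const int copg = Cout / groups;
  NumericMatrix dx((R_xlen_t)H * W * N, Cin);
  const double* dyp = dy.begin();
  const double* wp = weight.begin();
  double* dxp = dx.begin();
  const R_xlen_t planeIn = (R_xlen_t)H * W, rowsIn = planeIn * N;
  const R_xlen_t planeOut = (R_xlen_t)Ho * Wo, rowsOut = planeOut * N;

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / copg;
      const double* dO = dyp + (R_xlen_t)co * rowsOut + (R_xlen_t)n * planeOut;
      for (int cig = 0; cig < Cpg; ++cig) {
        const int ci = g * Cpg + cig;
        double* dP = dxp + (R_xlen_t)ci * rowsIn + (R_xlen_t)n * planeIn;
        for (int kw = 0; kw < k; ++kw) {
          for (int kh = 0; kh < k; ++kh) {
            const double wgt =
                wp[kh + k * (kw + k * (cig + (R_xlen_t)Cpg * co))];
            if (wgt == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride + kw - pad;
              if (wi < 0 || wi >= W) continue;
              double* dPc = dP + (R_xlen_t)H * wi;
              const double* dOc = dO + (R_xlen_t)Ho * wo;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride + kh - pad;
                if (hi < 0 || hi >= H) continue;
                dPc[hi] += wgt * dOc[ho];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_weight_cpp(const NumericMatrix& x,
                                    const NumericMatrix& dy, int H, int W,
                                    int N, int k, int Cpg, int stride,
                                    int groups) {
  const int Cout = dy.ncol();
  const int pad = k / 2;
  const int Ho = out_size(H, k, stride), Wo = out_size(W, k, stride);
  const int copg = Cout / groups;
  NumericVector dw((R_xlen_t)k * k * Cpg * Cout);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dwp = dw.begin();
  const R_xlen_t planeIn = (R_xlen_t)H * W, rowsIn = planeIn * N;
  const R_xlen_t planeOut = (R_xlen_t)Ho * Wo, rowsOut = planeOut * N;

  for (int co = 0; co < Cout; ++co) {
    const int g = co / copg;
    for (int cig = 0; cig < Cpg; ++cig) {
      const int ci = g * Cpg + cig;
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          double acc = 0.0;
          for (int n = 0; n < N; ++n) {
            const double* P =
                xp + (R_xlen_t)ci * rowsIn + (R_xlen_t)n * planeIn;
            const double* dO =
                dyp + (R_xlen_t)co * rowsOut + (R_xlen_t)n * planeOut;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride + kw - pad;
              if (wi < 0 || wi >= W) continue;
              const double* Pc = P + (R_xlen_t)H * wi;
              const double* dOc = dO + (R_xlen_t)Ho * wo;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride + kh - pad;
                if (hi < 0 || hi >= H) continue;
                acc += Pc[hi] * dOc[ho];
              }
            }
          }
          dwp[kh + k * (kw + k * (cig + (R_xlen_t)Cpg * co))] = acc;
        }
      }
    }
  }
  return dw;
}

// Nearest-neighbour x2 upsampling and its adjoint (sum pooling).
// [[Rcpp::export]]
NumericMatrix upsample2_fwd_cpp(const NumericMatrix& x, int H, int W, int N) {
  const int C = x.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix y((R_xlen_t)Ho * Wo * N, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t planeIn = (R_xlen_t)H * W, rowsIn = planeIn * N;
  const R_xlen_t planeOut = (R_xlen_t)Ho * Wo, rowsOut = planeOut * N;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* P = xp + (R_xlen_t)c * rowsIn + (R_xlen_t)n * planeIn;
      double* O = yp + (R_xlen_t)c * rowsOut + (R_xlen_t)n * planeOut;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = P[h + (R_xlen_t)H * w];
          double* base = O + 2 * h + (R_xlen_t)Ho * 2 * w;
          base[0] = v;
          base[1] = v;
          base[Ho] = v;
          base[Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericMatrix upsample2_bwd_cpp(const NumericMatrix& dy, int H, int W, int N) {
  // H, W are the *input* (small) sizes.
  const int C = dy.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix dx((R_xlen_t)H * W * N, C);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const R_xlen_t planeIn = (R_xlen_t)H * W, rowsIn = planeIn * N;
  const R_xlen_t planeOut = (R_xlen_t)Ho * Wo, rowsOut = planeOut * N;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      double* dP = dxp + (R_xlen_t)c * rowsIn + (R_xlen_t)n * planeIn;
      const double* dO = dyp + (R_xlen_t)c * rowsOut + (R_xlen_t)n * planeOut;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double* base = dO + 2 * h + (R_xlen_t)Ho * 2 * w;
          dP[h + (R_xlen_t)H * w] = base[0] + base[1] + base[Ho] + base[Ho + 1];
        }
    }
  return dx;
}

// column-wise scale: y[, j] = m[, j] * v[j]
// [[Rcpp::export]]
NumericMatrix col_scale_cpp(const NumericMatrix& m, const NumericVector& v) {
  NumericMatrix y(m.nrow(), m.ncol());
  const R_xlen_t nr = m.nrow();
  for (int j = 0; j < m.ncol(); ++j) {
    const double s = v[j];
    const double* src = m.begin() + (R_xlen_t)j * nr;
    double* dst = y.begin() + (R_xlen_t)j * nr;
    for (R_xlen_t i = 0; i < nr; ++i) dst[i] = src[i] * s;
  }
  return y;
}

// column-wise affine: y[, j] = m[, j] * v[j] + b[j]
// [[Rcpp::export]]
NumericMatrix col_scale_add_cpp(const NumericMatrix& m, const NumericVector& v,
                                const NumericVector& b) {
  NumericMatrix y(m.nrow(), m.ncol());
  const R_xlen_t nr = m.nrow();
  for (int j = 0; j < m.ncol(); ++j) {
    const double s = v[j], off = b[j];
    const double* src = m.begin() + (R_xlen_t)j * nr;
    double* dst = y.begin() + (R_xlen_t)j * nr;
    for (R_xlen_t i = 0; i < nr; ++i) dst[i] = src[i] * s + off;
  }
  return y;
}

// TanhExp f(x) = x * tanh(exp(min(x, cutoff))): above the cutoff
// tanh(exp(.)) is 1 in double precision so the clamp is the identity branch.
// [[Rcpp::export]]
NumericVector tanhexp_cpp(const NumericVector& x, double cutoff) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    y[i] = (v > cutoff) ? v : v * std::tanh(std::exp(v));
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// f'(x) = tanh(e^x) + x e^x (1 - tanh(e^x)^2); exactly 1 above the cutoff
// [[Rcpp::export]]
NumericVector tanhexp_grad_cpp(const NumericVector& x, double cutoff) {
  NumericVector g(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    if (v > cutoff) {
      g[i] = 1.0;
    } else {
      const double e = std::exp(v);
      const double t = std::tanh(e);
      g[i] = t + v * e * (1.0 - t * t);
    }
  }
  g.attr("dim") = x.attr("dim");
  return g;
}

// fused batch-norm backward (training mode):
// dx = invstd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat)),
// dxhat = dy * gamma; also returns dgamma = sum(dy*xhat), dbeta = sum(dy)
// [[Rcpp::export]]
List bn_bwd_cpp(const NumericMatrix& dy, const NumericMatrix& xhat,
                const NumericVector& gamma, const NumericVector& invstd) {
  const R_xlen_t nr = dy.nrow();
  const int nc = dy.ncol();
  NumericMatrix dx(nr, nc);
  NumericVector dgamma(nc), dbeta(nc);
  for (int j = 0; j < nc; ++j) {
    const double* dyj = dy.begin() + (R_xlen_t)j * nr;
    const double* xj = xhat.begin() + (R_xlen_t)j * nr;
    double s1 = 0, s2 = 0, sg = 0;
    for (R_xlen_t i = 0; i < nr; ++i) {
      s1 += dyj[i];
      s2 += dyj[i] * xj[i];
      sg += dyj[i] * xj[i];
    }
    dbeta[j] = s1;
    dgamma[j] = sg;
    const double g = gamma[j];
    const double m1 = g * s1 / nr, m2 = g * s2 / nr;
    const double is = invstd[j];
    double* dxj = dx.begin() + (R_xlen_t)j * nr;
    for (R_xlen_t i = 0; i < nr; ++i) {
      dxj[i] = is * (g * dyj[i] - m1 - xj[i] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
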