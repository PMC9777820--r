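// Hot kernels of the network engine: 'same' stride-1 convolution
// (forward/backward via per-sample im2col + BLAS gemm), 2x2 max pooling and
// leaky ReLU.  Layouts match the R reference implementations exactly:
// activations are column-major (H, W, C, N) arrays; convolution weights are
// (kh*kw*cin, cout) matrices with patch elements ordered dh-fastest, then
// dw, then channel.  Max-pool ties go to the first element in (dh, dw)
// scan order, as in the reference.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void gather_patches(const double* xn, arma::mat& P,
                                  int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ow = 0; ow < W; ++ow) {
    for (int oh = 0; oh < H; ++oh) {
      double* Pcol = P.colptr(oh + H * ow);
      for (int c = 0; c < C; ++c) {
        for (int dw = 0; dw < kw; ++dw) {
          const int w = ow + dw - pw;
          double* dst = Pcol + kh * (dw + kw * c);
          if (w < 0 || w >= W) {
            for (int dh = 0; dh < kh; ++dh) dst[dh] = 0.0;
            continue;
          }
          const double* src = xn + (size_t)H * (w + (size_t)W * c);
          for (int dh = 0; dh < kh; ++dh) {
            const int h = oh + dh - ph;
            dst[dh] = (h < 0 || h >= H) ? 0.0 : src[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(const NumericVector& x, const IntegerVector& dims,
                           const arma::mat& Wm, const arma::vec& b,
                           int kh, int kw) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int npos = H * W, patch = kh * kw * C, cout = Wm.n_cols;
  NumericVector out((size_t)npos * cout * N);
  arma::mat P(patch, npos);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    gather_patches(xp + (size_t)n * npos * C, P, H, W, C, kh, kw);
    arma::mat O = Wm.t() * P;                   // (cout, npos)
    O.each_col() += b;
    for (int co = 0; co < cout; ++co) {
      double* dst = op + (size_t)npos * (co + (size_t)cout * n);
      const double* src = O.memptr();
      for (int pos = 0; pos < npos; ++pos) dst[pos] = src[co + cout * pos];
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const NumericVector& x, const IntegerVector& dims,
                  const NumericVector& dout, const arma::mat& Wm,
                  int kh, int kw) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int npos = H * W, patch = kh * kw * C, cout = Wm.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector dx((size_t)npos * C * N);
  arma::mat dW(patch, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  arma::mat P(patch, npos);
  const double* xp = x.begin();
  const double* dp = dout.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    gather_patches(xp + (size_t)n * npos * C, P, H, W, C, kh, kw);
    // dout slab for sample n is a (npos x cout) column-major matrix
    const arma::mat Dn(const_cast<double*>(dp) + (size_t)n * npos * cout,
                       npos, cout, false, true);
    dW += P * Dn;
    db += arma::sum(Dn, 0).t();
    arma::mat dP = Wm * Dn.t();                 // (patch, npos)
    double* dxn = dxp + (size_t)n * npos * C;
    for (int ow = 0; ow < W; ++ow) {
      for (int oh = 0; oh < H; ++oh) {
        const double* Pg = dP.colptr(oh + H * ow);
        for (int c = 0; c < C; ++c) {
          for (int dw_ = 0; dw_ < kw; ++dw_) {
            const int w = ow + dw_ - pw;
            if (w < 0 || w >= W) continue;
            const double* src = Pg + kh * (dw_ + kw * c);
            double* dst = dxn + (size_t)H * (w + (size_t)W * c);
            for (int dh = 0; dh < kh; ++dh) {
              const int h = oh + dh - ph;
              if (h >= 0 && h < H) dst[h] += src[dh];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericVector& x, const IntegerVector& dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int OH = H / 2, OW = W / 2;
  const size_t plane = (size_t)H * W, oplane = (size_t)OH * OW;
  const int CN = C * N;
  NumericVector out(oplane * CN);
  IntegerVector which(oplane * CN);   // 0..3 = dh + 2*dw of the (first) max
  const double* xp = x.begin();
  double* op = out.begin();
  int* wp = which.begin();
  for (int cn = 0; cn < CN; ++cn) {
    const double* xc = xp + plane * cn;
    double* oc = op + oplane * cn;
    int* wc = wp + oplane * cn;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double best = xc[2 * oh + (size_t)H * (2 * ow)];
        int arg = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const double v = xc[2 * oh + dh + (size_t)H * (2 * ow + dw)];
            if (v > best) { best = v; arg = dh + 2 * dw; }
          }
        oc[oh + (size_t)OH * ow] = best;
        wc[oh + (size_t)OH * ow] = arg;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const NumericVector& dout,
                              const IntegerVector& which,
                              const IntegerVector& dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int OH = H / 2, OW = W / 2;
  const size_t plane = (size_t)H * W, oplane = (size_t)OH * OW;
  const int CN = C * N;
  NumericVector dx(plane * CN);
  const double* dp = dout.begin();
  const int* wp = which.begin();
  double* xp = dx.begin();
  for (int cn = 0; cn < CN; ++cn) {
    const double* dc = dp + oplane * cn;
    const int* wc = wp + oplane * cn;
    double* xc = xp + plane * cn;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const int arg = wc[oh + (size_t)OH * ow];
        const int dh = arg % 2, dw = arg / 2;
        xc[2 * oh + dh + (size_t)H * (2 * ow + dw)] +=
          dc[oh + (size_t)OH * ow];
      }
  }
  dx.attr("dim") = dims;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(const NumericVector& x, double alpha) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    op[i] = xp[i] > 0 ? xp[i] : alpha * xp[i];
  if (!Rf_isNull(x.attr("dim"))) out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(const NumericVector& dout,
                            const NumericVector& x, double alpha) {
  NumericVector dx(dout.size());
  const double* dp = dout.begin();
  const double* xp = x.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    op[i] = xp[i] > 0 ? dp[i] : alpha * dp[i];
  if (!Rf_isNull(dout.attr("dim"))) dx.attr("dim") = dout.attr("dim");
  return dx;
}

// ---- spatial batch norm (per-channel over H, W, N) ------------------------

// [[Rcpp::export]]
List cpp_bn2d_stats(const NumericVector& x, const IntegerVector& dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)H * W;
  NumericVector mu(C), va(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = (double)plane * N;
    mu[c] = s / m;
    va[c] = s2 / m - mu[c] * mu[c];
    if (va[c] < 0) va[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// [[Rcpp::export]]
NumericVector cpp_bn2d_norm(const NumericVector& x, const IntegerVector& dims,
                            const NumericVector& gamma,
                            const NumericVector& beta,
                            const NumericVector& mean,
                            const NumericVector& invstd) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)H * W;
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c] * invstd[c];
      const double b0 = beta[c] - mean[c] * g;
      const double* p = xp + plane * (c + (size_t)C * n);
      double* o = op + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) o[i] = g * p[i] + b0;
    }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List cpp_bn2d_bwd(const NumericVector& x, const IntegerVector& dims,
                  const NumericVector& dout, const NumericVector& gamma,
                  const NumericVector& mean, const NumericVector& invstd) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dp = dout.begin();
  double* op = dx.begin();
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + plane * (c + (size_t)C * n);
      const double* d = dp + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        sb += d[i];
        sg += d[i] * (p[i] - mean[c]) * invstd[c];
      }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double t1 = gamma[c] * sb / m;          // mean of dxhat
    const double t2 = gamma[c] * sg / m;          // mean of dxhat * xhat
    for (int n = 0; n < N; ++n) {
      const double* p = xp + plane * (c + (size_t)C * n);
      const double* d = dp + plane * (c + (size_t)C * n);
      double* o = op + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        const double xhat = (p[i] - mean[c]) * invstd[c];
        o[i] = invstd[c] * (gamma[c] * d[i] - t1 - xhat * t2);
      }
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- binding-matrix batch encoder -----------------------------------------
// Watson-Crick indicator grids for standardized (20 nt, 50 nt) pairs; any
// position involving a non-ACGU symbol scores 0.  Mirrors encode_pair().

// [[Rcpp::export]]
NumericVector cpp_encode_batch(const CharacterVector& mirna,
                               const CharacterVector& target,
                               int H, int W) {
  const int N = mirna.size();
  NumericVector out((size_t)H * W * N);
  double* op = out.begin();
  std::vector<char> comp(256, 0);
  comp['A'] = 'U'; comp['C'] = 'G'; comp['G'] = 'C'; comp['U'] = 'A';
  for (int n = 0; n < N; ++n) {
    const char* m = CHAR(STRING_ELT(mirna, n));
    const char* t = CHAR(STRING_ELT(target, n));
    double* o = op + (size_t)H * W * n;
    for (int i = 0; i < H; ++i) {
      const char c = comp[(unsigned char)m[i]];
      if (!c) continue;
      for (int j = 0; j < W; ++j)
        if (t[j] == c) o[i + (size_t)H * j] = 1.0;
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N);
  return out;
}
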