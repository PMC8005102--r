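// Minimal CPU kernels for the segmentation training stack.
// Tensors are R double arrays with dim (H, W, C, N); convolution weights are
// (9*Cin) x Cout matrices whose row order is channel-major over the 3x3
// neighbourhood: row = cin*9 + (kx+1)*3 + (ky+1), i.e. the value gathered at
// x[h+ky, w+kx, cin]. The whole mini-batch shares one single-precision GEMM
// (the usual deep-learning arithmetic); inputs/outputs stay double in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// gather one sample's 3x3 neighbourhoods into rows [n*H*W, (n+1)*H*W) of col
static void im2col3(const double* x, int H, int W, int C, int n,
                    arma::fmat& col) {
  const size_t off = (size_t)n * H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        int r = c * 9 + (kx + 1) * 3 + (ky + 1);
        float* dst = col.colptr(r) + off;
        for (int w = 0; w < W; ++w) {
          int ws = w + kx;
          float* d = dst + (size_t)w * H;
          if (ws < 0 || ws >= W) {
            std::fill(d, d + H, 0.0f);
          } else {
            const double* s = xc + (size_t)ws * H;
            int h0 = std::max(0, -ky), h1 = std::min(H, H - ky);
            for (int h = 0; h < h0; ++h) d[h] = 0.0f;
            for (int h = h0; h < h1; ++h) d[h] = (float)s[h + ky];
            for (int h = h1; h < H; ++h) d[h] = 0.0f;
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col3 for one sample
static void col2im3(const arma::fmat& dcol, int H, int W, int C, int n,
                    double* dx) {
  const size_t off = (size_t)n * H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        int r = c * 9 + (kx + 1) * 3 + (ky + 1);
        const float* src = dcol.colptr(r) + off;
        for (int w = 0; w < W; ++w) {
          int ws = w + kx;
          if (ws < 0 || ws >= W) continue;
          double* d = xc + (size_t)ws * H;
          const float* s = src + (size_t)w * H;
          int h0 = std::max(0, -ky), h1 = std::min(H, H - ky);
          for (int h = h0; h < h1; ++h) d[h + ky] += (double)s[h];
        }
      }
    }
  }
}

static arma::fmat toF(const NumericMatrix& m) {
  arma::fmat f(m.nrow(), m.ncol());
  const double* p = &m[0];
  float* q = f.memptr();
  for (size_t i = 0; i < (size_t)m.nrow() * m.ncol(); ++i) q[i] = (float)p[i];
  return f;
}

// [[Rcpp::export]]
NumericVector conv3x3Forward(NumericVector x, NumericMatrix wmat,
                             NumericVector bias) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Cout = wmat.ncol();
  if (wmat.nrow() != 9 * C) stop("weight rows must be 9*Cin");
  arma::fmat Wf = toF(wmat);
  arma::fmat col((size_t)H * W * N, 9 * C);
  for (int n = 0; n < N; ++n)
    im2col3(REAL(x) + (size_t)n * H * W * C, H, W, C, n, col);
  arma::fmat Y = col * Wf;                       // (H*W*N) x Cout
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* yp = REAL(y);
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < Cout; ++c) {
    const float* ys = Y.colptr(c);
    double b = bias[c];
    for (int n = 0; n < N; ++n) {
      double* d = yp + ((size_t)n * Cout + c) * HW;
      const float* s = ys + (size_t)n * HW;
      for (size_t i = 0; i < HW; ++i) d[i] = (double)s[i] + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3x3Backward(NumericVector x, NumericMatrix wmat, NumericVector dy) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Cout = wmat.ncol();
  arma::fmat Wf = toF(wmat);
  const size_t HW = (size_t)H * W;

  arma::fmat col(HW * N, 9 * C);
  for (int n = 0; n < N; ++n)
    im2col3(REAL(x) + (size_t)n * HW * C, H, W, C, n, col);

  arma::fmat dYm(HW * N, Cout);
  const double* dyp = REAL(dy);
  for (int c = 0; c < Cout; ++c) {
    float* d = dYm.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* s = dyp + ((size_t)n * Cout + c) * HW;
      float* dn = d + (size_t)n * HW;
      for (size_t i = 0; i < HW; ++i) dn[i] = (float)s[i];
    }
  }

  arma::fmat dW = col.t() * dYm;                 // (9C) x Cout
  arma::frowvec db = arma::sum(dYm, 0);
  arma::fmat dcol = dYm * Wf.t();                // (H*W*N) x 9C

  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    col2im3(dcol, H, W, C, n, REAL(dx) + (size_t)n * HW * C);

  NumericMatrix dwR(9 * C, Cout);
  NumericVector dbR(Cout);
  for (int j = 0; j < Cout; ++j) {
    dbR[j] = (double)db(j);
    for (int i = 0; i < 9 * C; ++i) dwR(i, j) = (double)dW(i, j);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwR, _["db"] = dbR);
}

// [[Rcpp::export]]
List maxpool2Forward(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  if (H % 2 || W % 2) stop("spatial dims must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // offset into the input plane
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t plane = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = plane + (size_t)(2 * w) * H + 2 * h;
          size_t cand[4] = {i00, i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          int best = 0;
          double bv = xp[cand[0]];
          for (int k = 1; k < 4; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = k; }
          yp[o] = bv;
          ip[o] = (int)(cand[best] - plane);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2Backward(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  double* dxp = REAL(dx);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t plane = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Ho * Wo; ++j, ++o) dxp[plane + ip[o]] += dyp[o];
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector upsample2Forward(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (size_t pc = 0; pc < (size_t)C * N; ++pc) {
    const double* xs = xp + pc * H * W;
    double* ys = yp + pc * Ho * Wo;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xs[(size_t)w * H + h];
        size_t base = (size_t)(2 * w) * Ho + 2 * h;
        ys[base] = v;
        ys[base + 1] = v;
        ys[base + Ho] = v;
        ys[base + Ho + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2Backward(NumericVector dy) {
  IntegerVector dims = dy.attr("dim");
  int Ho = dims[0], Wo = dims[1], C = dims[2], N = dims[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (size_t pc = 0; pc < (size_t)C * N; ++pc) {
    const double* ds = dyp + pc * Ho * Wo;
    double* xs = dxp + pc * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t base = (size_t)(2 * w) * Ho + 2 * h;
        xs[(size_t)w * H + h] =
            ds[base] + ds[base + 1] + ds[base + Ho] + ds[base + Ho + 1];
      }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector concatChannels(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  int H = da[0], W = da[1], Ca = da[2], N = da[3], Cb = db[2];
  if (db[0] != H || db[1] != W || db[3] != N)
    stop("incompatible dimensions for channel concatenation");
  NumericVector y((size_t)H * W * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  const size_t pa = (size_t)H * W * Ca, pb = (size_t)H * W * Cb;
  double* yp = REAL(y);
  const double* ap = REAL(a);
  const double* bp = REAL(b);
  for (int n = 0; n < N; ++n) {
    std::copy(ap + n * pa, ap + (n + 1) * pa, yp + n * (pa + pb));
    std::copy(bp + n * pb, bp + (n + 1) * pb, yp + n * (pa + pb) + pa);
  }
  return y;
}

// [[Rcpp::export]]
List splitChannels(NumericVector x, int c1) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int c2 = C - c1;
  NumericVector a((size_t)H * W * c1 * N), b((size_t)H * W * c2 * N);
  a.attr("dim") = IntegerVector::create(H, W, c1, N);
  b.attr("dim") = IntegerVector::create(H, W, c2, N);
  const size_t pa = (size_t)H * W * c1, pb = (size_t)H * W * c2;
  const double* xp = REAL(x);
  double* ap = REAL(a);
  double* bp = REAL(b);
  for (int n = 0; n < N; ++n) {
    std::copy(xp + n * (pa + pb), xp + n * (pa + pb) + pa, ap + n * pa);
    std::copy(xp + n * (pa + pb) + pa, xp + (n + 1) * (pa + pb), bp + n * pb);
  }
  return List::create(_["a"] = a, _["b"] = b);
}

static const double kSeluLambda = 1.0507009873554805;
static const double kSeluAlpha = 1.6732632423543772;

// [[Rcpp::export]]
NumericVector seluFwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = xp[i];
    yp[i] = kSeluLambda * (v > 0 ? v : kSeluAlpha * std::expm1(v));
  }
  return y;
}

// [[Rcpp::export]]
NumericVector seluBwd(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* dxp = REAL(dx);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = xp[i];
    dxp[i] = dp[i] * kSeluLambda * (v > 0 ? 1.0 : kSeluAlpha * std::exp(v));
  }
  return dx;
}

// group normalisation: channels are split into G contiguous groups; each
// (group, sample) block of size H*W*(C/G) is normalised to zero mean / unit
// variance, then scaled and shifted per channel.

// [[Rcpp::export]]
List gnFwd(NumericVector x, NumericVector gamma, NumericVector beta,
           int G, double eps) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t m = (size_t)H * W * (C / G);
  int nblk = G * N;
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = d;
  y.attr("dim") = d;
  NumericVector rstd(nblk);
  const double* xp = REAL(x);
  double* xh = REAL(xhat);
  double* yp = REAL(y);
  size_t HW = (size_t)H * W;
  for (int b = 0; b < nblk; ++b) {
    const double* xs = xp + (size_t)b * m;
    double* hs = xh + (size_t)b * m;
    double* ys = yp + (size_t)b * m;
    double mu = 0;
    for (size_t i = 0; i < m; ++i) mu += xs[i];
    mu /= m;
    double v = 0;
    for (size_t i = 0; i < m; ++i) { double c = xs[i] - mu; v += c * c; }
    v /= m;
    double rs = 1.0 / std::sqrt(v + eps);
    rstd[b] = rs;
    int c0 = (b % G) * (C / G);  // first channel of this block
    for (int cc = 0; cc < C / G; ++cc) {
      double ga = gamma[c0 + cc], be = beta[c0 + cc];
      const double* xsc = xs + (size_t)cc * HW;
      double* hsc = hs + (size_t)cc * HW;
      double* ysc = ys + (size_t)cc * HW;
      for (size_t i = 0; i < HW; ++i) {
        double h = (xsc[i] - mu) * rs;
        hsc[i] = h;
        ysc[i] = ga * h + be;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["rstd"] = rstd);
}

// [[Rcpp::export]]
List gnBwd(NumericVector xhat, NumericVector rstd, NumericVector gamma,
           NumericVector dy, int G) {
  IntegerVector d = xhat.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W;
  size_t m = HW * (C / G);
  NumericVector dx(xhat.size());
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  const double* xh = REAL(xhat);
  const double* dp = REAL(dy);
  double* dxp = REAL(dx);
  for (int b = 0; b < G * N; ++b) {
    const double* hs = xh + (size_t)b * m;
    const double* ds = dp + (size_t)b * m;
    double* os = dxp + (size_t)b * m;
    int c0 = (b % G) * (C / G);
    // per-channel contributions to dgamma/dbeta, block means of dxhat
    double s1 = 0, s2 = 0;
    for (int cc = 0; cc < C / G; ++cc) {
      double ga = gamma[c0 + cc];
      const double* hc = hs + (size_t)cc * HW;
      const double* dc = ds + (size_t)cc * HW;
      double dg = 0, db = 0;
      for (size_t i = 0; i < HW; ++i) {
        dg += dc[i] * hc[i];
        db += dc[i];
        double dxh = dc[i] * ga;
        s1 += dxh;
        s2 += dxh * hc[i];
      }
      dgamma[c0 + cc] += dg;
      dbeta[c0 + cc] += db;
    }
    s1 /= m; s2 /= m;
    double rs = rstd[b];
    for (int cc = 0; cc < C / G; ++cc) {
      double ga = gamma[c0 + cc];
      const double* hc = hs + (size_t)cc * HW;
      const double* dc = ds + (size_t)cc * HW;
      double* oc = os + (size_t)cc * HW;
      for (size_t i = 0; i < HW; ++i)
        oc[i] = (dc[i] * ga - s1 - hc[i] * s2) * rs;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// forward that also hands back the im2col matrix, so backward can skip
// regathering; the pointer lives only for the current iteration
// [[Rcpp::export]]
List conv3x3ForwardC(NumericVector x, NumericMatrix wmat,
                     NumericVector bias) {
  IntegerVector dims = x.attr("dim");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Cout = wmat.ncol();
  if (wmat.nrow() != 9 * C) stop("weight rows must be 9*Cin");
  arma::fmat Wf = toF(wmat);
  XPtr<arma::fmat> col(new arma::fmat((size_t)H * W * N, 9 * C), true);
  for (int n = 0; n < N; ++n)
    im2col3(REAL(x) + (size_t)n * H * W * C, H, W, C, n, *col);
  arma::fmat Y = (*col) * Wf;
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* yp = REAL(y);
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < Cout; ++c) {
    const float* ys = Y.colptr(c);
    double b = bias[c];
    for (int n = 0; n < N; ++n) {
      double* d = yp + ((size_t)n * Cout + c) * HW;
      const float* s = ys + (size_t)n * HW;
      for (size_t i = 0; i < HW; ++i) d[i] = (double)s[i] + b;
    }
  }
  return List::create(_["y"] = y, _["col"] = col);
}

// [[Rcpp::export]]
List conv3x3BackwardC(SEXP colPtr, NumericMatrix wmat, NumericVector dy,
                      IntegerVector xdim) {
  XPtr<arma::fmat> col(colPtr);
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Cout = wmat.ncol();
  arma::fmat Wf = toF(wmat);
  const size_t HW = (size_t)H * W;
  arma::fmat dYm(HW * N, Cout);
  const double* dyp = REAL(dy);
  for (int c = 0; c < Cout; ++c) {
    float* d = dYm.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* s = dyp + ((size_t)n * Cout + c) * HW;
      float* dn = d + (size_t)n * HW;
      for (size_t i = 0; i < HW; ++i) dn[i] = (float)s[i];
    }
  }
  arma::fmat dW = col->t() * dYm;
  arma::frowvec db = arma::sum(dYm, 0);
  arma::fmat dcol = dYm * Wf.t();
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    col2im3(dcol, H, W, C, n, REAL(dx) + (size_t)n * HW * C);
  NumericMatrix dwR(9 * C, Cout);
  NumericVector dbR(Cout);
  for (int j = 0; j < Cout; ++j) {
    dbR[j] = (double)db(j);
    for (int i = 0; i < 9 * C; ++i) dwR(i, j) = (double)dW(i, j);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwR, _["db"] = dbR);
}
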