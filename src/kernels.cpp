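// Numerical kernels for the Siamese 3D U-Net stack.
//
// Array convention (matches R column-major): a feature map of shape
// (D, H, W, C) is stored with voxel index n = d + D*h + D*H*w varying
// fastest and the channel slowest, i.e. as an N x C matrix with
// N = D*H*W.  Convolutions use kernel 3x3x3, zero padding 1, and are
// evaluated as im2row + GEMM in single precision: training a network of
// this size is GEMM-bound and float32 doubles the throughput while the
// optimiser (Adam) is insensitive to the extra rounding.

#include <RcppArmadillo.h>
#include <queue>
#include <cstring>
using namespace Rcpp;

typedef arma::uword uw;

static inline arma::fvec as_fvec(const NumericVector& x) {
  arma::fvec out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)x[i];
  return out;
}

static NumericVector as_numeric(const arma::fmat& m) {
  NumericVector out(m.n_elem);
  const float* p = m.memptr();
  for (uw i = 0; i < m.n_elem; ++i) out[i] = (double)p[i];
  return out;
}

// Fill rows of the im2row matrix for output planes wo in [wo0, wo1).
// col has (wo1-wo0)*Ho*Do rows and 27*Cin columns.  Inner loops are
// boundary-split so the hot path is a contiguous (or stride-2 gather)
// copy without conditionals.  Processing a few wo-planes at a time
// keeps the patch matrix cache-resident, which matters more than
// anything else on memory-bandwidth-poor machines.
static void im2row_range(const arma::fvec& x, int D, int H, int W,
                         int Cin, int s, int Do, int Ho, int wo0,
                         int wo1, arma::fmat& col) {
  const long N = (long)D * H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const float* xc = x.memptr() + (long)ci * N;
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh)
        for (int kd = 0; kd < 3; ++kd) {
          const int k = kd + 3 * kh + 9 * kw + 27 * ci;
          float* dst = col.colptr(k);
          int lo = 0;
          while (lo < Do && lo * s + kd - 1 < 0) ++lo;
          int hi = Do - 1;
          while (hi >= 0 && hi * s + kd - 1 > D - 1) --hi;
          for (int wo = wo0; wo < wo1; ++wo) {
            const int wi = wo * s + kw - 1;
            const bool wok = (wi >= 0 && wi < W);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi_ = ho * s + kh - 1;
              float* drow = dst +
                ((long)ho + (long)(wo - wo0) * Ho) * Do;
              if (!wok || hi_ < 0 || hi_ >= H) {
                std::memset(drow, 0, sizeof(float) * Do);
                continue;
              }
              const float* src = xc + (long)hi_ * D + (long)wi * D * H;
              if (lo > 0) std::memset(drow, 0, sizeof(float) * lo);
              if (hi < Do - 1)
                std::memset(drow + hi + 1, 0,
                            sizeof(float) * (Do - 1 - hi));
              if (s == 1) {
                std::memcpy(drow + lo, src + lo + kd - 1,
                            sizeof(float) * (hi - lo + 1));
              } else {
                for (int do_ = lo; do_ <= hi; ++do_)
                  drow[do_] = src[do_ * s + kd - 1];
              }
            }
          }
        }
  }
}

static void im2row(const arma::fvec& x, int D, int H, int W, int Cin,
                   int s, int Do, int Ho, int Wo, arma::fmat& col) {
  im2row_range(x, D, H, W, Cin, s, Do, Ho, 0, Wo, col);
}

// tile size (output wo-planes per GEMM) keeping ~2 MB of patches
static int tile_planes(int Do, int Ho, int K) {
  long per = (long)Do * Ho * K * 4;
  int t = (int)std::max(1L, (2L << 20) / std::max(per, 1L));
  return t;
}

static inline int out_sz(int n, int s) { return (n - 1) / s + 1; }

// [[Rcpp::export]]
List cpp_conv3d_fwd(NumericVector x, IntegerVector dims, int cin,
                    NumericVector w, NumericVector b, int stride) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int cout = b.size();
  const int Do = out_sz(D, stride), Ho = out_sz(H, stride),
            Wo = out_sz(W, stride);
  const long Nout = (long)Do * Ho * Wo;
  const int K = 27 * cin;
  arma::fvec xf = as_fvec(x);
  arma::fvec wf = as_fvec(w);
  arma::fmat wm(wf.memptr(), K, cout, false, true);
  arma::fmat out(Nout, cout);
  const int tb = tile_planes(Do, Ho, K);
  arma::fmat col((long)tb * Do * Ho, K);
  for (int wo0 = 0; wo0 < Wo; wo0 += tb) {
    const int wo1 = std::min(Wo, wo0 + tb);
    const long r0 = (long)wo0 * Do * Ho;
    const long nr = (long)(wo1 - wo0) * Do * Ho;
    im2row_range(xf, D, H, W, cin, stride, Do, Ho, wo0, wo1, col);
    out.rows(r0, r0 + nr - 1) = col.head_rows(nr) * wm;
  }
  for (int co = 0; co < cout; ++co) out.col(co) += (float)b[co];
  return List::create(_["out"] = as_numeric(out),
                      _["dims"] = IntegerVector::create(Do, Ho, Wo));
}

// Scatter-add dcol (N_out x 27*Cin) back onto the input grid.
static void row2im(const arma::fmat& dcol, int D, int H, int W, int Cin,
                   int s, int Do, int Ho, int Wo, arma::fvec& dx) {
  const int N = D * H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    float* xc = dx.memptr() + (long)ci * N;
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh)
        for (int kd = 0; kd < 3; ++kd) {
          const int k = kd + 3 * kh + 9 * kw + 27 * ci;
          const float* src = dcol.colptr(k);
          int lo = 0;
          while (lo < Do && lo * s + kd - 1 < 0) ++lo;
          int hi = Do - 1;
          while (hi >= 0 && hi * s + kd - 1 > D - 1) --hi;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * s + kw - 1;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi_ = ho * s + kh - 1;
              if (hi_ < 0 || hi_ >= H) continue;
              const float* srow = src + ((long)ho + (long)wo * Ho) * Do;
              float* drow = xc + (long)hi_ * D + (long)wi * D * H +
                            (kd - 1);
              if (s == 1) {
                for (int do_ = lo; do_ <= hi; ++do_)
                  drow[do_] += srow[do_];
              } else {
                for (int do_ = lo; do_ <= hi; ++do_)
                  drow[do_ * s] += srow[do_];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, int cin,
                    NumericVector w, int cout, int stride,
                    NumericVector dout) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Do = out_sz(D, stride), Ho = out_sz(H, stride),
            Wo = out_sz(W, stride);
  const long Nout = (long)Do * Ho * Wo;
  const int K = 27 * cin;
  arma::fvec xf = as_fvec(x);
  arma::fvec df = as_fvec(dout);
  arma::fmat dm(df.memptr(), Nout, cout, false, true);
  arma::frowvec db = arma::sum(dm, 0);
  arma::fvec wf = as_fvec(w);
  arma::fmat wm(wf.memptr(), K, cout, false, true);
  arma::fmat dW(K, cout);
  arma::fvec dx;
  if (stride == 1) {
    // One im2row of dout serves both gradients.
    // dx(N x cin) = im2row(dout) (N x 27*cout) * Wflip (27*cout x cin),
    // the correlation of dout with the flipped kernel; and
    // dW[k,ci,co] = sum_n x[n,ci] * col2[n, flip(k) + 27*co].
    arma::fmat wflip(27 * cout, cin);
    for (int co = 0; co < cout; ++co)
      for (int kw = 0; kw < 3; ++kw)
        for (int kh = 0; kh < 3; ++kh)
          for (int kd = 0; kd < 3; ++kd) {
            const int kf = (2 - kd) + 3 * (2 - kh) + 9 * (2 - kw);
            for (int ci = 0; ci < cin; ++ci)
              wflip(kd + 3 * kh + 9 * kw + 27 * co, ci) =
                wm(kf + 27 * ci, co);
          }
    arma::fmat xm(xf.memptr(), Nout, cin, false, true);
    arma::fmat dxm(Nout, cin);
    arma::fmat G(cin, 27 * cout, arma::fill::zeros);
    const int tb = tile_planes(D, H, 27 * cout);
    arma::fmat col2((long)tb * D * H, 27 * cout);
    for (int wo0 = 0; wo0 < W; wo0 += tb) {
      const int wo1 = std::min(W, wo0 + tb);
      const long r0 = (long)wo0 * D * H;
      const long nr = (long)(wo1 - wo0) * D * H;
      im2row_range(df, D, H, W, cout, 1, D, H, wo0, wo1, col2);
      dxm.rows(r0, r0 + nr - 1) = col2.head_rows(nr) * wflip;
      G += xm.rows(r0, r0 + nr - 1).t() * col2.head_rows(nr);
    }
    dx = arma::vectorise(dxm);
    for (int co = 0; co < cout; ++co)
      for (int kw = 0; kw < 3; ++kw)
        for (int kh = 0; kh < 3; ++kh)
          for (int kd = 0; kd < 3; ++kd) {
            const int kf = (2 - kd) + 3 * (2 - kh) + 9 * (2 - kw);
            for (int ci = 0; ci < cin; ++ci)
              dW(kd + 3 * kh + 9 * kw + 27 * ci, co) =
                G(ci, kf + 27 * co);
          }
  } else {
    arma::fmat col(Nout, K);
    im2row(xf, D, H, W, cin, stride, Do, Ho, Wo, col);
    dW = col.t() * dm;                                // K x cout
    arma::fmat dcol = dm * wm.t();                    // Nout x K
    dx.zeros((long)D * H * W * cin);
    row2im(dcol, D, H, W, cin, stride, Do, Ho, Wo, dx);
  }
  arma::fmat dxm2(dx.memptr(), dx.n_elem, 1, false, true);
  arma::fmat dbm(db.memptr(), cout, 1, false, true);
  return List::create(_["dx"] = as_numeric(dxm2),
                      _["dw"] = as_numeric(dW),
                      _["db"] = as_numeric(dbm));
}

// Depth-wise 3x3x3 convolution, stride 1, pad 1, no bias: one filter per
// input channel.  Direct loops; tap maps are small enough that GEMM gains
// nothing here.
// [[Rcpp::export]]
NumericVector cpp_dwconv3d_fwd(NumericVector x, IntegerVector dims, int c,
                               NumericVector w) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const long N = (long)D * H * W;
  NumericVector out((R_xlen_t)(N * c));
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = &x[0] + N * ci;
    const double* wc = &w[0] + 27 * ci;
    double* oc = &out[0] + N * ci;
    for (int wo = 0; wo < W; ++wo)
      for (int ho = 0; ho < H; ++ho)
        for (int do_ = 0; do_ < D; ++do_) {
          double acc = 0.0;
          for (int kw = 0; kw < 3; ++kw) {
            const int wi = wo + kw - 1;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < 3; ++kh) {
              const int hi = ho + kh - 1;
              if (hi < 0 || hi >= H) continue;
              for (int kd = 0; kd < 3; ++kd) {
                const int di = do_ + kd - 1;
                if (di < 0 || di >= D) continue;
                acc += wc[kd + 3 * kh + 9 * kw] *
                       xc[di + (long)hi * D + (long)wi * D * H];
              }
            }
          }
          oc[do_ + (long)ho * D + (long)wo * D * H] = acc;
        }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv3d_bwd(NumericVector x, IntegerVector dims, int c,
                      NumericVector w, NumericVector dout) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const long N = (long)D * H * W;
  NumericVector dx((R_xlen_t)(N * c));
  NumericVector dw((R_xlen_t)(27 * c));
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = &x[0] + N * ci;
    const double* gc = &dout[0] + N * ci;
    const double* wc = &w[0] + 27 * ci;
    double* dxc = &dx[0] + N * ci;
    double* dwc = &dw[0] + 27 * ci;
    for (int wo = 0; wo < W; ++wo)
      for (int ho = 0; ho < H; ++ho)
        for (int do_ = 0; do_ < D; ++do_) {
          const double g = gc[do_ + (long)ho * D + (long)wo * D * H];
          if (g == 0.0) continue;
          for (int kw = 0; kw < 3; ++kw) {
            const int wi = wo + kw - 1;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < 3; ++kh) {
              const int hi = ho + kh - 1;
              if (hi < 0 || hi >= H) continue;
              for (int kd = 0; kd < 3; ++kd) {
                const int di = do_ + kd - 1;
                if (di < 0 || di >= D) continue;
                const long ii = di + (long)hi * D + (long)wi * D * H;
                const int ki = kd + 3 * kh + 9 * kw;
                dxc[ii] += g * wc[ki];
                dwc[ki] += g * xc[ii];
              }
            }
          }
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Fused instance normalisation + leaky ReLU over an N x C feature map:
// y = lrelu(gamma * (x - mu_c)/sqrt(var_c + eps) + beta, slope).
// [[Rcpp::export]]
List cpp_inl_fwd(NumericVector x, double n_, int C, NumericVector gamma,
                 NumericVector beta, double slope, double eps) {
  const long n = (long)n_;
  NumericVector y((R_xlen_t)(n * C)), xhat((R_xlen_t)(n * C));
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[0] + n * c;
    double s = 0, ss = 0;
    for (long i = 0; i < n; ++i) { s += xc[i]; ss += xc[i] * xc[i]; }
    const double mu = s / n;
    double var = ss / n - mu * mu;
    if (var < 0) var = 0;
    const double is = 1.0 / std::sqrt(var + eps);
    istd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* yc = &y[0] + n * c;
    double* hc = &xhat[0] + n * c;
    for (long i = 0; i < n; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      const double z = g * h + b;
      yc[i] = z > 0 ? z : slope * z;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_inl_bwd(NumericVector dout, NumericVector xhat,
                 NumericVector istd, NumericVector gamma,
                 NumericVector beta, double slope, double n_) {
  const long n = (long)n_;
  const int C = istd.size();
  NumericVector dx((R_xlen_t)(n * C)), dgamma(C), dbeta(C);
  std::vector<double> dz(n);
  for (int c = 0; c < C; ++c) {
    const double* dc = &dout[0] + n * c;
    const double* hc = &xhat[0] + n * c;
    const double g = gamma[c], b = beta[c];
    double s1 = 0, s2 = 0;
    for (long i = 0; i < n; ++i) {
      const double z = g * hc[i] + b;
      const double d = (z > 0) ? dc[i] : slope * dc[i];
      dz[i] = d;
      s1 += d;
      s2 += d * hc[i];
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double m1 = s1 / n, m2 = s2 / n, sc = g * istd[c];
    double* xc = &dx[0] + n * c;
    for (long i = 0; i < n; ++i)
      xc[i] = (dz[i] - m1 - hc[i] * m2) * sc;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Fused per-level segmentation loss: soft Dice + weighted
// cross-entropy on logits (N x C) with integer targets in 0..C-1.
// Returns the two loss values and the gradient w.r.t. the logits.
// [[Rcpp::export]]
List cpp_seg_loss(NumericVector logits, IntegerVector target, int C,
                  NumericVector cw, double eps) {
  const long n = target.size();
  NumericVector p((R_xlen_t)(n * C)), dlog((R_xlen_t)(n * C));
  std::vector<double> num(C, eps), den(C, eps), sy(C, 0.0);
  double wsum = 0, ce = 0;
  for (long i = 0; i < n; ++i) {
    double mx = logits[i];
    for (int c = 1; c < C; ++c)
      mx = std::max(mx, (double)logits[i + n * c]);
    double s = 0;
    for (int c = 0; c < C; ++c) {
      const double e = std::exp(logits[i + n * c] - mx);
      p[i + n * c] = e;
      s += e;
    }
    const int t = target[i];
    for (int c = 0; c < C; ++c) {
      const double pv = p[i + n * c] / s;
      p[i + n * c] = pv;
      den[c] += pv;
    }
    num[t] += 2.0 * p[i + n * t];
    den[t] += 1.0;
    sy[t] += 1.0;
    const double w = cw[t];
    wsum += w;
    ce -= w * std::log(std::max(p[i + n * t], 1e-12));
  }
  ce /= wsum;
  double dice = 1.0;
  for (int c = 0; c < C; ++c) dice -= (num[c] / den[c]) / C;
  // gradients: dDice/dp then chain through softmax, plus CE term
  for (long i = 0; i < n; ++i) {
    const int t = target[i];
    double gp[8];   // C <= 8
    double dot = 0;
    for (int c = 0; c < C; ++c) {
      const double y = (c == t) ? 1.0 : 0.0;
      gp[c] = -(2.0 * y * den[c] - num[c]) / (den[c] * den[c]) / C;
      dot += gp[c] * p[i + n * c];
    }
    const double w = cw[t] / wsum;
    for (int c = 0; c < C; ++c) {
      const double y = (c == t) ? 1.0 : 0.0;
      dlog[i + n * c] = p[i + n * c] * (gp[c] - dot) +
        w * (p[i + n * c] - y);
    }
  }
  return List::create(_["dice"] = dice, _["ce"] = ce,
                      _["dlogits"] = dlog);
}

// Trilinear resize (align-corners = false), any channel count.
// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector dims, int c,
                           IntegerVector odims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Do = odims[0], Ho = odims[1], Wo = odims[2];
  const long N = (long)D * H * W, No = (long)Do * Ho * Wo;
  NumericVector out((R_xlen_t)(No * c));
  const double sd = (double)D / Do, sh = (double)H / Ho, sw = (double)W / Wo;
  for (int wo = 0; wo < Wo; ++wo) {
    double wi = (wo + 0.5) * sw - 0.5;
    if (wi < 0) wi = 0; if (wi > W - 1) wi = W - 1;
    const int w0 = (int)wi, w1 = (w0 < W - 1) ? w0 + 1 : w0;
    const double fw = wi - w0;
    for (int ho = 0; ho < Ho; ++ho) {
      double hi = (ho + 0.5) * sh - 0.5;
      if (hi < 0) hi = 0; if (hi > H - 1) hi = H - 1;
      const int h0 = (int)hi, h1 = (h0 < H - 1) ? h0 + 1 : h0;
      const double fh = hi - h0;
      for (int do_ = 0; do_ < Do; ++do_) {
        double di = (do_ + 0.5) * sd - 0.5;
        if (di < 0) di = 0; if (di > D - 1) di = D - 1;
        const int d0 = (int)di, d1 = (d0 < D - 1) ? d0 + 1 : d0;
        const double fd = di - d0;
        const long o = do_ + (long)ho * Do + (long)wo * Do * Ho;
        for (int ci = 0; ci < c; ++ci) {
          const double* xc = &x[0] + N * ci;
          const long b00 = (long)h0 * D + (long)w0 * D * H;
          const long b10 = (long)h1 * D + (long)w0 * D * H;
          const long b01 = (long)h0 * D + (long)w1 * D * H;
          const long b11 = (long)h1 * D + (long)w1 * D * H;
          const double v =
            (1-fd)*(1-fh)*(1-fw)*xc[d0+b00] + fd*(1-fh)*(1-fw)*xc[d1+b00] +
            (1-fd)*fh*(1-fw)*xc[d0+b10] + fd*fh*(1-fw)*xc[d1+b10] +
            (1-fd)*(1-fh)*fw*xc[d0+b01] + fd*(1-fh)*fw*xc[d1+b01] +
            (1-fd)*fh*fw*xc[d0+b11] + fd*fh*fw*xc[d1+b11];
          out[o + No * ci] = v;
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_resize3d: scatter output-grid gradients back to the
// input grid with the same trilinear weights.
// [[Rcpp::export]]
NumericVector cpp_resize3d_adj(NumericVector dout, IntegerVector odims,
                               int c, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Do = odims[0], Ho = odims[1], Wo = odims[2];
  const long N = (long)D * H * W, No = (long)Do * Ho * Wo;
  NumericVector dx((R_xlen_t)(N * c));
  const double sd = (double)D / Do, sh = (double)H / Ho, sw = (double)W / Wo;
  for (int wo = 0; wo < Wo; ++wo) {
    double wi = (wo + 0.5) * sw - 0.5;
    if (wi < 0) wi = 0; if (wi > W - 1) wi = W - 1;
    const int w0 = (int)wi, w1 = (w0 < W - 1) ? w0 + 1 : w0;
    const double fw = wi - w0;
    for (int ho = 0; ho < Ho; ++ho) {
      double hi = (ho + 0.5) * sh - 0.5;
      if (hi < 0) hi = 0; if (hi > H - 1) hi = H - 1;
      const int h0 = (int)hi, h1 = (h0 < H - 1) ? h0 + 1 : h0;
      const double fh = hi - h0;
      for (int do_ = 0; do_ < Do; ++do_) {
        double di = (do_ + 0.5) * sd - 0.5;
        if (di < 0) di = 0; if (di > D - 1) di = D - 1;
        const int d0 = (int)di, d1 = (d0 < D - 1) ? d0 + 1 : d0;
        const double fd = di - d0;
        const long o = do_ + (long)ho * Do + (long)wo * Do * Ho;
        for (int ci = 0; ci < c; ++ci) {
          double* xc = &dx[0] + N * ci;
          const double g = dout[o + No * ci];
          const long b00 = (long)h0 * D + (long)w0 * D * H;
          const long b10 = (long)h1 * D + (long)w0 * D * H;
          const long b01 = (long)h0 * D + (long)w1 * D * H;
          const long b11 = (long)h1 * D + (long)w1 * D * H;
          xc[d0+b00] += (1-fd)*(1-fh)*(1-fw)*g; xc[d1+b00] += fd*(1-fh)*(1-fw)*g;
          xc[d0+b10] += (1-fd)*fh*(1-fw)*g;     xc[d1+b10] += fd*fh*(1-fw)*g;
          xc[d0+b01] += (1-fd)*(1-fh)*fw*g;     xc[d1+b01] += fd*(1-fh)*fw*g;
          xc[d0+b11] += (1-fd)*fh*fw*g;         xc[d1+b11] += fd*fh*fw*g;
        }
      }
    }
  }
  return dx;
}

// Resample a single-channel volume under an affine map acting in
// physical (mm) coordinates about the grid centre: for each output voxel
// index i, p_out = (i - (odims-1)/2) * ospacing, p_in = A %*% p_out + t,
// and the input is interpolated at p_in / spacing + (dims-1)/2.
// nearest = true gives nearest-neighbour (for label masks).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector x, IntegerVector dims,
                                  NumericVector spacing, NumericMatrix A,
                                  NumericVector t, IntegerVector odims,
                                  NumericVector ospacing, bool nearest,
                                  double fill) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int Do = odims[0], Ho = odims[1], Wo = odims[2];
  NumericVector out((R_xlen_t)((long)Do * Ho * Wo));
  const double cd = (D - 1) / 2.0, ch = (H - 1) / 2.0, cw = (W - 1) / 2.0;
  const double cod = (Do - 1) / 2.0, coh = (Ho - 1) / 2.0,
               cow = (Wo - 1) / 2.0;
  long o = 0;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int do_ = 0; do_ < Do; ++do_) {
        // note the R loop order writes d fastest; recompute o explicitly
        o = do_ + (long)ho * Do + (long)wo * Do * Ho;
        const double pd = (do_ - cod) * ospacing[0];
        const double ph = (ho - coh) * ospacing[1];
        const double pw = (wo - cow) * ospacing[2];
        const double qd = A(0,0)*pd + A(0,1)*ph + A(0,2)*pw + t[0];
        const double qh = A(1,0)*pd + A(1,1)*ph + A(1,2)*pw + t[1];
        const double qw = A(2,0)*pd + A(2,1)*ph + A(2,2)*pw + t[2];
        const double id = qd / spacing[0] + cd;
        const double ih = qh / spacing[1] + ch;
        const double iw = qw / spacing[2] + cw;
        if (nearest) {
          const int d0 = (int)std::lround(id), h0 = (int)std::lround(ih),
                    w0 = (int)std::lround(iw);
          out[o] = (d0 >= 0 && d0 < D && h0 >= 0 && h0 < H && w0 >= 0 &&
                    w0 < W)
                     ? x[d0 + (long)h0 * D + (long)w0 * D * H]
                     : fill;
        } else {
          if (id < 0 || id > D - 1 || ih < 0 || ih > H - 1 || iw < 0 ||
              iw > W - 1) {
            out[o] = fill;
            continue;
          }
          const int d0 = (int)id, h0 = (int)ih, w0 = (int)iw;
          const int d1 = (d0 < D - 1) ? d0 + 1 : d0;
          const int h1 = (h0 < H - 1) ? h0 + 1 : h0;
          const int w1 = (w0 < W - 1) ? w0 + 1 : w0;
          const double fd = id - d0, fh = ih - h0, fw = iw - w0;
          const long b00 = (long)h0 * D + (long)w0 * D * H;
          const long b10 = (long)h1 * D + (long)w0 * D * H;
          const long b01 = (long)h0 * D + (long)w1 * D * H;
          const long b11 = (long)h1 * D + (long)w1 * D * H;
          out[o] =
            (1-fd)*(1-fh)*(1-fw)*x[d0+b00] + fd*(1-fh)*(1-fw)*x[d1+b00] +
            (1-fd)*fh*(1-fw)*x[d0+b10] + fd*fh*(1-fw)*x[d1+b10] +
            (1-fd)*(1-fh)*fw*x[d0+b01] + fd*(1-fh)*fw*x[d1+b01] +
            (1-fd)*fh*fw*x[d0+b11] + fd*fh*fw*x[d1+b11];
        }
      }
  return out;
}

// Separable Gaussian smoothing with reflection at the borders; sigma in
// voxels per axis (sigma <= 0 skips that axis).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector x, IntegerVector dims,
                               NumericVector sigma) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const long N = (long)D * H * W;
  std::vector<double> a(x.begin(), x.end()), b(N);
  const int n[3] = {D, H, W};
  const long strides[3] = {1, D, (long)D * H};
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * sigma[ax]));
    std::vector<double> k(2 * r + 1);
    double s = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (sigma[ax] * sigma[ax]));
      s += k[i + r];
    }
    for (double& v : k) v /= s;
    const int L = n[ax];
    const long st = strides[ax];
    for (long base = 0; base < N; ++base) {
      // walk only positions whose coordinate along ax is 0
      long rem = base;
      long coord;
      if (ax == 0) coord = rem % D;
      else if (ax == 1) coord = (rem / D) % H;
      else coord = rem / ((long)D * H);
      if (coord != 0) continue;
      for (int i = 0; i < L; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int ii = i + j;
          if (ii < 0) ii = -ii;                   // reflect
          if (ii > L - 1) ii = 2 * (L - 1) - ii;
          acc += k[j + r] * a[base + (long)ii * st];
        }
        b[base + (long)i * st] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Joint histogram of two equally sized volumes over [lo, hi] x [lo, hi].
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int nbins,
                             double lo, double hi) {
  NumericMatrix hmat(nbins, nbins);
  const double sc = nbins / (hi - lo);
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    int ia = (int)((a[i] - lo) * sc);
    int ib = (int)((b[i] - lo) * sc);
    if (ia < 0) ia = 0; if (ia >= nbins) ia = nbins - 1;
    if (ib < 0) ib = 0; if (ib >= nbins) ib = nbins - 1;
    hmat(ia, ib) += 1.0;
  }
  return hmat;
}

// 6-connected component labelling of voxels equal to `value`.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int value) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const long N = (long)D * H * W;
  IntegerVector lab(N);
  int cur = 0;
  std::queue<long> q;
  for (long i = 0; i < N; ++i) {
    if (mask[i] != value || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    q.push(i);
    while (!q.empty()) {
      const long v = q.front(); q.pop();
      const int d = v % D, h = (v / D) % H, w = v / ((long)D * H);
      const int dd[6] = {-1, 1, 0, 0, 0, 0};
      const int dh[6] = {0, 0, -1, 1, 0, 0};
      const int dw[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        const int d2 = d + dd[k], h2 = h + dh[k], w2 = w + dw[k];
        if (d2 < 0 || d2 >= D || h2 < 0 || h2 >= H || w2 < 0 || w2 >= W)
          continue;
        const long u = d2 + (long)h2 * D + (long)w2 * D * H;
        if (mask[u] == value && lab[u] == 0) { lab[u] = cur; q.push(u); }
      }
    }
  }
  return lab;
}
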