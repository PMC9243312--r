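// Low-level dense kernels for the multi-scale CNN engine.
//
// Array layout convention (column-major, as produced by base R):
//   activations: (C, D, H, W, N)   channel-fastest, batch-slowest
//   conv weight: (OC, C, kd, kh, kw)
//
// Convolution uses one of two equivalent schedules per sample:
//   * im2col + one GEMM when the patch matrix fits a modest buffer. The
//     column matrix is stored transposed, (npos x patch), so every
//     (offset, channel) pair owns one contiguous npos-long column and
//     gather/scatter writes are sequential. Fast when channels are few.
//   * a sum over kernel offsets of (OC x C)(C x npos) GEMMs with a single
//     (C x npos) gather buffer; memory-safe and GEMM-bound when channels
//     are many and the patch matrix would be huge.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// patch-matrix budget for the im2col path, in floats (~128 MB); the
// column matrix and its GEMMs run in single precision, adequate for
// SGD-style training and halving the memory traffic.
const long IM2COL_MAX = 32L * 1024L * 1024L;

struct Dims5 {
  int C, D, H, W, N;
};

Dims5 dims5(const IntegerVector &d) {
  if (d.size() != 5) stop("expected a 5-element dim vector");
  return Dims5{d[0], d[1], d[2], d[3], d[4]};
}

struct ConvGeom {
  Dims5 xd;
  int OC, kd, kh, kw, pd, ph, pw, oD, oH, oW;
  long npos, patch;
  bool im2col;
};

ConvGeom conv_geom(const IntegerVector &xdim, const IntegerVector &wdim,
                   const IntegerVector &pad, int force = 0) {
  ConvGeom g;
  g.xd = dims5(xdim);
  if (wdim.size() != 5) stop("weight dim must have 5 entries");
  if (wdim[1] != g.xd.C) stop("input channels do not match weight");
  g.OC = wdim[0];
  g.kd = wdim[2]; g.kh = wdim[3]; g.kw = wdim[4];
  g.pd = pad[0]; g.ph = pad[1]; g.pw = pad[2];
  g.oD = g.xd.D + 2 * g.pd - g.kd + 1;
  g.oH = g.xd.H + 2 * g.ph - g.kh + 1;
  g.oW = g.xd.W + 2 * g.pw - g.kw + 1;
  if (g.oD < 1 || g.oH < 1 || g.oW < 1)
    stop("kernel larger than padded input");
  g.npos = (long)g.oD * g.oH * g.oW;
  g.patch = (long)g.xd.C * g.kd * g.kh * g.kw;
  g.im2col = force == 0 ? g.patch * g.npos <= IM2COL_MAX : force == 1;
  return g;
}

// Gather the input slab shifted by offset (a,b,c) into buf (C x npos,
// channel-fastest), zero-filling padding positions.
void gather_block(const double *x, const ConvGeom &g,
                  int a, int b, int c, double *buf) {
  const int C = g.xd.C;
  for (int w = 0; w < g.oW; ++w) {
    const int sw = w + c - g.pw;
    for (int h = 0; h < g.oH; ++h) {
      const int sh = h + b - g.ph;
      double *dst = buf + (long)C * g.oD *
        ((long)h + (long)g.oH * w);
      const bool ok = sw >= 0 && sw < g.xd.W && sh >= 0 && sh < g.xd.H;
      int dlo = ok ? std::max(0, g.pd - a) : 1;
      int dhi = ok ? std::min(g.oD - 1, g.xd.D - 1 + g.pd - a) : 0;
      if (dlo > 0) std::fill(dst, dst + (long)C * std::min(dlo, g.oD), 0.0);
      if (dhi < g.oD - 1)
        std::fill(dst + (long)C * (dhi + 1), dst + (long)C * g.oD, 0.0);
      if (dlo <= dhi) {
        const double *src = x + (long)C *
          ((long)(dlo + a - g.pd) + (long)g.xd.D *
           ((long)sh + (long)g.xd.H * sw));
        std::copy(src, src + (long)C * (dhi - dlo + 1),
                  dst + (long)C * dlo);
      }
    }
  }
}

// Accumulate buf (C x npos) back into dx at the positions shifted by
// offset (a,b,c); transpose of gather_block.
void scatter_block(double *dx, const ConvGeom &g,
                   int a, int b, int c, const double *buf) {
  const int C = g.xd.C;
  for (int w = 0; w < g.oW; ++w) {
    const int sw = w + c - g.pw;
    if (sw < 0 || sw >= g.xd.W) continue;
    for (int h = 0; h < g.oH; ++h) {
      const int sh = h + b - g.ph;
      if (sh < 0 || sh >= g.xd.H) continue;
      const int dlo = std::max(0, g.pd - a);
      const int dhi = std::min(g.oD - 1, g.xd.D - 1 + g.pd - a);
      if (dlo > dhi) continue;
      const double *src = buf + (long)C * g.oD *
        ((long)h + (long)g.oH * w) + (long)C * dlo;
      double *out = dx + (long)C *
        ((long)(dlo + a - g.pd) + (long)g.xd.D *
         ((long)sh + (long)g.xd.H * sw));
      const long nn = (long)C * (dhi - dlo + 1);
      for (long i = 0; i < nn; ++i) out[i] += src[i];
    }
  }
}

// Fill the transposed column matrix (npos x patch): column (C*o + ci)
// holds channel ci of kernel offset o for every output position.
void im2col_t(const double *x, const ConvGeom &g, float *col) {
  const int C = g.xd.C;
  for (int c = 0; c < g.kw; ++c)
    for (int b = 0; b < g.kh; ++b)
      for (int a = 0; a < g.kd; ++a) {
        const long o = (long)a + g.kd * ((long)b + (long)g.kh * c);
        for (int ci = 0; ci < C; ++ci) {
          float *dst = col + ((long)C * o + ci) * g.npos;
          for (int w = 0; w < g.oW; ++w) {
            const int sw = w + c - g.pw;
            for (int h = 0; h < g.oH; ++h) {
              const int sh = h + b - g.ph;
              float *dcol = dst + (long)g.oD *
                ((long)h + (long)g.oH * w);
              const bool ok = sw >= 0 && sw < g.xd.W &&
                sh >= 0 && sh < g.xd.H;
              const int dlo = ok ? std::max(0, g.pd - a) : 1;
              const int dhi = ok ?
                std::min(g.oD - 1, g.xd.D - 1 + g.pd - a) : 0;
              for (int d = 0; d < dlo; ++d) dcol[d] = 0.0f;
              for (int d = dhi + 1; d < g.oD; ++d) dcol[d] = 0.0f;
              if (dlo <= dhi) {
                const double *src = x + ci + (long)C *
                  ((long)(dlo + a - g.pd) + (long)g.xd.D *
                   ((long)sh + (long)g.xd.H * sw));
                for (int d = dlo; d <= dhi; ++d)
                  dcol[d] = (float)src[(long)C * (d - dlo)];
              }
            }
          }
        }
      }
}

// Transpose of im2col_t: accumulate the (npos x patch) matrix back into
// the input gradient.
void col2im_t(double *dx, const ConvGeom &g, const float *col) {
  const int C = g.xd.C;
  for (int c = 0; c < g.kw; ++c)
    for (int b = 0; b < g.kh; ++b)
      for (int a = 0; a < g.kd; ++a) {
        const long o = (long)a + g.kd * ((long)b + (long)g.kh * c);
        for (int ci = 0; ci < C; ++ci) {
          const float *src = col + ((long)C * o + ci) * g.npos;
          for (int w = 0; w < g.oW; ++w) {
            const int sw = w + c - g.pw;
            if (sw < 0 || sw >= g.xd.W) continue;
            for (int h = 0; h < g.oH; ++h) {
              const int sh = h + b - g.ph;
              if (sh < 0 || sh >= g.xd.H) continue;
              const float *scol = src + (long)g.oD *
                ((long)h + (long)g.oH * w);
              const int dlo = std::max(0, g.pd - a);
              const int dhi = std::min(g.oD - 1, g.xd.D - 1 + g.pd - a);
              if (dlo > dhi) continue;
              double *out = dx + ci + (long)C *
                ((long)(dlo + a - g.pd) + (long)g.xd.D *
                 ((long)sh + (long)g.xd.H * sw));
              for (int d = dlo; d <= dhi; ++d)
                out[(long)C * (d - dlo)] += scol[d];
            }
          }
        }
      }
}

}  // namespace

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             IntegerVector pad, int force = 0) {
  ConvGeom g = conv_geom(xdim, wdim, pad, force);
  NumericVector y((long)g.OC * g.npos * g.xd.N);
  y.attr("dim") = IntegerVector::create(g.OC, g.oD, g.oH, g.oW, g.xd.N);
  const long xstride = (long)g.xd.C * g.xd.D * g.xd.H * g.xd.W;
  const arma::mat Wm(const_cast<double *>(&w[0]), g.OC, g.patch,
                     false, true);
  if (g.im2col) {
    std::vector<float> col(g.patch * g.npos);
    const arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wm);
    arma::fmat Yt(g.npos, g.OC);
    for (int n = 0; n < g.xd.N; ++n) {
      im2col_t(&x[0] + xstride * n, g, col.data());
      const arma::fmat Col(col.data(), g.npos, g.patch, false, true);
      Yt = Col * Wf.t();
      double *yn = &y[0] + (long)g.OC * g.npos * n;
      for (long p = 0; p < g.npos; ++p)
        for (int oc = 0; oc < g.OC; ++oc)
          yn[oc + (long)g.OC * p] = (double)Yt(p, oc);
    }
  } else {
    std::vector<double> buf((long)g.xd.C * g.npos);
    for (int n = 0; n < g.xd.N; ++n) {
      arma::mat Y(&y[0] + (long)g.OC * g.npos * n, g.OC, g.npos,
                  false, true);
      for (int c = 0; c < g.kw; ++c)
        for (int b = 0; b < g.kh; ++b)
          for (int a = 0; a < g.kd; ++a) {
            gather_block(&x[0] + xstride * n, g, a, b, c, buf.data());
            const arma::mat Wo(const_cast<double *>(&w[0]) +
                                   (long)g.OC * g.xd.C *
                                       ((long)a + g.kd *
                                        ((long)b + (long)g.kh * c)),
                               g.OC, g.xd.C, false, true);
            const arma::mat Xs(buf.data(), g.xd.C, g.npos, false, true);
            if (a == 0 && b == 0 && c == 0) Y = Wo * Xs;
            else Y += Wo * Xs;
          }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy, IntegerVector pad,
                    bool need_dx, int force = 0) {
  ConvGeom g = conv_geom(xdim, wdim, pad, force);
  NumericVector dw((long)g.OC * g.patch);
  dw.attr("dim") = wdim;
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(x.size());
    dx.attr("dim") = xdim;
  }
  const long xstride = (long)g.xd.C * g.xd.D * g.xd.H * g.xd.W;
  arma::mat dWm(&dw[0], g.OC, g.patch, false, true);
  const arma::mat Wm(const_cast<double *>(&w[0]), g.OC, g.patch,
                     false, true);
  if (g.im2col) {
    std::vector<float> col(g.patch * g.npos);
    std::vector<float> tbuf(need_dx ? g.patch * g.npos : 0);
    std::vector<float> dyf((long)g.OC * g.npos);
    const arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wm);
    arma::fmat dWf(g.OC, g.patch, arma::fill::zeros);
    for (int n = 0; n < g.xd.N; ++n) {
      const double *dyn = &dy[0] + (long)g.OC * g.npos * n;
      for (long i = 0; i < (long)g.OC * g.npos; ++i)
        dyf[i] = (float)dyn[i];
      const arma::fmat dY(dyf.data(), g.OC, g.npos, false, true);
      im2col_t(&x[0] + xstride * n, g, col.data());
      const arma::fmat Col(col.data(), g.npos, g.patch, false, true);
      dWf += dY * Col;
      if (need_dx) {
        arma::fmat T(tbuf.data(), g.npos, g.patch, false, true);
        T = dY.t() * Wf;
        col2im_t(&dx[0] + xstride * n, g, tbuf.data());
      }
    }
    dWm = arma::conv_to<arma::mat>::from(dWf);
  } else {
    std::vector<double> buf((long)g.xd.C * g.npos);
    std::vector<double> tbuf(need_dx ? (long)g.xd.C * g.npos : 0);
    for (int n = 0; n < g.xd.N; ++n) {
      const arma::mat dY(const_cast<double *>(&dy[0]) +
                             (long)g.OC * g.npos * n,
                         g.OC, g.npos, false, true);
      for (int c = 0; c < g.kw; ++c)
        for (int b = 0; b < g.kh; ++b)
          for (int a = 0; a < g.kd; ++a) {
            const long widx = (long)g.OC * g.xd.C *
              ((long)a + g.kd * ((long)b + (long)g.kh * c));
            gather_block(&x[0] + xstride * n, g, a, b, c, buf.data());
            const arma::mat Xs(buf.data(), g.xd.C, g.npos, false, true);
            arma::mat dWo(&dw[0] + widx, g.OC, g.xd.C, false, true);
            dWo += dY * Xs.t();
            if (need_dx) {
              const arma::mat Wo(const_cast<double *>(&w[0]) + widx,
                                 g.OC, g.xd.C, false, true);
              arma::mat T(tbuf.data(), g.xd.C, g.npos, false, true);
              T = Wo.t() * dY;
              scatter_block(&dx[0] + xstride * n, g, a, b, c,
                            tbuf.data());
            }
          }
    }
  }
  return List::create(_["dw"] = dw, _["dx"] = dx);
}

// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                       IntegerVector pool) {
  Dims5 xd = dims5(xdim);
  const int pd = pool[0], ph = pool[1], pw = pool[2];
  const int oD = xd.D / pd, oH = xd.H / ph, oW = xd.W / pw;
  if (oD < 1 || oH < 1 || oW < 1) stop("pool window exhausts an axis");
  const int C = xd.C;
  const long on = (long)C * oD * oH * oW;
  NumericVector y(on * xd.N);
  y.attr("dim") = IntegerVector::create(C, oD, oH, oW, xd.N);
  IntegerVector idx(on * xd.N);  // 0-based linear index into x (per sample)
  const long xstride = (long)C * xd.D * xd.H * xd.W;
  for (int n = 0; n < xd.N; ++n) {
    const double *xs = &x[0] + xstride * n;
    double *ys = &y[0] + on * n;
    int *is = &idx[0] + on * n;
    for (int w = 0; w < oW; ++w)
      for (int h = 0; h < oH; ++h)
        for (int d = 0; d < oD; ++d) {
          const long o = (long)C * ((long)d + (long)oD *
                                    ((long)h + (long)oH * w));
          double *yo = ys + o;
          int *io = is + o;
          bool first = true;
          for (int kw_ = 0; kw_ < pw; ++kw_)
            for (int kh_ = 0; kh_ < ph; ++kh_)
              for (int kd_ = 0; kd_ < pd; ++kd_) {
                const long li = (long)C *
                  ((long)(d * pd + kd_) + (long)xd.D *
                   ((long)(h * ph + kh_) + (long)xd.H * (w * pw + kw_)));
                const double *xi = xs + li;
                if (first) {
                  for (int ci = 0; ci < C; ++ci) {
                    yo[ci] = xi[ci];
                    io[ci] = (int)(li + ci);
                  }
                  first = false;
                } else {
                  for (int ci = 0; ci < C; ++ci) {
                    if (xi[ci] > yo[ci]) {
                      yo[ci] = xi[ci];
                      io[ci] = (int)(li + ci);
                    }
                  }
                }
              }
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector dy, IntegerVector idx,
                                IntegerVector xdim) {
  Dims5 xd = dims5(xdim);
  NumericVector dx((long)xd.C * xd.D * xd.H * xd.W * xd.N);
  dx.attr("dim") = xdim;
  const long xstride = (long)xd.C * xd.D * xd.H * xd.W;
  const long on = dy.size() / xd.N;
  for (int n = 0; n < xd.N; ++n) {
    double *dxs = &dx[0] + xstride * n;
    const long off = on * n;
    for (long o = 0; o < on; ++o) dxs[idx[off + o]] += dy[off + o];
  }
  return dx;
}
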