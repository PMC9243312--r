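// Fused batch-norm + leaky-ReLU passes. Arrays are channel-fastest; the
// channel statistics therefore stride over contiguous C-blocks.

#include <Rcpp.h>
using namespace Rcpp;

// per-channel mean and (biased) variance over all positions and samples
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x, int C) {
  const long m = x.size() / C;
  NumericVector mean(C), var(C);
  for (long j = 0; j < m; ++j) {
    const double *xi = &x[0] + (long)C * j;
    for (int ci = 0; ci < C; ++ci) {
      mean[ci] += xi[ci];
      var[ci] += xi[ci] * xi[ci];
    }
  }
  for (int ci = 0; ci < C; ++ci) {
    mean[ci] /= m;
    var[ci] = var[ci] / m - mean[ci] * mean[ci];
    if (var[ci] < 0) var[ci] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = leaky(g * xhat + b), xhat = (x - mean) * invstd; returns the
// activation and (optionally) the normalized input for backward.
// [[Rcpp::export]]
List bnleaky_fwd_cpp(NumericVector x, int C, NumericVector g,
                     NumericVector b, NumericVector mean,
                     NumericVector invstd, double slope,
                     bool want_cache) {
  const long m = x.size() / C;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector xhat;
  if (want_cache) xhat = NumericVector(x.size());
  for (long j = 0; j < m; ++j) {
    const double *xi = &x[0] + (long)C * j;
    double *yi = &y[0] + (long)C * j;
    double *hi = want_cache ? &xhat[0] + (long)C * j : nullptr;
    for (int ci = 0; ci < C; ++ci) {
      const double h = (xi[ci] - mean[ci]) * invstd[ci];
      const double z = g[ci] * h + b[ci];
      yi[ci] = z > 0 ? z : slope * z;
      if (hi) hi[ci] = h;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Backward through leaky(BN(x)) with training-mode statistics. dy and the
// cached activation y (for the leaky sign) and xhat come in; returns dx,
// dgamma, dbeta.
// [[Rcpp::export]]
List bnleaky_bwd_cpp(NumericVector dy, NumericVector y, NumericVector xhat,
                     int C, NumericVector g, NumericVector invstd,
                     double slope, bool batch_stats) {
  const long m = dy.size() / C;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  // first pass: gradients through the affine transform
  for (long j = 0; j < m; ++j) {
    const double *dyi = &dy[0] + (long)C * j;
    const double *yi = &y[0] + (long)C * j;
    const double *hi = &xhat[0] + (long)C * j;
    double *di = &dx[0] + (long)C * j;
    for (int ci = 0; ci < C; ++ci) {
      const double dz = yi[ci] > 0 ? dyi[ci] : slope * dyi[ci];
      di[ci] = dz;  // temporarily holds d(bn_y)
      dgamma[ci] += dz * hi[ci];
      dbeta[ci] += dz;
    }
  }
  // second pass: through the normalization
  if (batch_stats) {
    for (long j = 0; j < m; ++j) {
      const double *hi = &xhat[0] + (long)C * j;
      double *di = &dx[0] + (long)C * j;
      for (int ci = 0; ci < C; ++ci) {
        di[ci] = g[ci] * invstd[ci] *
          (di[ci] - hi[ci] * dgamma[ci] / m - dbeta[ci] / m);
      }
    }
  } else {
    for (long j = 0; j < m; ++j) {
      double *di = &dx[0] + (long)C * j;
      for (int ci = 0; ci < C; ++ci) di[ci] *= g[ci] * invstd[ci];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
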