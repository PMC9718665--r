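#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Tensors are stored as (H*W*N) x C matrices, rows ordered with the row
// coordinate fastest: row = h + H*w + H*W*n (0-based). All kernels below
// keep that convention.

// Expand a batch into 3x3 patch columns (zero padding, stride 1).
// Output: (H*W*N) x (9*C); column k + 9*c holds offset k = (dy+1) + 3*(dx+1).
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericMatrix x, int H, int W, int N) {
  int C = x.ncol();
  R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix out(rows, 9 * C);
  int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 9; ++k) {
      int dy = k % 3 - 1;
      int dx = k / 3 - 1;
      int oc = k + 9 * c;
      double *dst = &out(0, oc);
      const double *src = &x(0, c);
      int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);  // valid h range
      for (int n = 0; n < N; ++n) {
        const double *im = src + (R_xlen_t)n * HW;
        double *o = dst + (R_xlen_t)n * HW;
        for (int w = 0; w < W; ++w) {
          int ws = w + dx;
          if (ws < 0 || ws >= W) continue;  // column stays zero
          if (h1 > h0)
            std::memcpy(o + h0 + H * w, im + h0 + dy + H * ws,
                        (h1 - h0) * sizeof(double));
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch-column gradients back to the image.
// [[Rcpp::export(name = ".col2im3")]]
NumericMatrix col2im3(NumericMatrix g, int H, int W, int N, int C) {
  R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix out(rows, C);
  int HW = H * W;
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 9; ++k) {
      int dy = k % 3 - 1;
      int dx = k / 3 - 1;
      const double *src = &g(0, k + 9 * c);
      double *dst = &out(0, c);
      int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
      for (int n = 0; n < N; ++n) {
        const double *gi = src + (R_xlen_t)n * HW;
        double *o = dst + (R_xlen_t)n * HW;
        for (int w = 0; w < W; ++w) {
          int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          const double *gcol = gi + H * w;
          double *ocol = o + dy + H * ws;
          for (int h = h0; h < h1; ++h) ocol[h] += gcol[h];
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling (H, W even). Returns pooled matrix and 1-based argmax row
// indices into the input, for the backward pass.
// [[Rcpp::export(name = ".maxpool2")]]
List maxpool2(NumericMatrix x, int H, int W, int N) {
  int C = x.ncol();
  int Ho = H / 2, Wo = W / 2;
  R_xlen_t rows = (R_xlen_t)Ho * Wo * N;
  NumericMatrix out(rows, C);
  IntegerMatrix amax(rows, C);
  int HW = H * W, HWo = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t orow = h + (R_xlen_t)Ho * w + (R_xlen_t)HWo * n;
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t bidx = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              R_xlen_t irow = (2 * h + dh) + (R_xlen_t)H * (2 * w + dw) +
                              (R_xlen_t)HW * n;
              double v = x(irow, c);
              if (v > best) { best = v; bidx = irow; }
            }
          }
          out(orow, c) = best;
          amax(orow, c) = (int)(bidx + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// Backward of 2x2 max pooling: route gradients to the argmax positions.
// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericMatrix maxpool2_bwd(NumericMatrix g, IntegerMatrix amax,
                           int H, int W, int N) {
  int C = g.ncol();
  NumericMatrix out((R_xlen_t)H * W * N, C);
  for (int c = 0; c < C; ++c) {
    for (R_xlen_t r = 0; r < g.nrow(); ++r) {
      out(amax(r, c) - 1, c) += g(r, c);
    }
  }
  return out;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(name = ".upsample2")]]
NumericMatrix upsample2(NumericMatrix x, int H, int W, int N) {
  int C = x.ncol();
  int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix out((R_xlen_t)Ho * Wo * N, C);
  int HW = H * W, HWo = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          out(h + (R_xlen_t)Ho * w + (R_xlen_t)HWo * n, c) =
            x((h / 2) + (R_xlen_t)H * (w / 2) + (R_xlen_t)HW * n, c);
        }
      }
    }
  }
  return out;
}

// Backward of nearest 2x upsampling: sum the four children of each source.
// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericMatrix upsample2_bwd(NumericMatrix g, int H, int W, int N) {
  // H, W are the *input* (coarse) dims.
  int C = g.ncol();
  int Ho = 2 * H, Wo = 2 * W;
  NumericMatrix out((R_xlen_t)H * W * N, C);
  int HW = H * W, HWo = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          out((h / 2) + (R_xlen_t)H * (w / 2) + (R_xlen_t)HW * n, c) +=
            g(h + (R_xlen_t)Ho * w + (R_xlen_t)HWo * n, c);
        }
      }
    }
  }
  return out;
}

// Heat diffusion inside one ROI mask. Each iteration deposits one unit of
// heat at the centre pixel and replaces every in-mask value by the mean of
// its 9-neighbourhood (out-of-mask neighbours contribute 0). Returns the
// scalar field whose gradient points toward the centre.
// [[Rcpp::export(name = ".diffuseMask")]]
NumericMatrix diffuseMask(LogicalMatrix mask, int cy, int cx, int niter) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix T(H, W), Tn(H, W);
  for (int it = 0; it < niter; ++it) {
    T(cy, cx) += 1.0;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        if (!mask(h, w)) { Tn(h, w) = 0.0; continue; }
        double s = 0.0;
        for (int dw = -1; dw <= 1; ++dw) {
          int ww = w + dw;
          if (ww < 0 || ww >= W) continue;
          for (int dh = -1; dh <= 1; ++dh) {
            int hh = h + dh;
            if (hh < 0 || hh >= H) continue;
            if (mask(hh, ww)) s += T(hh, ww);
          }
        }
        Tn(h, w) = s / 9.0;
      }
    }
    std::swap(T, Tn);
  }
  return T;
}

// Minimum-cost square assignment (Hungarian algorithm with potentials,
// O(n^3)). cost is n x n; returns for each row its assigned column (1-based).
// [[Rcpp::export(name = ".hungarian")]]
IntegerVector hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// Fused batch-norm forward. Returns y, xh (normalized input), ist and the
// updated running statistics.
// [[Rcpp::export(name = ".bnFwd")]]
List bnFwd(NumericMatrix x, NumericVector gamma, NumericVector beta,
           NumericVector rm, NumericVector rv, bool train,
           double momentum, double eps) {
  R_xlen_t n = x.nrow();
  int C = x.ncol();
  NumericMatrix y(n, C), xh(n, C);
  NumericVector ist(C), newRm(C), newRv(C);
  for (int c = 0; c < C; ++c) {
    const double *xc = &x(0, c);
    double mu, var;
    if (train) {
      double s = 0.0, s2 = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu = s / n;
      var = s2 / n - mu * mu;
      newRm[c] = (1 - momentum) * rm[c] + momentum * mu;
      newRv[c] = (1 - momentum) * rv[c] + momentum * var;
    } else {
      mu = rm[c]; var = rv[c];
      newRm[c] = rm[c]; newRv[c] = rv[c];
    }
    double is = 1.0 / std::sqrt(var + eps);
    ist[c] = is;
    double g = gamma[c], b = beta[c];
    double *yc = &y(0, c), *hc = &xh(0, c);
    for (R_xlen_t i = 0; i < n; ++i) {
      double h = (xc[i] - mu) * is;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xh"] = xh, _["ist"] = ist,
                      _["newRm"] = newRm, _["newRv"] = newRv);
}

// Fused batch-norm backward (training statistics).
// [[Rcpp::export(name = ".bnBwd")]]
List bnBwd(NumericMatrix dy, NumericMatrix xh, NumericVector gamma,
           NumericVector ist) {
  R_xlen_t n = dy.nrow();
  int C = dy.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *dc = &dy(0, c), *hc = &xh(0, c);
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    double g = gamma[c], is = ist[c];
    double m1 = g * sb / n, m2 = g * sg / n;
    double *xc = &dx(0, c);
    for (R_xlen_t i = 0; i < n; ++i)
      xc[i] = (g * dc[i] - m1 - hc[i] * m2) * is;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
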