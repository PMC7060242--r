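#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: images / feature maps are R arrays dim (H, W, C, N),
// column-major. Kernels are arrays dim (k, k, Cin, Cout) flattened to a
// (k*k*Cin) x Cout matrix on the R side. im2col row r = h + H*w + H*W*n,
// column j = ky + k*kx + k*k*c, so cols %*% kmat gives 'same'-padded
// stride-1 convolution outputs in (H, W) order per item.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N, int k) {
  const int p = k / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  const int cols = k * k * C;
  NumericMatrix out(rows, cols);
  const double *xp = x.begin();
  double *op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int j = ky + k * kx + k * k * c;
        double *col = op + (R_xlen_t)j * rows;
        for (int n = 0; n < N; ++n) {
          const double *plane = xp + ((R_xlen_t)n * C + c) * H * W;
          R_xlen_t r = (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + kx - p;
            if (sw < 0 || sw >= W) { r += H; continue; }
            const double *src = plane + (R_xlen_t)sw * H;
            for (int h = 0; h < H; ++h, ++r) {
              const int sh = h + ky - p;
              if (sh >= 0 && sh < H) col[r] = src[sh];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int N, int k) {
  const int p = k / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericVector out((R_xlen_t)H * W * C * N);
  double *xp = out.begin();
  const double *cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int j = ky + k * kx + k * k * c;
        const double *col = cp + (R_xlen_t)j * rows;
        for (int n = 0; n < N; ++n) {
          double *plane = xp + ((R_xlen_t)n * C + c) * H * W;
          R_xlen_t r = (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + kx - p;
            if (sw < 0 || sw >= W) { r += H; continue; }
            double *dst = plane + (R_xlen_t)sw * H;
            for (int h = 0; h < H; ++h, ++r) {
              const int sh = h + ky - p;
              if (sh >= 0 && sh < H) dst[sh] += col[r];
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based linear
// indices of each maximum (first occurrence in column-major scan wins),
// for use by the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t no = (R_xlen_t)Ho * Wo * C * N;
  NumericVector out(no);
  IntegerVector idx(no);
  const double *xp = x.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          R_xlen_t best = base + (R_xlen_t)(2 * wo) * H + 2 * ho;
          double bv = xp[best];
          const R_xlen_t cand[3] = { best + 1, best + H, best + H + 1 };
          for (int t = 0; t < 3; ++t) {
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          }
          out[o] = bv;
          idx[o] = (int)(best + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector idx, R_xlen_t n_in) {
  NumericVector dx(n_in);
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[idx[i] - 1] += dout[i];
  return dx;
}

// Disc rasteriser for the simulator: adds `value` to every pixel of `img`
// (H x W, column-major) within radius r of (cy, cx), 1-based centres.
// Returns the number of pixels touched so callers can normalise by area.
// [[Rcpp::export]]
int cpp_add_disc(NumericVector img, int H, int W, double cy, double cx,
                 double r, double value) {
  int lo_w = (int)std::ceil(cx - r), hi_w = (int)std::floor(cx + r);
  if (lo_w < 1) lo_w = 1;
  if (hi_w > W) hi_w = W;
  const double r2 = r * r;
  double *p = img.begin();
  int count = 0;
  for (int w = lo_w; w <= hi_w; ++w) {
    const double dx = w - cx;
    const double span = std::sqrt(std::max(0.0, r2 - dx * dx));
    int lo_h = (int)std::ceil(cy - span), hi_h = (int)std::floor(cy + span);
    if (lo_h < 1) lo_h = 1;
    if (hi_h > H) hi_h = H;
    double *colp = p + (R_xlen_t)(w - 1) * H;
    for (int h = lo_h; h <= hi_h; ++h, ++count) colp[h - 1] += value;
  }
  return count;
}

// Annulus rasteriser: adds value on r_in < d <= r_out.
// [[Rcpp::export]]
int cpp_add_annulus(NumericVector img, int H, int W, double cy, double cx,
                    double r_in, double r_out, double value) {
  int lo_w = (int)std::ceil(cx - r_out), hi_w = (int)std::floor(cx + r_out);
  if (lo_w < 1) lo_w = 1;
  if (hi_w > W) hi_w = W;
  const double ri2 = r_in * r_in, ro2 = r_out * r_out;
  double *p = img.begin();
  int count = 0;
  for (int w = lo_w; w <= hi_w; ++w) {
    const double dx2 = (w - cx) * (w - cx);
    if (dx2 > ro2) continue;
    double *colp = p + (R_xlen_t)(w - 1) * H;
    int lo_h = (int)std::ceil(cy - std::sqrt(ro2 - dx2));
    int hi_h = (int)std::floor(cy + std::sqrt(ro2 - dx2));
    if (lo_h < 1) lo_h = 1;
    if (hi_h > H) hi_h = H;
    for (int h = lo_h; h <= hi_h; ++h) {
      const double d2 = dx2 + (h - cy) * (h - cy);
      if (d2 > ri2 && d2 <= ro2) { colp[h - 1] += value; ++count; }
    }
  }
  return count;
}

// ---- matrix-layout kernels -------------------------------------------------
// Activations flow through the feature extractor as (H*W*N) x C matrices
// with row index r = h + H*w + H*W*n. This keeps convolution (im2col +
// GEMM), batch norm and pooling in one memory layout with no transposes.

// im2col from the matrix layout, for items n0..n1 (0-based, inclusive).
// [[Rcpp::export]]
NumericMatrix cpp_im2col_mat(NumericMatrix x, int H, int W, int N, int k,
                             int n0, int n1) {
  const int p = k / 2;
  const int C = x.ncol();
  const int nItems = n1 - n0 + 1;
  const R_xlen_t rows = (R_xlen_t)H * W * nItems;
  NumericMatrix out(rows, k * k * C);
  const double *xp = x.begin();
  const R_xlen_t xrows = x.nrow();
  double *op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = xp + (R_xlen_t)c * xrows;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int j = ky + k * kx + k * k * c;
        double *col = op + (R_xlen_t)j * rows;
        R_xlen_t r = 0;
        for (int n = n0; n <= n1; ++n) {
          const double *item = plane + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + kx - p;
            if (sw < 0 || sw >= W) {
              for (int h = 0; h < H; ++h, ++r) col[r] = 0.0;
              continue;
            }
            const double *src = item + (R_xlen_t)sw * H;
            for (int h = 0; h < H; ++h, ++r) {
              const int sh = h + ky - p;
              col[r] = (sh >= 0 && sh < H) ? src[sh] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col_mat: scatter-add cols into a (H*W*nItems) x C
// gradient block.
// [[Rcpp::export]]
NumericMatrix cpp_col2im_mat(NumericMatrix cols, int H, int W, int C,
                             int nItems, int k) {
  const int p = k / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * nItems;
  NumericMatrix out(rows, C);
  const double *cp = cols.begin();
  double *op = out.begin();
  for (int c = 0; c < C; ++c) {
    double *plane = op + (R_xlen_t)c * rows;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int j = ky + k * kx + k * k * c;
        const double *col = cp + (R_xlen_t)j * rows;
        R_xlen_t r = 0;
        for (int n = 0; n < nItems; ++n) {
          double *item = plane + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + kx - p;
            if (sw < 0 || sw >= W) { r += H; continue; }
            double *dst = item + (R_xlen_t)sw * H;
            for (int h = 0; h < H; ++h, ++r) {
              const int sh = h + ky - p;
              if (sh >= 0 && sh < H) dst[sh] += col[r];
            }
          }
        }
      }
    }
  }
  return out;
}

// In-place fused bias add + ReLU on a (rows x F) pre-activation matrix.
// [[Rcpp::export]]
void cpp_bias_relu(NumericMatrix A, NumericVector b) {
  const R_xlen_t rows = A.nrow();
  const int F = A.ncol();
  double *p = A.begin();
  for (int f = 0; f < F; ++f) {
    const double bf = b[f];
    double *col = p + (R_xlen_t)f * rows;
    for (R_xlen_t r = 0; r < rows; ++r) {
      const double v = col[r] + bf;
      col[r] = v > 0.0 ? v : 0.0;
    }
  }
}

// Column means and (population) variances in one pass.
// [[Rcpp::export]]
List cpp_col_meanvar(NumericMatrix A) {
  const R_xlen_t rows = A.nrow();
  const int F = A.ncol();
  NumericVector mu(F), v(F);
  const double *p = A.begin();
  for (int f = 0; f < F; ++f) {
    const double *col = p + (R_xlen_t)f * rows;
    double s = 0, s2 = 0;
    for (R_xlen_t r = 0; r < rows; ++r) { s += col[r]; s2 += col[r] * col[r]; }
    mu[f] = s / rows;
    v[f] = s2 / rows - mu[f] * mu[f];
    if (v[f] < 0) v[f] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// Batch-norm affine transform into a fresh matrix.
// [[Rcpp::export]]
NumericMatrix cpp_bn_apply(NumericMatrix A, NumericVector mu,
                           NumericVector invstd, NumericVector gamma,
                           NumericVector beta) {
  const R_xlen_t rows = A.nrow();
  const int F = A.ncol();
  NumericMatrix out(rows, F);
  const double *p = A.begin();
  double *o = out.begin();
  for (int f = 0; f < F; ++f) {
    const double m = mu[f], is = invstd[f], g = gamma[f], bt = beta[f];
    const double *col = p + (R_xlen_t)f * rows;
    double *oc = o + (R_xlen_t)f * rows;
    for (R_xlen_t r = 0; r < rows; ++r) oc[r] = g * (col[r] - m) * is + bt;
  }
  return out;
}

// Batch-norm backward: dX, dgamma, dbeta from upstream dY and the stored
// pre-normalisation activations Ar (xhat is recomputed on the fly).
// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dY, NumericMatrix Ar, NumericVector mu,
                NumericVector invstd, NumericVector gamma) {
  const R_xlen_t rows = dY.nrow();
  const int F = dY.ncol();
  NumericMatrix dX(rows, F);
  NumericVector dgamma(F), dbeta(F);
  const double *dp = dY.begin();
  const double *ap = Ar.begin();
  double *xp = dX.begin();
  for (int f = 0; f < F; ++f) {
    const double m = mu[f], is = invstd[f], g = gamma[f];
    const double *dc = dp + (R_xlen_t)f * rows;
    const double *ac = ap + (R_xlen_t)f * rows;
    double *xc = xp + (R_xlen_t)f * rows;
    double s1 = 0, s2 = 0;
    for (R_xlen_t r = 0; r < rows; ++r) {
      const double xhat = (ac[r] - m) * is;
      s1 += dc[r];
      s2 += dc[r] * xhat;
    }
    dbeta[f] = s1;
    dgamma[f] = s2;
    const double c1 = s1 / rows, c2 = s2 / rows;
    for (R_xlen_t r = 0; r < rows; ++r) {
      const double xhat = (ac[r] - m) * is;
      xc[r] = g * is * (dc[r] - c1 - xhat * c2);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 2x2 max pooling on the matrix layout: rows (h, w, n), one column per
// channel. Returns the pooled matrix and 1-based linear indices into the
// input matrix for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_mat(NumericMatrix Y, int H, int W, int N) {
  const int F = Y.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t inRows = Y.nrow();
  const R_xlen_t outRows = (R_xlen_t)Ho * Wo * N;
  NumericMatrix out(outRows, F);
  IntegerVector idx(outRows * F);
  const double *yp = Y.begin();
  double *op = out.begin();
  int *ip = idx.begin();
  for (int f = 0; f < F; ++f) {
    const double *col = yp + (R_xlen_t)f * inRows;
    double *oc = op + (R_xlen_t)f * outRows;
    int *ic = ip + (R_xlen_t)f * outRows;
    R_xlen_t o = 0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t base = (R_xlen_t)n * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          R_xlen_t best = base + (R_xlen_t)(2 * wo) * H + 2 * ho;
          double bv = col[best];
          const R_xlen_t cand[3] = { best + 1, best + H, best + H + 1 };
          for (int t = 0; t < 3; ++t)
            if (col[cand[t]] > bv) { bv = col[cand[t]]; best = cand[t]; }
          oc[o] = bv;
          ic[o] = (int)((R_xlen_t)f * inRows + best + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Scatter pooled gradients back through the max locations.
// [[Rcpp::export]]
NumericMatrix cpp_maxpool_mat_bwd(NumericMatrix dOut, IntegerVector idx,
                                  int inRows) {
  const int F = dOut.ncol();
  NumericMatrix dX(inRows, F);
  const double *dp = dOut.begin();
  double *xp = dX.begin();
  const int *ip = idx.begin();
  const R_xlen_t n = dOut.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[ip[i] - 1] += dp[i];
  return dX;
}

// In-place ReLU gradient gate: dX[i] = 0 where Ar[i] == 0.
// [[Rcpp::export]]
void cpp_relu_bwd(NumericMatrix dX, NumericMatrix Ar) {
  double *dp = dX.begin();
  const double *ap = Ar.begin();
  const R_xlen_t n = dX.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (ap[i] <= 0.0) dp[i] = 0.0;
}

// Block row means: rows grouped in consecutive blocks of `block`; output
// one row per block (global average pooling over the spatial rows).
// [[Rcpp::export]]
NumericMatrix cpp_block_rowmeans(NumericMatrix P, int block) {
  const R_xlen_t rows = P.nrow();
  const int F = P.ncol();
  const R_xlen_t nb = rows / block;
  NumericMatrix out(nb, F);
  const double *p = P.begin();
  double *o = out.begin();
  for (int f = 0; f < F; ++f) {
    const double *col = p + (R_xlen_t)f * rows;
    double *oc = o + (R_xlen_t)f * nb;
    for (R_xlen_t b = 0; b < nb; ++b) {
      double s = 0;
      const double *blk = col + b * block;
      for (int i = 0; i < block; ++i) s += blk[i];
      oc[b] = s / block;
    }
  }
  return out;
}

// Adjoint of cpp_block_rowmeans: spread each block mean gradient evenly.
// [[Rcpp::export]]
NumericMatrix cpp_block_rowmeans_bwd(NumericMatrix dV, int block) {
  const R_xlen_t nb = dV.nrow();
  const int F = dV.ncol();
  NumericMatrix out(nb * block, F);
  const double *p = dV.begin();
  double *o = out.begin();
  for (int f = 0; f < F; ++f) {
    const double *col = p + (R_xlen_t)f * nb;
    double *oc = o + (R_xlen_t)f * nb * block;
    for (R_xlen_t b = 0; b < nb; ++b) {
      const double v = col[b] / block;
      double *blk = oc + b * block;
      for (int i = 0; i < block; ++i) blk[i] = v;
    }
  }
  return out;
}

// Direct 'same' 3x3 convolution on the matrix layout, cache-blocked by
// image column: for the shallow wide layers the im2col buffer is pure
// memory traffic, and reading each input column once beats GEMM on
// bandwidth-limited machines. Kernel kt is transposed: kt[f + F*j] with
// j = ky + 3*kx + 9*c.
// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(NumericMatrix x, int H, int W, int N,
                            NumericVector kt, int F) {
  const int C = x.ncol();
  const R_xlen_t rows = x.nrow();
  NumericMatrix out(rows, F);
  const double *xp = x.begin();
  const double *kp = kt.begin();
  double *op = out.begin();
  std::vector<double> acc(F);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t ibase = (R_xlen_t)n * H * W;
    for (int w = 0; w < W; ++w) {
      const R_xlen_t obase = ibase + (R_xlen_t)w * H;
      for (int h = 0; h < H; ++h) {
        for (int f = 0; f < F; ++f) acc[f] = 0.0;
        for (int c = 0; c < C; ++c) {
          const double *plane = xp + (R_xlen_t)c * rows + ibase;
          for (int kx = 0; kx < 3; ++kx) {
            const int sw = w + kx - 1;
            if (sw < 0 || sw >= W) continue;
            const double *col = plane + (R_xlen_t)sw * H;
            for (int ky = 0; ky < 3; ++ky) {
              const int sh = h + ky - 1;
              if (sh < 0 || sh >= H) continue;
              const double v = col[sh];
              const double *kf = kp + (R_xlen_t)F * (ky + 3 * kx + 9 * c);
              for (int f = 0; f < F; ++f) acc[f] += v * kf[f];
            }
          }
        }
        const R_xlen_t r = obase + h;
        for (int f = 0; f < F; ++f) op[r + (R_xlen_t)f * rows] = acc[f];
      }
    }
  }
  return out;
}

// Kernel gradient of the direct 3x3 convolution: dK[j, f] with the same
// j layout as the im2col columns. One pass over X and dA, accumulating
// into a small local buffer (intended for the first module, where
// 9*C*F is tiny).
// [[Rcpp::export]]
NumericMatrix cpp_conv3_dk(NumericMatrix x, NumericMatrix dA, int H,
                           int W, int N) {
  const int C = x.ncol();
  const int F = dA.ncol();
  const R_xlen_t rows = x.nrow();
  NumericMatrix dK(9 * C, F);
  const double *xp = x.begin();
  const double *dp = dA.begin();
  std::vector<double> local((size_t)9 * C * F, 0.0);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base = (R_xlen_t)n * H * W;
    for (int w = 0; w < W; ++w) {
      const R_xlen_t cbase = base + (R_xlen_t)w * H;
      for (int h = 0; h < H; ++h) {
        const double *dr = dp + cbase + h;   // dA row, strided by rows
        for (int c = 0; c < C; ++c) {
          const double *plane = xp + (R_xlen_t)c * rows + base;
          for (int kx = 0; kx < 3; ++kx) {
            const int sw = w + kx - 1;
            if (sw < 0 || sw >= W) continue;
            const double *col = plane + (R_xlen_t)sw * H;
            for (int ky = 0; ky < 3; ++ky) {
              const int sh = h + ky - 1;
              if (sh < 0 || sh >= H) continue;
              const double v = col[sh];
              double *lj = &local[(size_t)(ky + 3 * kx + 9 * c) * F];
              for (int f = 0; f < F; ++f)
                lj[f] += v * dr[(R_xlen_t)f * rows];
            }
          }
        }
      }
    }
  }
  double *gp = dK.begin();
  for (int j = 0; j < 9 * C; ++j)
    for (int f = 0; f < F; ++f)
      gp[j + (R_xlen_t)9 * C * f] = local[(size_t)j * F + f];
  return dK;
}

// Rejection placement of nuclei with a spatial hash. Draws candidate
// positions from R's RNG (so layouts are seed-reproducible), rejects
// candidates whose disc overlaps an existing nucleus by more than
// maxOverlap of the smaller disc (lens area), and accepts the last
// candidate after maxTries attempts. Returns an n x 2 matrix of (y, x).
// [[Rcpp::export]]
NumericMatrix cpp_place_nuclei(NumericVector radii, double fov,
                               double maxOverlap, int maxTries) {
  const int n = radii.size();
  NumericMatrix out(n, 2);
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  const double bin = std::max(2.0 * rmax, 1.0);
  const int nb = std::max(1, (int)std::ceil(fov / bin));
  std::vector<std::vector<int>> grid((size_t)nb * nb);
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    const double r = radii[i];
    double lo = r + 1, hi = fov - r;
    if (hi <= lo) { lo = fov / 2; hi = fov / 2; }
    double y = 0, x = 0;
    for (int t = 0; t < maxTries; ++t) {
      y = lo + unif_rand() * (hi - lo);
      x = lo + unif_rand() * (hi - lo);
      const int by = std::min(nb - 1, std::max(0, (int)(y / bin)));
      const int bx = std::min(nb - 1, std::max(0, (int)(x / bin)));
      bool ok = true;
      for (int dy = -1; dy <= 1 && ok; ++dy) {
        for (int dx = -1; dx <= 1 && ok; ++dx) {
          const int gy = by + dy, gx = bx + dx;
          if (gy < 0 || gy >= nb || gx < 0 || gx >= nb) continue;
          for (int j : grid[(size_t)gx * nb + gy]) {
            const double d = std::sqrt((out(j, 0) - y) * (out(j, 0) - y) +
                                       (out(j, 1) - x) * (out(j, 1) - x));
            const double rs = std::min(r, radii[j]);
            const double rl = std::max(r, radii[j]);
            double frac;
            if (d >= r + radii[j]) {
              frac = 0.0;
            } else if (d <= rl - rs) {
              frac = 1.0;
            } else {
              const double d1 = (d * d - rs * rs + rl * rl) / (2 * d);
              const double d2 = d - d1;
              const double c1 = std::min(1.0, std::max(-1.0, d1 / rl));
              const double c2 = std::min(1.0, std::max(-1.0, d2 / rs));
              const double lens =
                rl * rl * std::acos(c1) -
                d1 * std::sqrt(std::max(0.0, rl * rl - d1 * d1)) +
                rs * rs * std::acos(c2) -
                d2 * std::sqrt(std::max(0.0, rs * rs - d2 * d2));
              frac = lens / (M_PI * rs * rs);
            }
            if (frac > maxOverlap) { ok = false; break; }
          }
        }
      }
      if (ok || t == maxTries - 1) break;
    }
    out(i, 0) = y;
    out(i, 1) = x;
    const int by = std::min(nb - 1, std::max(0, (int)(y / bin)));
    const int bx = std::min(nb - 1, std::max(0, (int)(x / bin)));
    grid[(size_t)bx * nb + by].push_back(i);
  }
  PutRNGstate();
  return out;
}
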