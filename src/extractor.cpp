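// Single-precision feature-extractor engine.
//
// The conv/ReLU/batch-norm/max-pool stack runs entirely in C++ on float
// matrices in the (H*W*N) x C layout (row r = h + H*w + H*W*n): master
// weights stay double on the R side, activations and their gradients are
// single precision, which halves memory traffic and uses sgemm. The
// double-precision R path computes identical quantities up to float
// rounding; the test suite checks the two against each other and against
// finite differences.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <malloc.h>
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::uword;

static const float BN_EPS_F = 1e-5f;

struct ModCache {
  fmat X;                 // module input
  fmat Ar;                // post-ReLU pre-norm activations
  frowvec mu, invstd;     // batch statistics used
  std::vector<unsigned> idx;  // max locations (pre-pool linear index)
  int side;               // input side
};

struct ExtCache {
  std::vector<ModCache> mods;
  int N;
};

// 'same' 3x3 direct convolution, blocked by image column.
static fmat conv3_direct(const fmat &x, int H, int W, int N,
                         const fmat &Wk /* (9C) x F */) {
  const int C = x.n_cols;
  const int F = Wk.n_cols;
  const uword rows = x.n_rows;
  fmat out(rows, F);
  // transpose kernel for f-contiguous access
  fmat kt = Wk.t();        // F x (9C)
  std::vector<float> acc(F);
  const float *kp = kt.memptr();
  float *op = out.memptr();
  const float *xp = x.memptr();
  for (int n = 0; n < N; ++n) {
    const uword ibase = (uword)n * H * W;
    for (int w = 0; w < W; ++w) {
      const uword obase = ibase + (uword)w * H;
      const bool wEdge = (w == 0 || w == W - 1);
      const int h0 = wEdge ? 0 : 1;
      const int h1 = wEdge ? H : H - 1;
      if (!wEdge) {
        // branch-free interior of the column
        for (int h = 1; h < H - 1; ++h) {
          for (int f = 0; f < F; ++f) acc[f] = 0.0f;
          for (int c = 0; c < C; ++c) {
            const float *plane = xp + (uword)c * rows + ibase;
            for (int kx = 0; kx < 3; ++kx) {
              const float *col = plane + (uword)(w + kx - 1) * H + h - 1;
              for (int ky = 0; ky < 3; ++ky) {
                const float v = col[ky];
                const float *kf = kp + (uword)F * (ky + 3 * kx + 9 * c);
                for (int f = 0; f < F; ++f) acc[f] += v * kf[f];
              }
            }
          }
          const uword r = obase + h;
          for (int f = 0; f < F; ++f) op[r + (uword)f * rows] = acc[f];
        }
      }
      // border pixels (h = 0, h = H-1, and whole first/last columns)
      for (int h = (wEdge ? 0 : 0); h < H; ++h) {
        if (!wEdge && h != 0 && h != H - 1) continue;
        for (int f = 0; f < F; ++f) acc[f] = 0.0f;
        for (int c = 0; c < C; ++c) {
          const float *plane = xp + (uword)c * rows + ibase;
          for (int kx = 0; kx < 3; ++kx) {
            const int sw = w + kx - 1;
            if (sw < 0 || sw >= W) continue;
            const float *col = plane + (uword)sw * H;
            for (int ky = 0; ky < 3; ++ky) {
              const int sh = h + ky - 1;
              if (sh < 0 || sh >= H) continue;
              const float v = col[sh];
              const float *kf = kp + (uword)F * (ky + 3 * kx + 9 * c);
              for (int f = 0; f < F; ++f) acc[f] += v * kf[f];
            }
          }
        }
        const uword r = obase + h;
        for (int f = 0; f < F; ++f) op[r + (uword)f * rows] = acc[f];
      }
      (void)h0; (void)h1;
    }
  }
  return out;
}

// dK for the direct conv: one pass over X and dA, local accumulator.
static fmat conv3_direct_dk(const fmat &x, const fmat &dA, int H, int W,
                            int N) {
  const int C = x.n_cols;
  const int F = dA.n_cols;
  const uword rows = x.n_rows;
  std::vector<double> local((size_t)9 * C * F, 0.0);
  const float *xp = x.memptr();
  const float *dp = dA.memptr();
  for (int n = 0; n < N; ++n) {
    const uword base = (uword)n * H * W;
    for (int w = 0; w < W; ++w) {
      const uword cbase = base + (uword)w * H;
      const bool wEdge = (w == 0 || w == W - 1);
      for (int h = 0; h < H; ++h) {
        const float *dr = dp + cbase + h;
        const bool edge = wEdge || h == 0 || h == H - 1;
        if (!edge) {
          for (int c = 0; c < C; ++c) {
            const float *plane = xp + (uword)c * rows + base;
            for (int kx = 0; kx < 3; ++kx) {
              const float *col = plane + (uword)(w + kx - 1) * H + h - 1;
              for (int ky = 0; ky < 3; ++ky) {
                const double v = col[ky];
                double *lj = &local[(size_t)(ky + 3 * kx + 9 * c) * F];
                for (int f = 0; f < F; ++f)
                  lj[f] += v * dr[(uword)f * rows];
              }
            }
          }
          continue;
        }
        for (int c = 0; c < C; ++c) {
          const float *plane = xp + (uword)c * rows + base;
          for (int kx = 0; kx < 3; ++kx) {
            const int sw = w + kx - 1;
            if (sw < 0 || sw >= W) continue;
            const float *col = plane + (uword)sw * H;
            for (int ky = 0; ky < 3; ++ky) {
              const int sh = h + ky - 1;
              if (sh < 0 || sh >= H) continue;
              const double v = col[sh];
              double *lj = &local[(size_t)(ky + 3 * kx + 9 * c) * F];
              for (int f = 0; f < F; ++f)
                lj[f] += v * dr[(uword)f * rows];
            }
          }
        }
      }
    }
  }
  fmat dK(9 * C, F);
  for (int j = 0; j < 9 * C; ++j)
    for (int f = 0; f < F; ++f)
      dK(j, f) = (float)local[(size_t)j * F + f];
  return dK;
}

// float im2col for items n0..n1 (0-based, inclusive), k = 3 only.
static fmat im2colf(const fmat &x, int H, int W, int n0, int n1) {
  const int C = x.n_cols;
  const int nItems = n1 - n0 + 1;
  const uword rows = (uword)H * W * nItems;
  fmat out(rows, 9 * C);
  const float *xp = x.memptr();
  const uword xrows = x.n_rows;
  float *op = out.memptr();
  for (int c = 0; c < C; ++c) {
    const float *plane = xp + (uword)c * xrows;
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        const int j = ky + 3 * kx + 9 * c;
        float *col = op + (uword)j * rows;
        uword r = 0;
        for (int n = n0; n <= n1; ++n) {
          const float *item = plane + (uword)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + kx - 1;
            if (sw < 0 || sw >= W) {
              for (int h = 0; h < H; ++h, ++r) col[r] = 0.0f;
              continue;
            }
            const float *src = item + (uword)sw * H;
            for (int h = 0; h < H; ++h, ++r) {
              const int sh = h + ky - 1;
              col[r] = (sh >= 0 && sh < H) ? src[sh] : 0.0f;
            }
          }
        }
      }
    }
  }
  return out;
}

// adjoint scatter of the float im2col
static void col2imf_add(const fmat &cols, int H, int W, int n0, int n1,
                        fmat &dX) {
  const int C = dX.n_cols;
  const uword rows = cols.n_rows;
  const float *cp = cols.memptr();
  float *xp = dX.memptr();
  const uword xrows = dX.n_rows;
  for (int c = 0; c < C; ++c) {
    float *plane = xp + (uword)c * xrows;
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        const int j = ky + 3 * kx + 9 * c;
        const float *col = cp + (uword)j * rows;
        uword r = 0;
        for (int n = n0; n <= n1; ++n) {
          float *item = plane + (uword)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + kx - 1;
            if (sw < 0 || sw >= W) { r += H; continue; }
            float *dst = item + (uword)sw * H;
            for (int h = 0; h < H; ++h, ++r) {
              const int sh = h + ky - 1;
              if (sh >= 0 && sh < H) dst[sh] += col[r];
            }
          }
        }
      }
    }
  }
}

// item chunking keeping each im2col float buffer under ~240 MB
static int chunkItems(int H, int W, int C) {
  const double perItem = (double)H * W * 9.0 * C;
  int chunk = (int)(6e7 / perItem);
  return chunk < 1 ? 1 : chunk;
}

static fmat convForwardF(const fmat &X, int H, int W, int N,
                         const fmat &Wk) {
  if (X.n_cols <= 3) return conv3_direct(X, H, W, N, Wk);
  fmat out(X.n_rows, Wk.n_cols);
  const int chunk = chunkItems(H, W, X.n_cols);
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N - 1, s + chunk - 1);
    fmat cols = im2colf(X, H, W, s, e);
    out.rows((uword)s * H * W, (uword)(e + 1) * H * W - 1) = cols * Wk;
  }
  return out;
}

// 2x2 max pool on the matrix layout; records max locations.
static fmat maxpoolF(const fmat &Y, int H, int W, int N,
                     std::vector<unsigned> &idx) {
  const int F = Y.n_cols;
  const int Ho = H / 2, Wo = W / 2;
  const uword inRows = Y.n_rows;
  const uword outRows = (uword)Ho * Wo * N;
  fmat out(outRows, F);
  idx.resize(outRows * F);
  const float *yp = Y.memptr();
  float *op = out.memptr();
  unsigned *ip = idx.data();
  for (int f = 0; f < F; ++f) {
    const float *col = yp + (uword)f * inRows;
    float *oc = op + (uword)f * outRows;
    uword *ic = ip + (uword)f * outRows;
    uword o = 0;
    for (int n = 0; n < N; ++n) {
      const uword base = (uword)n * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          uword best = base + (uword)(2 * wo) * H + 2 * ho;
          float bv = col[best];
          const uword cand[3] = { best + 1, best + (uword)H,
                                  best + (uword)H + 1 };
          for (int t = 0; t < 3; ++t)
            if (col[cand[t]] > bv) { bv = col[cand[t]]; best = cand[t]; }
          oc[o] = bv;
          ic[o] = (unsigned)((uword)f * inRows + best);
        }
      }
    }
  }
  return out;
}


// Fused batch-norm affine + 2x2 max pool: pools y = slope*a + shift per
// channel without materialising y. For negative slopes the maximum of y
// sits at the minimum of a, so selection is sign-aware and exact.
static fmat bnPoolFused(const fmat &A, const frowvec &mu,
                        const frowvec &invstd, const frowvec &gamma,
                        const frowvec &beta, int H, int W, int N,
                        std::vector<unsigned> &idx) {
  const int F = A.n_cols;
  const int Ho = H / 2, Wo = W / 2;
  const uword inRows = A.n_rows;
  const uword outRows = (uword)Ho * Wo * N;
  fmat out(outRows, F);
  idx.resize(outRows * F);
  const float *ap = A.memptr();
  float *op = out.memptr();
  unsigned *ip = idx.data();
  for (int f = 0; f < F; ++f) {
    const float slope = gamma[f] * invstd[f];
    const float shift = beta[f] - slope * mu[f];
    const bool pos = slope >= 0.0f;
    const float *col = ap + (uword)f * inRows;
    float *oc = op + (uword)f * outRows;
    unsigned *ic = ip + (uword)f * outRows;
    uword o = 0;
    for (int n = 0; n < N; ++n) {
      const uword base = (uword)n * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          uword best = base + (uword)(2 * wo) * H + 2 * ho;
          float bv = col[best];
          const uword cand[3] = { best + 1, best + (uword)H,
                                  best + (uword)H + 1 };
          if (pos) {
            for (int t = 0; t < 3; ++t)
              if (col[cand[t]] > bv) { bv = col[cand[t]]; best = cand[t]; }
          } else {
            for (int t = 0; t < 3; ++t)
              if (col[cand[t]] < bv) { bv = col[cand[t]]; best = cand[t]; }
          }
          oc[o] = slope * bv + shift;
          ic[o] = (unsigned)((uword)f * inRows + best);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ext_forward(List mods, NumericMatrix Xm, int side, int N,
                     bool training) {
  const int M = mods.size();
  fmat X = arma::conv_to<fmat>::from(
    arma::mat(Xm.begin(), Xm.nrow(), Xm.ncol(), false));
  Rcpp::XPtr<ExtCache> cache(new ExtCache(), true);
  cache->mods.resize(M);
  cache->N = N;
  List stats(M);
  int H = side;
  for (int m = 0; m < M; ++m) {
    List mod = mods[m];
    fmat Wk = arma::conv_to<fmat>::from(as<arma::mat>(mod["W"]));
    frowvec b = arma::conv_to<frowvec>::from(
      as<arma::rowvec>(mod["b"]));
    frowvec gamma = arma::conv_to<frowvec>::from(
      as<arma::rowvec>(mod["gamma"]));
    frowvec beta = arma::conv_to<frowvec>::from(
      as<arma::rowvec>(mod["beta"]));
    fmat A = convForwardF(X, H, H, N, Wk);
    // fused bias + ReLU in place
    for (uword f = 0; f < A.n_cols; ++f) {
      float *col = A.colptr(f);
      const float bf = b[f];
      const uword nr = A.n_rows;
      for (uword r = 0; r < nr; ++r) {
        const float v = col[r] + bf;
        col[r] = v > 0.0f ? v : 0.0f;
      }
    }
    frowvec mu, var;
    if (training) {
      mu.set_size(A.n_cols);
      var.set_size(A.n_cols);
      for (uword f = 0; f < A.n_cols; ++f) {
        // accumulate in double: column lengths reach 1e7
        const float *col = A.colptr(f);
        double s = 0, s2 = 0;
        const uword nr = A.n_rows;
        for (uword r = 0; r < nr; ++r) { s += col[r]; s2 += col[r] * col[r]; }
        const double m_ = s / nr;
        double v_ = s2 / nr - m_ * m_;
        if (v_ < 0) v_ = 0;
        mu[f] = (float)m_;
        var[f] = (float)v_;
      }
      stats[m] = List::create(_["mean"] = NumericVector(mu.begin(), mu.end()),
                              _["var"] = NumericVector(var.begin(), var.end()));
    } else {
      mu = arma::conv_to<frowvec>::from(as<arma::rowvec>(mod["rm"]));
      var = arma::conv_to<frowvec>::from(as<arma::rowvec>(mod["rv"]));
    }
    frowvec invstd = 1.0f / arma::sqrt(var + BN_EPS_F);
    ModCache &cc = cache->mods[m];
    cc.side = H;
    cc.mu = mu;
    cc.invstd = invstd;
    std::vector<unsigned> idx;
    fmat P = bnPoolFused(A, mu, invstd, gamma, beta, H, H, N, idx);
    if (training) {
      cc.X = std::move(X);
      cc.Ar = std::move(A);
      cc.idx = std::move(idx);
    }
    X = std::move(P);
    H /= 2;
  }
  NumericMatrix out(X.n_rows, X.n_cols);
  std::copy(X.begin(), X.end(), out.begin());
  return List::create(_["out"] = out, _["cache"] = cache,
                      _["stats"] = stats);
}

// [[Rcpp::export]]
List cpp_ext_backward(List mods, SEXP cachePtr, NumericMatrix dOut) {
  Rcpp::XPtr<ExtCache> cache(cachePtr);
  const int M = mods.size();
  const int N = cache->N;
  fmat dP = arma::conv_to<fmat>::from(
    arma::mat(dOut.begin(), dOut.nrow(), dOut.ncol(), false));
  List grads(M);
  for (int m = M - 1; m >= 0; --m) {
    List mod = mods[m];
    fmat Wk = arma::conv_to<fmat>::from(as<arma::mat>(mod["W"]));
    frowvec gamma = arma::conv_to<frowvec>::from(
      as<arma::rowvec>(mod["gamma"]));
    ModCache &cc = cache->mods[m];
    const int H = cc.side;
    const uword inRows = (uword)H * H * N;
    const uword nr = inRows;
    const int F = dP.n_cols;
    const uword poolRows = dP.n_rows;
    // batch-norm + pool backward without materialising the dense pool
    // gradient: the reductions run over the sparse pooled entries (all
    // other positions carry zero), then dA is filled with the dense
    // -c1 - xhat*c2 term and the sparse dP contributions are scattered
    // on top, with the ReLU gate applied throughout.
    arma::rowvec dgamma(F), dbeta(F);
    fmat dA(nr, F);
    for (int f = 0; f < F; ++f) {
      const float m_ = cc.mu[f], is = cc.invstd[f], g = gamma[f];
      const float *pc = dP.colptr(f);
      const unsigned *ic = cc.idx.data() + (uword)f * poolRows;
      const float *ac = cc.Ar.colptr(f);
      double s1 = 0, s2 = 0;
      for (uword i = 0; i < poolRows; ++i) {
        const float av = cc.Ar.memptr()[ic[i]];
        s1 += pc[i];
        s2 += pc[i] * (double)((av - m_) * is);
      }
      dbeta[f] = s1;
      dgamma[f] = s2;
      const float c1 = (float)(s1 / nr), c2 = (float)(s2 / nr);
      const float gis = g * is;
      float *xc = dA.colptr(f);
      for (uword r = 0; r < nr; ++r) {
        const float av = ac[r];
        xc[r] = av > 0.0f ? -gis * (c1 + (av - m_) * is * c2) : 0.0f;
      }
      const float *arAll = cc.Ar.memptr();
      float *daAll = dA.memptr();
      for (uword i = 0; i < poolRows; ++i) {
        const uword t = ic[i];
        if (arAll[t] > 0.0f)
          daAll[t] += gis * pc[i];
      }
    }
    // convolution backward
    fmat dK;
    arma::rowvec db(F);
    for (int f = 0; f < F; ++f) {
      const float *col = dA.colptr(f);
      double s = 0;
      for (uword r = 0; r < nr; ++r) s += col[r];
      db[f] = s;
    }
    const bool needDX = m > 0;
    fmat dX;
    if (cc.X.n_cols <= 3 && !needDX) {
      dK = conv3_direct_dk(cc.X, dA, H, H, N);
    } else {
      dK.zeros(9 * cc.X.n_cols, F);
      if (needDX) dX.zeros(cc.X.n_rows, cc.X.n_cols);
      fmat WkT = Wk.t();
      const int chunk = chunkItems(H, H, cc.X.n_cols);
      for (int s = 0; s < N; s += chunk) {
        const int e = std::min(N - 1, s + chunk - 1);
        fmat cols = im2colf(cc.X, H, H, s, e);
        fmat dAc = dA.rows((uword)s * H * H, (uword)(e + 1) * H * H - 1);
        dK += cols.t() * dAc;
        if (needDX) {
          fmat dCols = dAc * WkT;
          col2imf_add(dCols, H, H, s, e, dX);
        }
      }
    }
    grads[m] = List::create(
      _["W"] = wrap(arma::conv_to<arma::mat>::from(dK)),
      _["b"] = NumericVector(db.begin(), db.end()),
      _["gamma"] = NumericVector(dgamma.begin(), dgamma.end()),
      _["beta"] = NumericVector(dbeta.begin(), dbeta.end()));
    cc.X.reset();
    cc.Ar.reset();
    if (needDX) dP = std::move(dX);
  }
  return grads;
}


// Large Armadillo temporaries otherwise go through mmap/munmap on every
// call, and first-touch page faulting dominates runtime on slow-memory
// machines. Keeping big allocations on the heap lets freed buffers be
// reused across batches. Called once at package load.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef M_MMAP_MAX
  mallopt(M_MMAP_MAX, 0);
  mallopt(M_TRIM_THRESHOLD, -1);
#endif
}
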