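// Low-level numerical kernels: 3-D convolution (im2col + BLAS gemm),
// max-pooling, strided transposed convolution, affine grid resampling and
// brute-force nearest-surface distances. Tensors cross the R boundary as
// double vectors with dim (X, Y, Z, C, N) -- X fastest, matching R arrays;
// arithmetic runs in single precision, which is ample for network training
// and keeps the im2col buffers small.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;

static inline void to_float(const double* src, float* dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
}

// Fill one column block of the transposed im2col matrix colT (cols x K) for a
// single sample. Sample layout: channel-major planes, voxel v = x + X*(y + Y*z).
// Row/column r of the patch dimension indexes (c, kx, ky, kz) with
// r = c*27 + (kx+1) + 3*((ky+1) + 3*(kz+1)); kernel 3x3x3, pad 1, stride 1.
static void im2col_block(const float* xs, int X, int Y, int Z, int C,
                         int z0, int zb, fmat& colT) {
  const size_t XY = (size_t)X * Y;
  const size_t V = XY * Z;
  for (int c = 0; c < C; ++c) {
    const float* xc = xs + (size_t)c * V;
    for (int kz = -1; kz <= 1; ++kz) {
      for (int ky = -1; ky <= 1; ++ky) {
        for (int kx = -1; kx <= 1; ++kx) {
          const int r = c * 27 + (kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1));
          float* dst0 = colT.colptr(r);
          for (int z = z0; z < z0 + zb; ++z) {
            const int sz = z + kz;
            for (int y = 0; y < Y; ++y) {
              float* dst = dst0 + ((size_t)(z - z0) * Y + y) * X;
              const int sy = y + ky;
              if (sz < 0 || sz >= Z || sy < 0 || sy >= Y) {
                std::memset(dst, 0, sizeof(float) * X);
                continue;
              }
              const float* src = xc + XY * sz + (size_t)X * sy;
              if (kx == 0) {
                std::memcpy(dst, src, sizeof(float) * X);
              } else if (kx == 1) {
                std::memcpy(dst, src + 1, sizeof(float) * (X - 1));
                dst[X - 1] = 0.0f;
              } else {
                dst[0] = 0.0f;
                std::memcpy(dst + 1, src, sizeof(float) * (X - 1));
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the gradient held in dcolT (cols x K) back onto the input
// gradient buffer of one sample (inverse of im2col_block).
static void col2im_block(float* dxs, int X, int Y, int Z, int C,
                         int z0, int zb, const fmat& dcolT) {
  const size_t XY = (size_t)X * Y;
  const size_t V = XY * Z;
  for (int c = 0; c < C; ++c) {
    float* xc = dxs + (size_t)c * V;
    for (int kz = -1; kz <= 1; ++kz) {
      for (int ky = -1; ky <= 1; ++ky) {
        for (int kx = -1; kx <= 1; ++kx) {
          const int r = c * 27 + (kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1));
          const float* src0 = dcolT.colptr(r);
          for (int z = z0; z < z0 + zb; ++z) {
            const int sz = z + kz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + ky;
              if (sy < 0 || sy >= Y) continue;
              const float* src = src0 + ((size_t)(z - z0) * Y + y) * X;
              float* dst = xc + XY * sz + (size_t)X * sy;
              if (kx == 0) {
                for (int x = 0; x < X; ++x) dst[x] += src[x];
              } else if (kx == 1) {
                for (int x = 0; x < X - 1; ++x) dst[x + 1] += src[x];
              } else {
                for (int x = 1; x < X; ++x) dst[x - 1] += src[x];
              }
            }
          }
        }
      }
    }
  }
}

static int slab_height(int X, int Y, int Z) {
  const size_t target = 65536;  // ~ columns per gemm block
  size_t XY = (size_t)X * Y;
  int zb = (int)std::max((size_t)1, target / std::max(XY, (size_t)1));
  return std::min(zb, Z);
}

// Persistent scratch buffers: repeated mallocs of tens of MB per gemm call
// (and the page faults that come with them) would otherwise dominate the
// cost of small-filter convolutions.
static std::vector<float>& scratch(int which, size_t n) {
  static std::vector<float> bufs[4];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

// [[Rcpp::export]]
NumericVector conv3_fwd(NumericVector x, IntegerVector xdim,
                        NumericMatrix Wt, NumericVector b) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int K = C * 27, Cout = Wt.ncol();
  if (Wt.nrow() != K) stop("conv3_fwd: weight rows != C*27");
  const size_t V = (size_t)X * Y * Z;
  NumericVector y((R_xlen_t)V * Cout * N);
  fmat Wtf(K, Cout);
  to_float(Wt.begin(), Wtf.memptr(), (size_t)K * Cout);
  arma::fvec bf(Cout);
  to_float(b.begin(), bf.memptr(), Cout);

  const int zb0 = slab_height(X, Y, Z);
  const size_t maxcols = (size_t)X * Y * zb0;
  std::vector<float>& xs = scratch(0, V * C);
  std::vector<float>& colbuf = scratch(1, maxcols * K);
  std::vector<float>& y2buf = scratch(2, maxcols * Cout);
  for (int n = 0; n < N; ++n) {
    to_float(&x[0] + (size_t)n * V * C, xs.data(), V * C);
    for (int z0 = 0; z0 < Z; z0 += zb0) {
      const int zb = std::min(zb0, Z - z0);
      const size_t cols = (size_t)X * Y * zb;
      fmat colT(colbuf.data(), cols, K, false, true);
      im2col_block(xs.data(), X, Y, Z, C, z0, zb, colT);
      fmat Y2(y2buf.data(), cols, Cout, false, true);
      Y2 = colT * Wtf;  // cols x Cout
      for (int co = 0; co < Cout; ++co) {
        const float* src = Y2.colptr(co);
        double* dst = &y[0] + (size_t)n * V * Cout + (size_t)co * V +
                      (size_t)X * Y * z0;
        const float bb = bf[co];
        for (size_t i = 0; i < cols; ++i) dst[i] = (double)(src[i] + bb);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3_bwd(NumericVector x, IntegerVector xdim,
               NumericMatrix Wt, NumericVector dy) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int K = C * 27, Cout = Wt.ncol();
  const size_t V = (size_t)X * Y * Z;
  fmat Wtf(K, Cout);
  to_float(Wt.begin(), Wtf.memptr(), (size_t)K * Cout);
  // transposed, spatially flipped weights: the input gradient is the
  // full correlation of dy with the flipped kernels, i.e. another conv
  const int K2 = Cout * 27;
  fmat W2f(K2, C);
  for (int ci = 0; ci < C; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int r = 0; r < 27; ++r)
        W2f(co * 27 + (26 - r), ci) = Wtf(ci * 27 + r, co);

  fmat dWt(K, Cout, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)V * C * N);

  const int zb0 = slab_height(X, Y, Z);
  const size_t maxcols = (size_t)X * Y * zb0;
  std::vector<float>& xs = scratch(0, V * C + V * Cout);
  float* dys = xs.data() + V * C;
  std::vector<float>& colbuf = scratch(1, maxcols * std::max(K, K2));
  std::vector<float>& gbuf = scratch(2, maxcols * std::max(Cout, C));
  for (int n = 0; n < N; ++n) {
    to_float(&x[0] + (size_t)n * V * C, xs.data(), V * C);
    to_float(&dy[0] + (size_t)n * V * Cout, dys, V * Cout);
    for (int z0 = 0; z0 < Z; z0 += zb0) {
      const int zb = std::min(zb0, Z - z0);
      const size_t cols = (size_t)X * Y * zb;
      // weight/bias gradients from the im2col of the input
      fmat colT(colbuf.data(), cols, K, false, true);
      im2col_block(xs.data(), X, Y, Z, C, z0, zb, colT);
      fmat G(gbuf.data(), cols, Cout, false, true);
      for (int co = 0; co < Cout; ++co) {
        std::memcpy(G.colptr(co), dys + (size_t)co * V + (size_t)X * Y * z0,
                    sizeof(float) * cols);
      }
      dWt += colT.t() * G;
      db += arma::sum(G, 0).t();
    }
    for (int z0 = 0; z0 < Z; z0 += zb0) {
      const int zb = std::min(zb0, Z - z0);
      const size_t cols = (size_t)X * Y * zb;
      // input gradient via the transposed-filter convolution of dy
      fmat colT2(colbuf.data(), cols, K2, false, true);
      im2col_block(dys, X, Y, Z, Cout, z0, zb, colT2);
      fmat DX(gbuf.data(), cols, C, false, true);
      DX = colT2 * W2f;
      for (int ci = 0; ci < C; ++ci) {
        double* dst = &dx[0] + (size_t)n * V * C + (size_t)ci * V +
                      (size_t)X * Y * z0;
        const float* src = DX.colptr(ci);
        for (size_t i = 0; i < cols; ++i) dst[i] = (double)src[i];
      }
    }
  }

  NumericMatrix dWt_r(K, Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) dWt_r[i] = dWt.memptr()[i];
  NumericVector db_r(Cout);
  for (int i = 0; i < Cout; ++i) db_r[i] = db[i];
  return List::create(_["dx"] = dx, _["dW"] = dWt_r, _["db"] = db_r);
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool_fwd: odd spatial extent");
  const int X2 = X / 2, Y2 = Y / 2, Z2 = Z / 2;
  const size_t V = (size_t)X * Y * Z, V2 = (size_t)X2 * Y2 * Z2;
  NumericVector y((R_xlen_t)V2 * C * N);
  IntegerVector idx((R_xlen_t)V2 * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[0] + ((size_t)n * C + c) * V;
      double* yc = &y[0] + ((size_t)n * C + c) * V2;
      int* ic = &idx[0] + ((size_t)n * C + c) * V2;
      for (int z = 0; z < Z2; ++z)
        for (int yy = 0; yy < Y2; ++yy)
          for (int xx = 0; xx < X2; ++xx) {
            double best = -HUGE_VAL;
            int barg = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dyy = 0; dyy < 2; ++dyy)
                for (int dxx = 0; dxx < 2; ++dxx) {
                  const int sx = 2 * xx + dxx, sy = 2 * yy + dyy,
                            sz = 2 * z + dz;
                  const int si = sx + X * (sy + Y * sz);
                  if (xc[si] > best) { best = xc[si]; barg = si; }
                }
            const int oi = xx + X2 * (yy + Y2 * z);
            yc[oi] = best;
            ic[oi] = barg;
          }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector idx,
                          IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int X2 = X / 2, Y2 = Y / 2, Z2 = Z / 2;
  const size_t V = (size_t)X * Y * Z, V2 = (size_t)X2 * Y2 * Z2;
  NumericVector dx((R_xlen_t)V * C * N);
  for (size_t j = 0; j < (size_t)C * N; ++j) {
    const double* dyc = &dy[0] + j * V2;
    const int* ic = &idx[0] + j * V2;
    double* dxc = &dx[0] + j * V;
    for (size_t i = 0; i < V2; ++i) dxc[ic[i]] += dyc[i];
  }
  return dx;
}

// Transposed convolution, kernel 2x2x2, stride 2, no padding.
// Weights Wt: C x (Cout*8); octant o = i + 2*j + 4*k.
// [[Rcpp::export]]
NumericVector upconv_fwd(NumericVector x, IntegerVector xdim,
                         NumericMatrix Wt, NumericVector b) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int Cout = Wt.ncol() / 8;
  if (Wt.nrow() != C) stop("upconv_fwd: weight rows != C");
  const size_t V = (size_t)X * Y * Z;
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  const size_t V2 = (size_t)X2 * Y2 * Z2;
  fmat Wtf(C, Cout * 8);
  to_float(Wt.begin(), Wtf.memptr(), (size_t)C * Cout * 8);
  NumericVector y((R_xlen_t)V2 * Cout * N);
  fmat A(V, C);
  for (int n = 0; n < N; ++n) {
    to_float(&x[0] + (size_t)n * V * C, A.memptr(), V * C);
    fmat Y2m = A * Wtf;  // V x (Cout*8)
    for (int co = 0; co < Cout; ++co) {
      double* yc = &y[0] + ((size_t)n * Cout + co) * V2;
      const double bb = b[co];
      for (int k = 0; k < 2; ++k)
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            const float* src = Y2m.colptr(co * 8 + (i + 2 * j + 4 * k));
            for (int z = 0; z < Z; ++z)
              for (int yy = 0; yy < Y; ++yy) {
                const float* s = src + ((size_t)z * Y + yy) * X;
                double* d = yc + (size_t)(2 * z + k) * X2 * Y2 +
                            (size_t)(2 * yy + j) * X2 + i;
                for (int xx = 0; xx < X; ++xx) d[2 * xx] = (double)s[xx] + bb;
              }
          }
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv_bwd(NumericVector x, IntegerVector xdim,
                NumericMatrix Wt, NumericVector dy) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const int Cout = Wt.ncol() / 8;
  const size_t V = (size_t)X * Y * Z;
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  const size_t V2 = (size_t)X2 * Y2 * Z2;
  fmat Wtf(C, Cout * 8);
  to_float(Wt.begin(), Wtf.memptr(), (size_t)C * Cout * 8);

  NumericVector dx((R_xlen_t)V * C * N);
  fmat dWt(C, Cout * 8, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  fmat A(V, C), G(V, Cout * 8);
  for (int n = 0; n < N; ++n) {
    to_float(&x[0] + (size_t)n * V * C, A.memptr(), V * C);
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = &dy[0] + ((size_t)n * Cout + co) * V2;
      for (int k = 0; k < 2; ++k)
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            float* dst = G.colptr(co * 8 + (i + 2 * j + 4 * k));
            for (int z = 0; z < Z; ++z)
              for (int yy = 0; yy < Y; ++yy) {
                float* d = dst + ((size_t)z * Y + yy) * X;
                const double* s = dyc + (size_t)(2 * z + k) * X2 * Y2 +
                                  (size_t)(2 * yy + j) * X2 + i;
                for (int xx = 0; xx < X; ++xx) d[xx] = (float)s[2 * xx];
              }
          }
      db[co] += arma::accu(G.cols(co * 8, co * 8 + 7));
    }
    dWt += A.t() * G;
    fmat dA = G * Wtf.t();  // V x C
    double* dst = &dx[0] + (size_t)n * V * C;
    const float* src = dA.memptr();
    for (size_t i = 0; i < V * C; ++i) dst[i] = (double)src[i];
  }
  NumericMatrix dWt_r(C, Cout * 8);
  for (size_t i = 0; i < (size_t)C * Cout * 8; ++i) dWt_r[i] = dWt.memptr()[i];
  NumericVector db_r(Cout);
  for (int i = 0; i < Cout; ++i) db_r[i] = db[i];
  return List::create(_["dx"] = dx, _["dW"] = dWt_r, _["db"] = db_r);
}

// Resample a 3-D volume onto a target grid. M maps 0-based target voxel
// indices to 0-based source voxel indices (homogeneous 4x4). Out-of-field
// voxels are filled with 0.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  NumericMatrix M, IntegerVector tdim,
                                  bool nearest) {
  const int SX = sdim[0], SY = sdim[1], SZ = sdim[2];
  const int TX = tdim[0], TY = tdim[1], TZ = tdim[2];
  NumericVector out((R_xlen_t)TX * TY * TZ);
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2), m03 = M(0, 3);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2), m13 = M(1, 3);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2), m23 = M(2, 3);
  const double* s = &src[0];
  size_t o = 0;
  for (int k = 0; k < TZ; ++k)
    for (int j = 0; j < TY; ++j)
      for (int i = 0; i < TX; ++i, ++o) {
        const double sx = m00 * i + m01 * j + m02 * k + m03;
        const double sy = m10 * i + m11 * j + m12 * k + m13;
        const double sz = m20 * i + m21 * j + m22 * k + m23;
        if (nearest) {
          const int xi = (int)std::lround(sx), yi = (int)std::lround(sy),
                    zi = (int)std::lround(sz);
          if (xi < 0 || xi >= SX || yi < 0 || yi >= SY || zi < 0 || zi >= SZ)
            continue;
          out[o] = s[xi + (size_t)SX * (yi + (size_t)SY * zi)];
        } else {
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                    z0 = (int)std::floor(sz);
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dyy = 0; dyy < 2; ++dyy)
              for (int dxx = 0; dxx < 2; ++dxx) {
                const int xi = x0 + dxx, yi = y0 + dyy, zi = z0 + dz;
                if (xi < 0 || xi >= SX || yi < 0 || yi >= SY || zi < 0 ||
                    zi >= SZ)
                  continue;
                const double w = (dxx ? fx : 1.0 - fx) *
                                 (dyy ? fy : 1.0 - fy) * (dz ? fz : 1.0 - fz);
                acc += w * s[xi + (size_t)SX * (yi + (size_t)SY * zi)];
              }
          out[o] = acc;
        }
      }
  return out;
}

// For each row of A (points, mm), the Euclidean distance to the nearest row
// of B. Brute force; point sets here are surface voxels or curve samples.
// [[Rcpp::export]]
NumericVector nn_min_dists(NumericMatrix A, NumericMatrix B) {
  const int nA = A.nrow(), nB = B.nrow();
  NumericVector out(nA);
  for (int i = 0; i < nA; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = HUGE_VAL;
    for (int j = 0; j < nB; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Fused batch-normalisation + ReLU. Statistics are per channel over all
// voxels and batch samples. The backward pass recomputes xhat from the
// saved pre-normalisation activations, so only the tiny per-channel
// statistics need to be cached between passes.
// [[Rcpp::export]]
List bnrelu_fwd(NumericVector x, IntegerVector xdim, NumericVector g,
                NumericVector be, NumericVector rm, NumericVector rv,
                bool training, double momentum, double eps) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const size_t V = (size_t)X * Y * Z;
  const double m = (double)V * N;
  NumericVector y((R_xlen_t)V * C * N);
  NumericVector mu(C), isd(C), rm_new(clone(rm)), rv_new(clone(rv));
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    if (training) {
      for (int n = 0; n < N; ++n) {
        const double* xc = &x[0] + ((size_t)n * C + c) * V;
        for (size_t i = 0; i < V; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      const double mean = s / m;
      const double var = s2 / m - mean * mean;
      mu[c] = mean;
      isd[c] = 1.0 / std::sqrt(var + eps);
      rm_new[c] = (1 - momentum) * rm[c] + momentum * mean;
      rv_new[c] = (1 - momentum) * rv[c] + momentum * var * m / (m - 1);
    } else {
      mu[c] = rm[c];
      isd[c] = 1.0 / std::sqrt(rv[c] + eps);
    }
    const double gc = g[c], bc = be[c], mc = mu[c], ic = isd[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = &x[0] + ((size_t)n * C + c) * V;
      double* yc = &y[0] + ((size_t)n * C + c) * V;
      for (size_t i = 0; i < V; ++i) {
        const double v = gc * (xc[i] - mc) * ic + bc;
        yc[i] = v > 0 ? v : 0.0;
      }
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["isd"] = isd,
                      _["rm"] = rm_new, _["rv"] = rv_new);
}

// [[Rcpp::export]]
List bnrelu_bwd(NumericVector x, IntegerVector xdim, NumericVector dy,
                NumericVector g, NumericVector be, NumericVector mu,
                NumericVector isd) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  const size_t V = (size_t)X * Y * Z;
  const double m = (double)V * N;
  NumericVector dx((R_xlen_t)V * C * N), dg(C), dbe(C);
  for (int c = 0; c < C; ++c) {
    const double gc = g[c], bc = be[c], mc = mu[c], ic = isd[c];
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = &x[0] + ((size_t)n * C + c) * V;
      const double* dyc = &dy[0] + ((size_t)n * C + c) * V;
      for (size_t i = 0; i < V; ++i) {
        const double xh = (xc[i] - mc) * ic;
        if (gc * xh + bc > 0) { sg += dyc[i] * xh; sb += dyc[i]; }
      }
    }
    dg[c] = sg;
    dbe[c] = sb;
    const double mg = sg / m, mb = sb / m, gi = gc * ic;
    for (int n = 0; n < N; ++n) {
      const double* xc = &x[0] + ((size_t)n * C + c) * V;
      const double* dyc = &dy[0] + ((size_t)n * C + c) * V;
      double* dxc = &dx[0] + ((size_t)n * C + c) * V;
      for (size_t i = 0; i < V; ++i) {
        const double xh = (xc[i] - mc) * ic;
        const double d = (gc * xh + bc > 0) ? dyc[i] : 0.0;
        dxc[i] = gi * (d - mb - xh * mg);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["dbe"] = dbe);
}
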