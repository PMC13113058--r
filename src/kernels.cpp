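#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are stored as L x C matrices: L = d1*d2*d3 voxel locations in
// column-major order (first axis fastest), one column per channel. This keeps
// batch-norm / ReLU as plain matrix ops on the R side and lets convolution be
// a single BLAS GEMM against the unrolled patch matrix produced here.

static inline int out_extent(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

// Unroll a (d1,d2,d3,C) feature map into an Lout x (C*k1*k2*k3) patch matrix.
// Column layout: channel-major, then kernel offset (first axis fastest).
// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& X, IntegerVector dims,
                      IntegerVector ksize, IntegerVector stride,
                      IntegerVector pad, int n_batch = 1) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int k1 = ksize[0], k2 = ksize[1], k3 = ksize[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int C = X.ncol();
  const int L = d1 * d2 * d3;
  if (X.nrow() != (R_xlen_t)L * n_batch)
    stop("im2col3: row count does not match dims");
  const int o1 = out_extent(d1, k1, s1, p1);
  const int o2 = out_extent(d2, k2, s2, p2);
  const int o3 = out_extent(d3, k3, s3, p3);
  const int Lout = o1 * o2 * o3, K = k1 * k2 * k3;
  NumericMatrix out((R_xlen_t)Lout * n_batch, C * K);
  for (int s = 0; s < n_batch; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &X((R_xlen_t)s * L, c);
      for (int kk = 0; kk < k3; ++kk)
        for (int kj = 0; kj < k2; ++kj)
          for (int ki = 0; ki < k1; ++ki) {
            const int koff = ki + kj * k1 + kk * k1 * k2;
            double* oc = &out((R_xlen_t)s * Lout, c * K + koff);
            int r = 0;
            for (int z = 0; z < o3; ++z) {
              const int iz = z * s3 - p3 + kk;
              const bool zok = iz >= 0 && iz < d3;
              for (int y = 0; y < o2; ++y) {
                const int iy = y * s2 - p2 + kj;
                const bool yok = zok && iy >= 0 && iy < d2;
                const int base = iy * d1 + iz * d1 * d2;
                for (int x = 0; x < o1; ++x, ++r) {
                  const int ix = x * s1 - p1 + ki;
                  oc[r] = (yok && ix >= 0 && ix < d1) ? xc[ix + base] : 0.0;
                }
              }
            }
          }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch-matrix gradients back onto the grid.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& cols, IntegerVector dims,
                      IntegerVector ksize, IntegerVector stride,
                      IntegerVector pad, int C, int n_batch = 1) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int k1 = ksize[0], k2 = ksize[1], k3 = ksize[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int o1 = out_extent(d1, k1, s1, p1);
  const int o2 = out_extent(d2, k2, s2, p2);
  const int o3 = out_extent(d3, k3, s3, p3);
  const int K = k1 * k2 * k3;
  const int Lout = o1 * o2 * o3;
  if (cols.ncol() != C * K) stop("col2im3: column count mismatch");
  NumericMatrix out((R_xlen_t)d1 * d2 * d3 * n_batch, C);
  for (int s = 0; s < n_batch; ++s) {
    for (int c = 0; c < C; ++c) {
      double* xc = &out((R_xlen_t)s * d1 * d2 * d3, c);
      for (int kk = 0; kk < k3; ++kk)
        for (int kj = 0; kj < k2; ++kj)
          for (int ki = 0; ki < k1; ++ki) {
            const int koff = ki + kj * k1 + kk * k1 * k2;
            const double* oc = &cols((R_xlen_t)s * Lout, c * K + koff);
            int r = 0;
            for (int z = 0; z < o3; ++z) {
              const int iz = z * s3 - p3 + kk;
              const bool zok = iz >= 0 && iz < d3;
              for (int y = 0; y < o2; ++y) {
                const int iy = y * s2 - p2 + kj;
                const bool yok = zok && iy >= 0 && iy < d2;
                const int base = iy * d1 + iz * d1 * d2;
                for (int x = 0; x < o1; ++x, ++r) {
                  const int ix = x * s1 - p1 + ki;
                  if (yok && ix >= 0 && ix < d1) xc[ix + base] += oc[r];
                }
              }
            }
          }
    }
  }
  return out;
}

// Max-pool with argmax bookkeeping (1-based input row per output element).
// Padding is -Inf padding, never selected.
// [[Rcpp::export]]
List maxpool3_fwd(const NumericMatrix& X, IntegerVector dims,
                  IntegerVector ksize, IntegerVector stride,
                  IntegerVector pad, int n_batch = 1) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int k1 = ksize[0], k2 = ksize[1], k3 = ksize[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int C = X.ncol();
  const int L = d1 * d2 * d3;
  const int o1 = out_extent(d1, k1, s1, p1);
  const int o2 = out_extent(d2, k2, s2, p2);
  const int o3 = out_extent(d3, k3, s3, p3);
  const int Lout = o1 * o2 * o3;
  NumericMatrix out((R_xlen_t)Lout * n_batch, C);
  IntegerMatrix amax((R_xlen_t)Lout * n_batch, C);
  for (int s = 0; s < n_batch; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &X((R_xlen_t)s * L, c);
      R_xlen_t r = (R_xlen_t)s * Lout;
      for (int z = 0; z < o3; ++z)
        for (int y = 0; y < o2; ++y)
          for (int x = 0; x < o1; ++x, ++r) {
            double best = R_NegInf;
            int besti = -1;
            for (int kk = 0; kk < k3; ++kk) {
              const int iz = z * s3 - p3 + kk;
              if (iz < 0 || iz >= d3) continue;
              for (int kj = 0; kj < k2; ++kj) {
                const int iy = y * s2 - p2 + kj;
                if (iy < 0 || iy >= d2) continue;
                for (int ki = 0; ki < k1; ++ki) {
                  const int ix = x * s1 - p1 + ki;
                  if (ix < 0 || ix >= d1) continue;
                  const int idx = ix + iy * d1 + iz * d1 * d2;
                  if (xc[idx] > best) { best = xc[idx]; besti = idx; }
                }
              }
            }
            out(r, c) = best;
            amax(r, c) = besti + s * L + 1;
          }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericMatrix maxpool3_bwd(const NumericMatrix& dout, const IntegerMatrix& amax,
                           int Lin) {
  const int Lout = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(Lin, C);
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < Lout; ++r)
      dx(amax(r, c) - 1, c) += dout(r, c);
  return dx;
}

// Resize a single-channel 3D array (half-pixel-centre convention, clamped).
// method 0 = trilinear, 1 = nearest neighbour.
// [[Rcpp::export]]
NumericVector resize3(const NumericVector& x, IntegerVector din,
                      IntegerVector dout, int method) {
  const int a1 = din[0], a2 = din[1], a3 = din[2];
  const int b1 = dout[0], b2 = dout[1], b3 = dout[2];
  if ((int)x.size() != a1 * a2 * a3) stop("resize3: input size mismatch");
  NumericVector out(b1 * b2 * b3);
  const double r1 = (double)a1 / b1, r2 = (double)a2 / b2, r3 = (double)a3 / b3;
  int r = 0;
  for (int z = 0; z < b3; ++z) {
    const double sz = (z + 0.5) * r3 - 0.5;
    for (int y = 0; y < b2; ++y) {
      const double sy = (y + 0.5) * r2 - 0.5;
      for (int xo = 0; xo < b1; ++xo, ++r) {
        const double sx = (xo + 0.5) * r1 - 0.5;
        if (method == 1) {
          int ix = (int)std::lround(sx), iy = (int)std::lround(sy),
              iz = (int)std::lround(sz);
          ix = std::min(std::max(ix, 0), a1 - 1);
          iy = std::min(std::max(iy, 0), a2 - 1);
          iz = std::min(std::max(iz, 0), a3 - 1);
          out[r] = x[ix + iy * a1 + iz * a1 * a2];
        } else {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
              z0 = (int)std::floor(sz);
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          const int x0c = std::min(std::max(x0, 0), a1 - 1);
          const int x1c = std::min(std::max(x0 + 1, 0), a1 - 1);
          const int y0c = std::min(std::max(y0, 0), a2 - 1);
          const int y1c = std::min(std::max(y0 + 1, 0), a2 - 1);
          const int z0c = std::min(std::max(z0, 0), a3 - 1);
          const int z1c = std::min(std::max(z0 + 1, 0), a3 - 1);
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            const int iz = dz ? z1c : z0c;
            const double wz = dz ? fz : 1.0 - fz;
            if (wz == 0.0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              const int iy = dy ? y1c : y0c;
              const double wy = dy ? fy : 1.0 - fy;
              if (wy == 0.0) continue;
              for (int dx = 0; dx < 2; ++dx) {
                const int ix = dx ? x1c : x0c;
                const double wx = dx ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                acc += wz * wy * wx * x[ix + iy * a1 + iz * a1 * a2];
              }
            }
          }
          out[r] = acc;
        }
      }
    }
  }
  return out;
}
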