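// 3D convolution / pooling kernels for the SFCN.
//
// Feature tensors cross the R/C++ boundary as cubes of shape (V, C, N):
// V = number of voxels of the current spatial grid flattened in R's
// column-major order (x fastest), C = channels, N = batch samples.
// Convolutions are stride 1 with zero padding; im2col is laid out as
// (V x C*k^3) so that inner writes are contiguous and the contraction is
// a single GEMM against the (Cout x C*k^3) weight matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fill `col` (V x Cin*K, K = k^3) from one sample's (V x Cin) slab.
static void im2col3d(const mat& X, int dx, int dy, int dz,
                     int k, int pad, mat& col) {
  const int Cin = X.n_cols;
  const int K = k * k * k;
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    int off = 0;
    for (int oz = 0; oz < k; ++oz)
      for (int oy = 0; oy < k; ++oy)
        for (int ox = 0; ox < k; ++ox, ++off) {
          const int sx = ox - pad, sy = oy - pad, sz = oz - pad;
          double* dst = col.colptr(c * K + off);
          for (int z = 0; z < dz; ++z) {
            const int zi = z + sz;
            if (zi < 0 || zi >= dz) continue;
            for (int y = 0; y < dy; ++y) {
              const int yi = y + sy;
              if (yi < 0 || yi >= dy) continue;
              const int x0 = std::max(0, -sx);
              const int x1 = std::min(dx, dx - sx);
              const double* src = xc + (static_cast<size_t>(zi) * dy + yi) * dx + sx;
              double* out = dst + (static_cast<size_t>(z) * dy + y) * dx;
              for (int x = x0; x < x1; ++x) out[x] = src[x];
            }
          }
        }
  }
}

// Scatter-add of `col` gradients back onto the (V x Cin) input gradient.
static void col2im3d(const mat& dcol, int dx, int dy, int dz,
                     int k, int pad, mat& dX) {
  const int Cin = dX.n_cols;
  const int K = k * k * k;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dX.colptr(c);
    int off = 0;
    for (int oz = 0; oz < k; ++oz)
      for (int oy = 0; oy < k; ++oy)
        for (int ox = 0; ox < k; ++ox, ++off) {
          const int sx = ox - pad, sy = oy - pad, sz = oz - pad;
          const double* dsrc = dcol.colptr(c * K + off);
          for (int z = 0; z < dz; ++z) {
            const int zi = z + sz;
            if (zi < 0 || zi >= dz) continue;
            for (int y = 0; y < dy; ++y) {
              const int yi = y + sy;
              if (yi < 0 || yi >= dy) continue;
              const int x0 = std::max(0, -sx);
              const int x1 = std::min(dx, dx - sx);
              double* acc = xc + (static_cast<size_t>(zi) * dy + yi) * dx + sx;
              const double* in = dsrc + (static_cast<size_t>(z) * dy + y) * dx;
              for (int x = x0; x < x1; ++x) acc[x] += in[x];
            }
          }
        }
  }
}

// [[Rcpp::export]]
arma::cube conv3d_fw_cpp(const arma::cube& X, const arma::ivec& dims,
                         const arma::mat& W, const arma::vec& b,
                         int k, int pad) {
  const int dx = dims(0), dy = dims(1), dz = dims(2);
  const int V = dx * dy * dz;
  const int N = X.n_slices;
  const int Cout = W.n_rows;
  cube Y(V, Cout, N);
  mat col(V, W.n_cols);
  for (int n = 0; n < N; ++n) {
    im2col3d(X.slice(n), dx, dy, dz, k, pad, col);
    Y.slice(n) = col * W.t();
    Y.slice(n).each_row() += b.t();
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bw_cpp(const arma::cube& X, const arma::ivec& dims,
                         const arma::mat& W, const arma::cube& dY,
                         int k, int pad, bool need_dx) {
  const int dx = dims(0), dy = dims(1), dz = dims(2);
  const int V = dx * dy * dz;
  const int N = X.n_slices;
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_rows, fill::zeros);
  cube dX(need_dx ? V : 1, need_dx ? X.n_cols : 1, need_dx ? N : 1,
          fill::zeros);
  mat col(V, W.n_cols);
  mat dXn(V, X.n_cols);
  for (int n = 0; n < N; ++n) {
    im2col3d(X.slice(n), dx, dy, dz, k, pad, col);
    dW += dY.slice(n).t() * col;                    // (Cout x V)(V x CinK)
    db += sum(dY.slice(n), 0).t();
    if (need_dx) {
      mat dcol = dY.slice(n) * W;                   // (V x Cout)(Cout x CinK)
      dXn.zeros();
      col2im3d(dcol, dx, dy, dz, k, pad, dXn);
      dX.slice(n) = dXn;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2x2 max pooling, stride 2. Spatial extents must be even.
// Returns pooled values plus the 1-based flat input index of each maximum
// so the backward pass is an exact scatter.
// [[Rcpp::export]]
Rcpp::List maxpool3d_fw_cpp(const arma::cube& X, const arma::ivec& dims) {
  const int dx = dims(0), dy = dims(1), dz = dims(2);
  const int ox = dx / 2, oy = dy / 2, oz = dz / 2;
  const int Vo = ox * oy * oz;
  const int C = X.n_cols, N = X.n_slices;
  cube Y(Vo, C, N);
  cube idx(Vo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = X.slice(n).colptr(c);
      double* yc = Y.slice(n).colptr(c);
      double* ic = idx.slice(n).colptr(c);
      for (int z = 0; z < oz; ++z)
        for (int y = 0; y < oy; ++y)
          for (int x = 0; x < ox; ++x) {
            double best = -std::numeric_limits<double>::infinity();
            int besti = -1;
            for (int wz = 0; wz < 2; ++wz)
              for (int wy = 0; wy < 2; ++wy)
                for (int wx = 0; wx < 2; ++wx) {
                  const int xi = 2 * x + wx, yi = 2 * y + wy, zi = 2 * z + wz;
                  const int vi = (zi * dy + yi) * dx + xi;
                  if (xc[vi] > best) { best = xc[vi]; besti = vi; }
                }
            const int vo = (z * oy + y) * ox + x;
            yc[vo] = best;
            ic[vo] = besti + 1;
          }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool3d_bw_cpp(const arma::cube& idx, const arma::cube& dY,
                            int Vin) {
  const int C = dY.n_cols, N = dY.n_slices;
  const int Vo = dY.n_rows;
  cube dX(Vin, C, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* ic = idx.slice(n).colptr(c);
      const double* dyc = dY.slice(n).colptr(c);
      double* dxc = dX.slice(n).colptr(c);
      for (int v = 0; v < Vo; ++v)
        dxc[static_cast<int>(ic[v]) - 1] += dyc[v];
    }
  return dX;
}
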