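// Numerical kernels for the registration networks: 3D convolution
// (im2col + BLAS dgemm), trilinear rigid warping with gradients w.r.t.
// the affine coefficients, 3x3x3 box filtering and integer shifts used
// by the MIND descriptor, and nearest-neighbour upsampling.
//
// Array layout follows R column-major arrays: volumes are [X, Y, Z] or
// [X, Y, Z, C] with X fastest. All indices 0-based internally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int X, int Y) {
  return x + X * (y + Y * z);
}

// ---------------------------------------------------------------------
// im2row for a chunk of output voxels [n0, n1): K is [n1-n0, R] with
// rows = output voxels (x fastest) and columns = (kx, ky, kz, cin)
// taps, so out = K * W directly. Stride-1 fills use contiguous row
// copies; strided convs fall back to a scalar gather.
static void im2row_chunk(const double* x, int X, int Y, int Z, int Cin,
                         int k, int pad, int sx, int sy, int sz,
                         int Xo, int Yo, int Zo,
                         int n0, int n1, arma::mat& K) {
  const int XY = X * Y;
  const size_t plane = (size_t)X * Y * Z;
  if (sx == 1 && sy == 1 && sz == 1) {
    // n = x + X*(y + Y*z); chunk rows are n - n0
    int r = 0;
    for (int c = 0; c < Cin; ++c) {
      const double* xc = x + (size_t)c * plane;
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx, ++r) {
            double* col = K.colptr(r);
            const int dx = kx - pad, dy = ky - pad, dz = kz - pad;
            // first and last output voxel of the chunk
            for (int n = n0; n < n1;) {
              const int z = n / XY;
              const int rem = n - z * XY;
              const int y = rem / X;
              const int x0 = rem - y * X;
              const int rowLen = std::min(X - x0, n1 - n);
              const int iz = z + dz, iy = y + dy;
              double* seg = col + (n - n0);
              if (iz >= 0 && iz < Z && iy >= 0 && iy < Y) {
                // valid input x range within [x0, x0+rowLen)
                int a = x0, b = x0 + rowLen;     // output x range
                if (a + dx < 0) a = -dx;
                if (b + dx > X) b = X - dx;
                if (b <= a) {
                  std::fill(seg, seg + rowLen, 0.0);
                } else {
                  if (a > x0) std::fill(seg, seg + (a - x0), 0.0);
                  std::copy(xc + (a + dx) + X * iy + (size_t)XY * iz,
                            xc + (b + dx) + X * iy + (size_t)XY * iz,
                            seg + (a - x0));
                  if (b < x0 + rowLen)
                    std::fill(seg + (b - x0), seg + rowLen, 0.0);
                }
              } else {
                std::fill(seg, seg + rowLen, 0.0);
              }
              n += rowLen;
            }
          }
    }
  } else {
    K.zeros();
    for (int n = n0; n < n1; ++n) {
      int rem = n;
      const int ox = rem % Xo; rem /= Xo;
      const int oy = rem % Yo; rem /= Yo;
      const int oz = rem;
      int r = 0;
      for (int c = 0; c < Cin; ++c) {
        const double* xc = x + (size_t)c * plane;
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * sz - pad + kz;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * sy - pad + ky;
            for (int kx = 0; kx < k; ++kx, ++r) {
              const int ix = ox * sx - pad + kx;
              if (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 &&
                  iz < Z)
                K(n - n0, r) = xc[ix + X * iy + (size_t)XY * iz];
            }
          }
        }
      }
    }
  }
}

// Forward 3D convolution, 'same' padding, odd kernel k, per-axis stride.
// x: [X,Y,Z,Cin]; w: [k,k,k,Cin,Cout]; b: length Cout (may be empty).
// If keep_k is nonzero and the full column matrix fits the cap, it is
// built unchunked and returned for reuse by the backward pass.
// [[Rcpp::export]]
List cpp_conv3d(NumericVector x, NumericVector w, NumericVector b,
                IntegerVector xdim, int cin, int cout, int k,
                IntegerVector stride, int keep_k) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int pad = k / 2;
  const int Xo = (X + sx - 1) / sx, Yo = (Y + sy - 1) / sy,
            Zo = (Z + sz - 1) / sz;
  const int N = Xo * Yo * Zo;
  const int R = k * k * k * cin;

  arma::mat W(w.begin(), R, cout, false, true);
  NumericVector out(static_cast<R_xlen_t>(N) * cout);
  arma::mat O(out.begin(), N, cout, false, true);

  const bool full = keep_k && (double)N * R <= 13e6;
  if (full) {
    NumericMatrix Kout(N, R);
    arma::mat K(Kout.begin(), N, R, false, true);
    im2row_chunk(x.begin(), X, Y, Z, cin, k, pad, sx, sy, sz,
                 Xo, Yo, Zo, 0, N, K);
    O = K * W;
    if (b.size() == cout)
      for (int c = 0; c < cout; ++c) O.col(c) += b[c];
    out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, cout);
    return List::create(_["out"] = out, _["K"] = Kout);
  }
  const int chunk = std::max(1, std::min(N, 1 << 15));
  arma::mat K(chunk, R);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int n1 = std::min(N, n0 + chunk);
    if (n1 - n0 != (int)K.n_rows) K.set_size(n1 - n0, R);
    im2row_chunk(x.begin(), X, Y, Z, cin, k, pad, sx, sy, sz,
                 Xo, Yo, Zo, n0, n1, K);
    O.rows(n0, n1 - 1) = K * W;
  }
  if (b.size() == cout) {
    for (int c = 0; c < cout; ++c) O.col(c) += b[c];
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, cout);
  return List::create(_["out"] = out, _["K"] = R_NilValue);
}

// Backward pass: returns list(gx, gw, gb) given upstream gradient gout
// on the [Xo,Yo,Zo,Cout] output. need_gx = 0 skips the input gradient
// (constant inputs); for stride-1 convs the input gradient is computed
// as a convolution of gout with the flipped transposed kernel (BLAS
// path) instead of the scatter-add col2im.
// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, NumericVector w,
                         NumericVector gout, IntegerVector xdim, int cin,
                         int cout, int k, IntegerVector stride,
                         int need_gx, Nullable<NumericMatrix> Kcache) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int pad = k / 2;
  const int Xo = (X + sx - 1) / sx, Yo = (Y + sy - 1) / sy,
            Zo = (Z + sz - 1) / sz;
  const int N = Xo * Yo * Zo;
  const int R = k * k * k * cin;
  const int XY = X * Y;
  const int plane = X * Y * Z;

  arma::mat W(w.begin(), R, cout, false, true);
  arma::mat G(gout.begin(), N, cout, false, true);

  NumericVector gw(w.size());
  NumericVector gb(cout);
  arma::mat GW(gw.begin(), R, cout, false, true);

  const bool fastGx = need_gx && sx == 1 && sy == 1 && sz == 1;
  NumericVector gx(need_gx ? static_cast<R_xlen_t>(plane) * cin : 0);

  const int chunk = std::max(1, std::min(N, 1 << 15));
  if (Kcache.isNotNull()) {
    NumericMatrix Km(Kcache.get());
    arma::mat K(Km.begin(), N, R, false, true);
    GW = K.t() * G;
  }
  arma::mat K(chunk, R);
  arma::mat GC;
  for (int n0 = 0; Kcache.isNull() && n0 < N; n0 += chunk) {
    const int n1 = std::min(N, n0 + chunk);
    if (n1 - n0 != (int)K.n_rows) K.set_size(n1 - n0, R);
    im2row_chunk(x.begin(), X, Y, Z, cin, k, pad, sx, sy, sz,
                 Xo, Yo, Zo, n0, n1, K);
    GW += K.t() * G.rows(n0, n1 - 1);
    if (need_gx && !fastGx) {
      // gradient w.r.t. the row matrix, then scatter-add (col2im)
      GC = G.rows(n0, n1 - 1) * W.t();  // [n1-n0, R]
      for (int n = n0; n < n1; ++n) {
        int rem = n;
        const int ox = rem % Xo; rem /= Xo;
        const int oy = rem % Yo; rem /= Yo;
        const int oz = rem;
        int r = 0;
        for (int c = 0; c < cin; ++c) {
          double* gxc = gx.begin() + (size_t)c * plane;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = oz * sz - pad + kz;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = oy * sy - pad + ky;
              for (int kx = 0; kx < k; ++kx, ++r) {
                const int ix = ox * sx - pad + kx;
                if (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 &&
                    iz < Z)
                  gxc[ix + X * iy + XY * iz] += GC(n - n0, r);
              }
            }
          }
        }
      }
    }
  }
  if (fastGx) {
    // gx = gout (*) flip(w) with channel roles swapped
    const int kk = k * k * k;
    const int R2 = kk * cout;
    arma::mat Wf(R2, cin);
    // Wf[(tap, cout), cin] = w[flipped tap, cin, cout]
    const double* wp = w.begin();
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < cin; ++ci)
        for (int t = 0; t < kk; ++t) {
          const int kx = t % k, ky = (t / k) % k, kz = t / (k * k);
          Wf(t + kk * co, ci) =
              wp[(k - 1 - kx) + k * ((k - 1 - ky) + k * (k - 1 - kz)) +
                 (size_t)kk * (ci + (size_t)cin * co)];
        }
    arma::mat GX(gx.begin(), plane, cin, false, true);
    arma::mat K2(chunk, R2);
    for (int n0 = 0; n0 < plane; n0 += chunk) {
      const int n1 = std::min(plane, n0 + chunk);
      if (n1 - n0 != (int)K2.n_rows) K2.set_size(n1 - n0, R2);
      im2row_chunk(gout.begin(), X, Y, Z, cout, k, pad, 1, 1, 1,
                   X, Y, Z, n0, n1, K2);
      GX.rows(n0, n1 - 1) = K2 * Wf;
    }
  }
  for (int c = 0; c < cout; ++c) gb[c] = arma::accu(G.col(c));
  if (need_gx)
    gx.attr("dim") = IntegerVector::create(X, Y, Z, cin);
  gw.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------
// Trilinear / nearest resampling of a single-channel volume by a 3x4
// affine map A (row-major rows: sample = A[, 1:3] %*% out_idx + A[, 4],
// in 0-based voxel coordinates of the input). Out-of-volume -> 0.
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector vol, NumericMatrix A,
                              IntegerVector dim, IntegerVector odim,
                              int nearest) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const int Xo = odim[0], Yo = odim[1], Zo = odim[2];
  NumericVector out(static_cast<R_xlen_t>(Xo) * Yo * Zo);
  const double* v = vol.begin();
  double* o = out.begin();
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  int n = 0;
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int x = 0; x < Xo; ++x, ++n) {
        const double px = a00 * x + a01 * y + a02 * z + a03;
        const double py = a10 * x + a11 * y + a12 * z + a13;
        const double pz = a20 * x + a21 * y + a22 * z + a23;
        if (nearest) {
          const int ix = (int)std::lround(px);
          const int iy = (int)std::lround(py);
          const int iz = (int)std::lround(pz);
          o[n] = (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 &&
                  iz < Z)
                     ? v[idx3(ix, iy, iz, X, Y)]
                     : 0.0;
        } else {
          const int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
                    z0 = (int)std::floor(pz);
          const double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int ix = x0 + dx, iy = y0 + dy, iz = z0 + dz;
                if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 ||
                    iz >= Z)
                  continue;
                const double wgt = (dx ? fx : 1 - fx) *
                                   (dy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                acc += wgt * v[idx3(ix, iy, iz, X, Y)];
              }
          o[n] = acc;
        }
      }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  return out;
}

// Gradient of sum(gout * warp(vol, A)) w.r.t. the 12 entries of A
// (trilinear mode). Returns a 3x4 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine_backward(NumericVector vol, NumericMatrix A,
                                       NumericVector gout,
                                       IntegerVector dim) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const double* v = vol.begin();
  const double* g = gout.begin();
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  double gA[12] = {0};
  int n = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++n) {
        const double gn = g[n];
        if (gn == 0.0) continue;
        const double px = a00 * x + a01 * y + a02 * z + a03;
        const double py = a10 * x + a11 * y + a12 * z + a13;
        const double pz = a20 * x + a21 * y + a22 * z + a23;
        const int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
                  z0 = (int)std::floor(pz);
        const double fx = px - x0, fy = py - y0, fz = pz - z0;
        double dpx = 0.0, dpy = 0.0, dpz = 0.0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int ix = x0 + dx, iy = y0 + dy, iz = z0 + dz;
              if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 ||
                  iz >= Z)
                continue;
              const double val = v[idx3(ix, iy, iz, X, Y)];
              const double wx = dx ? fx : 1 - fx;
              const double wy = dy ? fy : 1 - fy;
              const double wz = dz ? fz : 1 - fz;
              dpx += (dx ? 1.0 : -1.0) * wy * wz * val;
              dpy += wx * (dy ? 1.0 : -1.0) * wz * val;
              dpz += wx * wy * (dz ? 1.0 : -1.0) * val;
            }
        const double gx = gn * dpx, gy = gn * dpy, gz = gn * dpz;
        gA[0] += gx * x; gA[3] += gx * y; gA[6] += gx * z; gA[9] += gx;
        gA[1] += gy * x; gA[4] += gy * y; gA[7] += gy * z; gA[10] += gy;
        gA[2] += gz * x; gA[5] += gz * y; gA[8] += gz * z; gA[11] += gz;
      }
  NumericMatrix out(3, 4);
  std::copy(gA, gA + 12, out.begin());
  return out;
}

// ---------------------------------------------------------------------
// 3x3x3 mean filter with zero padding (divisor fixed at 27), applied
// per channel on an [X,Y,Z,C] array. Separable; self-adjoint, so the
// backward pass reuses this function.
// [[Rcpp::export]]
NumericVector cpp_boxfilter3(NumericVector x, IntegerVector dim) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const int C = (dim.size() > 3) ? dim[3] : 1;
  const int plane = X * Y * Z;
  NumericVector out(x.size());
  std::vector<double> t1(plane), t2(plane);
  for (int c = 0; c < C; ++c) {
    const double* xi = x.begin() + (size_t)c * plane;
    double* oo = out.begin() + (size_t)c * plane;
    // along X
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) {
        const int base = X * (y + Y * z);
        for (int i = 0; i < X; ++i) {
          double s = xi[base + i];
          if (i > 0) s += xi[base + i - 1];
          if (i < X - 1) s += xi[base + i + 1];
          t1[base + i] = s;
        }
      }
    // along Y
    for (int z = 0; z < Z; ++z)
      for (int i = 0; i < X; ++i) {
        const int base = X * Y * z + i;
        for (int y = 0; y < Y; ++y) {
          double s = t1[base + X * y];
          if (y > 0) s += t1[base + X * (y - 1)];
          if (y < Y - 1) s += t1[base + X * (y + 1)];
          t2[base + X * y] = s;
        }
      }
    // along Z
    for (int y = 0; y < Y; ++y)
      for (int i = 0; i < X; ++i) {
        const int base = i + X * y;
        for (int z = 0; z < Z; ++z) {
          double s = t2[base + X * Y * z];
          if (z > 0) s += t2[base + X * Y * (z - 1)];
          if (z < Z - 1) s += t2[base + X * Y * (z + 1)];
          oo[base + X * Y * z] = s / 27.0;
        }
      }
  }
  out.attr("dim") = dim;
  return out;
}

// Integer-voxel shift with zero fill: out(i) = x(i + s), per channel.
// [[Rcpp::export]]
NumericVector cpp_shift3d(NumericVector x, IntegerVector dim,
                          IntegerVector s) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const int C = (dim.size() > 3) ? dim[3] : 1;
  const int plane = X * Y * Z;
  const int sx = s[0], sy = s[1], sz = s[2];
  NumericVector out(x.size());
  for (int c = 0; c < C; ++c) {
    const double* xi = x.begin() + (size_t)c * plane;
    double* oo = out.begin() + (size_t)c * plane;
    for (int z = 0; z < Z; ++z) {
      const int iz = z + sz;
      if (iz < 0 || iz >= Z) continue;
      for (int y = 0; y < Y; ++y) {
        const int iy = y + sy;
        if (iy < 0 || iy >= Y) continue;
        const int x0 = std::max(0, -sx), x1 = std::min(X, X - sx);
        const double* src = xi + idx3(x0 + sx, iy, iz, X, Y);
        double* dst = oo + idx3(x0, y, z, X, Y);
        for (int i = 0; i < x1 - x0; ++i) dst[i] = src[i];
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Nearest-neighbour upsampling by integer per-axis factors.
// [[Rcpp::export]]
NumericVector cpp_upsample_nn(NumericVector x, IntegerVector dim,
                              IntegerVector f) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const int C = (dim.size() > 3) ? dim[3] : 1;
  const int fx = f[0], fy = f[1], fz = f[2];
  const int Xo = X * fx, Yo = Y * fy, Zo = Z * fz;
  const int plane = X * Y * Z, planeo = Xo * Yo * Zo;
  NumericVector out(static_cast<R_xlen_t>(planeo) * C);
  for (int c = 0; c < C; ++c) {
    const double* xi = x.begin() + (size_t)c * plane;
    double* oo = out.begin() + (size_t)c * planeo;
    int n = 0;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y)
        for (int xx = 0; xx < Xo; ++xx, ++n)
          oo[n] = xi[idx3(xx / fx, y / fy, z / fz, X, Y)];
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return out;
}

// Adjoint of nearest upsampling: block-sum pooling of the gradient.
// [[Rcpp::export]]
NumericVector cpp_upsample_nn_backward(NumericVector g, IntegerVector odim,
                                       IntegerVector f) {
  const int Xo = odim[0], Yo = odim[1], Zo = odim[2];
  const int C = (odim.size() > 3) ? odim[3] : 1;
  const int fx = f[0], fy = f[1], fz = f[2];
  const int X = Xo / fx, Y = Yo / fy, Z = Zo / fz;
  const int plane = X * Y * Z, planeo = Xo * Yo * Zo;
  NumericVector out(static_cast<R_xlen_t>(plane) * C);
  for (int c = 0; c < C; ++c) {
    const double* gi = g.begin() + (size_t)c * planeo;
    double* oo = out.begin() + (size_t)c * plane;
    int n = 0;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y)
        for (int xx = 0; xx < Xo; ++xx, ++n)
          oo[idx3(xx / fx, y / fy, z / fz, X, Y)] += gi[n];
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return out;
}
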