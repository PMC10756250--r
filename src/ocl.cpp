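#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable correlation along one axis of a 3D volume stored column-major
// (x fastest). Borders are handled by edge replication. kernel has odd length
// and is centred; out[i] = sum_t kernel[t + r] * vol[i + t along axis].
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = (kernel.size() - 1) / 2;
  NumericVector out(vol.size());
  const double *v = REAL(vol);
  const double *k = REAL(kernel);
  double *o = REAL(out);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  if (axis == 0) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = (R_xlen_t)z * sxy + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t)
            s += k[t + r] * v[base + clampi(x + t, 0, nx - 1)];
          o[base + x] = s;
        }
      }
    }
  } else if (axis == 1) {
    for (int z = 0; z < nz; ++z) {
      const R_xlen_t zb = (R_xlen_t)z * sxy;
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = zb + (R_xlen_t)y * nx;
        for (int t = -r; t <= r; ++t) {
          const R_xlen_t src = zb + (R_xlen_t)clampi(y + t, 0, ny - 1) * nx;
          const double kt = k[t + r];
          if (t == -r)
            for (int x = 0; x < nx; ++x) o[base + x] = kt * v[src + x];
          else
            for (int x = 0; x < nx; ++x) o[base + x] += kt * v[src + x];
        }
      }
    }
  } else {
    for (int z = 0; z < nz; ++z) {
      const R_xlen_t zb = (R_xlen_t)z * sxy;
      for (int t = -r; t <= r; ++t) {
        const R_xlen_t src = (R_xlen_t)clampi(z + t, 0, nz - 1) * sxy;
        const double kt = k[t + r];
        if (t == -r)
          for (R_xlen_t i = 0; i < sxy; ++i) o[zb + i] = kt * v[src + i];
        else
          for (R_xlen_t i = 0; i < sxy; ++i) o[zb + i] += kt * v[src + i];
      }
    }
  }
  return out;
}

// Trilinear (or nearest) interpolation of a 3D volume at arbitrary 0-based
// continuous voxel coordinates. Points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector interp3_cpp(NumericVector vol, IntegerVector dim,
                          NumericMatrix pts, double fill = 0.0,
                          bool nearest = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (nearest) {
      const int xi = (int)std::lround(x), yi = (int)std::lround(y),
                zi = (int)std::lround(z);
      if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
        out[i] = fill;
      } else {
        out[i] = v[(R_xlen_t)zi * sxy + (R_xlen_t)yi * nx + xi];
      }
      continue;
    }
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) --x0;
    if (y0 == ny - 1) --y0;
    if (z0 == nz - 1) --z0;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double s = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      const int zi = clampi(z0 + dz, 0, nz - 1);
      const double wz = dz ? fz : 1.0 - fz;
      if (wz == 0.0) continue;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yi = clampi(y0 + dy, 0, ny - 1);
        const double wy = dy ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xi = clampi(x0 + dx, 0, nx - 1);
          const double wx = dx ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          s += wz * wy * wx * v[(R_xlen_t)zi * sxy + (R_xlen_t)yi * nx + xi];
        }
      }
    }
    out[i] = s;
  }
  return out;
}

// Resample `vol` (dim_in) onto an output grid (dim_out) under the affine map
// src = A %*% dst + b in 0-based voxel coordinates.
// [[Rcpp::export]]
NumericVector affine_resample_cpp(NumericVector vol, IntegerVector dim_in,
                                  IntegerVector dim_out, NumericMatrix A,
                                  NumericVector b, double fill = 0.0,
                                  bool nearest = false) {
  const int nxo = dim_out[0], nyo = dim_out[1], nzo = dim_out[2];
  NumericVector out((R_xlen_t)nxo * nyo * nzo);
  NumericMatrix pt(1, 3);
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  const int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double *v = REAL(vol);
  double *o = REAL(out);
  R_xlen_t idx = 0;
  for (int z = 0; z < nzo; ++z) {
    for (int y = 0; y < nyo; ++y) {
      for (int x = 0; x < nxo; ++x, ++idx) {
        const double sx = a00 * x + a01 * y + a02 * z + b[0];
        const double sy = a10 * x + a11 * y + a12 * z + b[1];
        const double sz = a20 * x + a21 * y + a22 * z + b[2];
        if (nearest) {
          const int xi = (int)std::lround(sx), yi = (int)std::lround(sy),
                    zi = (int)std::lround(sz);
          o[idx] = (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
                       ? fill
                       : v[(R_xlen_t)zi * sxy + (R_xlen_t)yi * nx + xi];
          continue;
        }
        if (sx < 0 || sy < 0 || sz < 0 || sx > nx - 1 || sy > ny - 1 ||
            sz > nz - 1) {
          o[idx] = fill;
          continue;
        }
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
            z0 = (int)std::floor(sz);
        if (x0 == nx - 1 && nx > 1) --x0;
        if (y0 == ny - 1 && ny > 1) --y0;
        if (z0 == nz - 1 && nz > 1) --z0;
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double s = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          const int zi = clampi(z0 + dz, 0, nz - 1);
          const double wz = dz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int dy = 0; dy <= 1; ++dy) {
            const int yi = clampi(y0 + dy, 0, ny - 1);
            const double wy = dy ? fy : 1.0 - fy;
            if (wy == 0.0) continue;
            for (int dx = 0; dx <= 1; ++dx) {
              const int xi = clampi(x0 + dx, 0, nx - 1);
              const double wx = dx ? fx : 1.0 - fx;
              if (wx == 0.0) continue;
              s += wz * wy * wx * v[(R_xlen_t)zi * sxy + (R_xlen_t)yi * nx + xi];
            }
          }
        }
        o[idx] = s;
      }
    }
  }
  return out;
}

// Warp an integer label image (codes 0..K-1) onto an output grid under
// src = A %*% dst + b, spreading each destination voxel's trilinear weights
// over the one-hot encoding of the source labels (soft resampling), or
// nearest-neighbour when `nearest`. Out-of-bounds mass goes to class 0.
// Returns an (n_out x K) weight matrix whose rows sum to 1.
// [[Rcpp::export]]
NumericMatrix warp_labels_onehot_cpp(IntegerVector labels, IntegerVector dim_in,
                                     IntegerVector dim_out, NumericMatrix A,
                                     NumericVector b, int K,
                                     bool nearest = false) {
  const int nxo = dim_out[0], nyo = dim_out[1], nzo = dim_out[2];
  const int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const R_xlen_t nout = (R_xlen_t)nxo * nyo * nzo;
  NumericMatrix out(nout, K);
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  const int *lab = INTEGER(labels);
  R_xlen_t idx = 0;
  for (int z = 0; z < nzo; ++z) {
    for (int y = 0; y < nyo; ++y) {
      for (int x = 0; x < nxo; ++x, ++idx) {
        const double sx = a00 * x + a01 * y + a02 * z + b[0];
        const double sy = a10 * x + a11 * y + a12 * z + b[1];
        const double sz = a20 * x + a21 * y + a22 * z + b[2];
        if (nearest) {
          const int xi = (int)std::lround(sx), yi = (int)std::lround(sy),
                    zi = (int)std::lround(sz);
          int cls = 0;
          if (!(xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz))
            cls = lab[(R_xlen_t)zi * sxy + (R_xlen_t)yi * nx + xi];
          out(idx, cls) = 1.0;
          continue;
        }
        if (sx < 0 || sy < 0 || sz < 0 || sx > nx - 1 || sy > ny - 1 ||
            sz > nz - 1) {
          out(idx, 0) = 1.0;
          continue;
        }
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
            z0 = (int)std::floor(sz);
        if (x0 == nx - 1 && nx > 1) --x0;
        if (y0 == ny - 1 && ny > 1) --y0;
        if (z0 == nz - 1 && nz > 1) --z0;
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        for (int dz = 0; dz <= 1; ++dz) {
          const int zi = clampi(z0 + dz, 0, nz - 1);
          const double wz = dz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int dy = 0; dy <= 1; ++dy) {
            const int yi = clampi(y0 + dy, 0, ny - 1);
            const double wy = dy ? fy : 1.0 - fy;
            if (wy == 0.0) continue;
            for (int dx = 0; dx <= 1; ++dx) {
              const int xi = clampi(x0 + dx, 0, nx - 1);
              const double wx = dx ? fx : 1.0 - fx;
              if (wx == 0.0) continue;
              const int cls = lab[(R_xlen_t)zi * sxy + (R_xlen_t)yi * nx + xi];
              out(idx, cls) += wz * wy * wx;
            }
          }
        }
      }
    }
  }
  return out;
}

// Eigenvalues (ascending) and determinant of per-voxel symmetric 3x3 Hessians
// given the six unique components. Returns an n x 4 matrix (ev1, ev2, ev3, det).
// Closed-form trigonometric solution for symmetric 3x3 matrices.
// [[Rcpp::export]]
NumericMatrix sym3_eigs_cpp(NumericVector hxx, NumericVector hyy,
                            NumericVector hzz, NumericVector hxy,
                            NumericVector hxz, NumericVector hyz) {
  const R_xlen_t n = hxx.size();
  NumericMatrix out(n, 4);
  const double twopi3 = 2.0 * M_PI / 3.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xx = hxx[i], yy = hyy[i], zz = hzz[i];
    const double xy = hxy[i], xz = hxz[i], yz = hyz[i];
    const double det = xx * (yy * zz - yz * yz) - xy * (xy * zz - yz * xz) +
                       xz * (xy * yz - yy * xz);
    const double p1 = xy * xy + xz * xz + yz * yz;
    double e1, e2, e3;
    if (p1 < 1e-30) {
      e1 = xx; e2 = yy; e3 = zz;
      if (e1 > e2) std::swap(e1, e2);
      if (e2 > e3) std::swap(e2, e3);
      if (e1 > e2) std::swap(e1, e2);
    } else {
      const double q = (xx + yy + zz) / 3.0;
      const double p2 = (xx - q) * (xx - q) + (yy - q) * (yy - q) +
                        (zz - q) * (zz - q) + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // r = det(B)/2 with B = (H - qI)/p
      const double bxx = (xx - q) / p, byy = (yy - q) / p, bzz = (zz - q) / p;
      const double bxy = xy / p, bxz = xz / p, byz = yz / p;
      double r = 0.5 * (bxx * (byy * bzz - byz * byz) -
                        bxy * (bxy * bzz - byz * bxz) +
                        bxz * (bxy * byz - byy * bxz));
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      const double phi = std::acos(r) / 3.0;
      const double emax = q + 2.0 * p * std::cos(phi);
      const double emin = q + 2.0 * p * std::cos(phi + twopi3);
      e1 = emin;
      e3 = emax;
      e2 = 3.0 * q - emax - emin;
    }
    out(i, 0) = e1;
    out(i, 1) = e2;
    out(i, 2) = e3;
    out(i, 3) = det;
  }
  return out;
}
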