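#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
// Out-of-range coordinates are clamped to the edge (replicate boundary).
// [[Rcpp::export]]
NumericVector c_trilinear(NumericVector a, IntegerVector dims,
                          NumericVector x, NumericVector y, NumericVector z) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t m = x.size();
  NumericVector out(m);
  const double *A = a.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    double xc = x[p], yc = y[p], zc = z[p];
    if (xc < 0) xc = 0; else if (xc > n1 - 1) xc = n1 - 1;
    if (yc < 0) yc = 0; else if (yc > n2 - 1) yc = n2 - 1;
    if (zc < 0) zc = 0; else if (zc > n3 - 1) zc = n3 - 1;
    int i0 = (int)xc, j0 = (int)yc, k0 = (int)zc;
    if (i0 > n1 - 2) i0 = n1 > 1 ? n1 - 2 : 0;
    if (j0 > n2 - 2) j0 = n2 > 1 ? n2 - 2 : 0;
    if (k0 > n3 - 2) k0 = n3 > 1 ? n3 - 2 : 0;
    const double fx = xc - i0, fy = yc - j0, fz = zc - k0;
    const int i1 = i0 + 1 < n1 ? i0 + 1 : i0;
    const int j1 = j0 + 1 < n2 ? j0 + 1 : j0;
    const int k1 = k0 + 1 < n3 ? k0 + 1 : k0;
    const double *pk0 = A + (size_t)k0 * n1 * n2;
    const double *pk1 = A + (size_t)k1 * n1 * n2;
    const double b000 = pk0[i0 + n1 * j0], b100 = pk0[i1 + n1 * j0];
    const double b010 = pk0[i0 + n1 * j1], b110 = pk0[i1 + n1 * j1];
    const double b001 = pk1[i0 + n1 * j0], b101 = pk1[i1 + n1 * j0];
    const double b011 = pk1[i0 + n1 * j1], b111 = pk1[i1 + n1 * j1];
    const double c00 = b000 + fx * (b100 - b000);
    const double c10 = b010 + fx * (b110 - b010);
    const double c01 = b001 + fx * (b101 - b001);
    const double c11 = b011 + fx * (b111 - b011);
    const double c0 = c00 + fy * (c10 - c00);
    const double c1 = c01 + fy * (c11 - c01);
    out[p] = c0 + fz * (c1 - c0);
  }
  return out;
}

// Nearest-neighbour sampling with edge clamping (used for label volumes).
// [[Rcpp::export]]
NumericVector c_nearest(NumericVector a, IntegerVector dims,
                        NumericVector x, NumericVector y, NumericVector z) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t m = x.size();
  NumericVector out(m);
  const double *A = a.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    double xc = x[p], yc = y[p], zc = z[p];
    if (xc < 0) xc = 0; else if (xc > n1 - 1) xc = n1 - 1;
    if (yc < 0) yc = 0; else if (yc > n2 - 1) yc = n2 - 1;
    if (zc < 0) zc = 0; else if (zc > n3 - 1) zc = n3 - 1;
    const int i = (int)(xc + 0.5), j = (int)(yc + 0.5), k = (int)(zc + 0.5);
    out[p] = A[(size_t)k * n1 * n2 + (size_t)j * n1 + i];
  }
  return out;
}

// One self/general composition step for displacement fields in voxel
// units: out(x) = u_outer(x) + u_inner(x + u_outer(x)), trilinear with
// edge clamping.  Both fields are [n1*n2*n3, 3] column-major 4D arrays.
// [[Rcpp::export]]
NumericVector c_field_compose(NumericVector uo, NumericVector ui,
                              IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t nv = (size_t)n1 * n2 * n3;
  NumericVector out((R_xlen_t)(nv * 3));
  const double *O = uo.begin(), *I = ui.begin();
  double *P = out.begin();
  size_t p = 0;
  for (int k = 0; k < n3; ++k) for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i, ++p) {
      double xc = i + O[p], yc = j + O[p + nv], zc = k + O[p + 2 * nv];
      if (xc < 0) xc = 0; else if (xc > n1 - 1) xc = n1 - 1;
      if (yc < 0) yc = 0; else if (yc > n2 - 1) yc = n2 - 1;
      if (zc < 0) zc = 0; else if (zc > n3 - 1) zc = n3 - 1;
      int i0 = (int)xc, j0 = (int)yc, k0 = (int)zc;
      if (i0 > n1 - 2) i0 = n1 > 1 ? n1 - 2 : 0;
      if (j0 > n2 - 2) j0 = n2 > 1 ? n2 - 2 : 0;
      if (k0 > n3 - 2) k0 = n3 > 1 ? n3 - 2 : 0;
      const double fx = xc - i0, fy = yc - j0, fz = zc - k0;
      const int i1 = i0 + 1 < n1 ? i0 + 1 : i0;
      const int j1 = j0 + 1 < n2 ? j0 + 1 : j0;
      const int k1 = k0 + 1 < n3 ? k0 + 1 : k0;
      const size_t b000 = (size_t)k0 * n1 * n2 + (size_t)j0 * n1 + i0;
      const size_t b100 = (size_t)k0 * n1 * n2 + (size_t)j0 * n1 + i1;
      const size_t b010 = (size_t)k0 * n1 * n2 + (size_t)j1 * n1 + i0;
      const size_t b110 = (size_t)k0 * n1 * n2 + (size_t)j1 * n1 + i1;
      const size_t b001 = (size_t)k1 * n1 * n2 + (size_t)j0 * n1 + i0;
      const size_t b101 = (size_t)k1 * n1 * n2 + (size_t)j0 * n1 + i1;
      const size_t b011 = (size_t)k1 * n1 * n2 + (size_t)j1 * n1 + i0;
      const size_t b111 = (size_t)k1 * n1 * n2 + (size_t)j1 * n1 + i1;
      const double w000 = (1 - fx) * (1 - fy) * (1 - fz);
      const double w100 = fx * (1 - fy) * (1 - fz);
      const double w010 = (1 - fx) * fy * (1 - fz);
      const double w110 = fx * fy * (1 - fz);
      const double w001 = (1 - fx) * (1 - fy) * fz;
      const double w101 = fx * (1 - fy) * fz;
      const double w011 = (1 - fx) * fy * fz;
      const double w111 = fx * fy * fz;
      for (int c = 0; c < 3; ++c) {
        const double *U = I + (size_t)c * nv;
        P[p + (size_t)c * nv] = O[p + (size_t)c * nv] +
          U[b000] * w000 + U[b100] * w100 + U[b010] * w010 +
          U[b110] * w110 + U[b001] * w001 + U[b101] * w101 +
          U[b011] * w011 + U[b111] * w111;
      }
    }
  return out;
}

// Warp a scalar volume through a displacement field (voxel units,
// backward convention) with trilinear interpolation and edge clamping.
// [[Rcpp::export]]
NumericVector c_warp_scalar(NumericVector a, NumericVector u,
                            IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t nv = (size_t)n1 * n2 * n3;
  NumericVector out((R_xlen_t)nv);
  const double *A = a.begin(), *U = u.begin();
  double *P = out.begin();
  size_t p = 0;
  for (int k = 0; k < n3; ++k) for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i, ++p) {
      double xc = i + U[p], yc = j + U[p + nv], zc = k + U[p + 2 * nv];
      if (xc < 0) xc = 0; else if (xc > n1 - 1) xc = n1 - 1;
      if (yc < 0) yc = 0; else if (yc > n2 - 1) yc = n2 - 1;
      if (zc < 0) zc = 0; else if (zc > n3 - 1) zc = n3 - 1;
      int i0 = (int)xc, j0 = (int)yc, k0 = (int)zc;
      if (i0 > n1 - 2) i0 = n1 > 1 ? n1 - 2 : 0;
      if (j0 > n2 - 2) j0 = n2 > 1 ? n2 - 2 : 0;
      if (k0 > n3 - 2) k0 = n3 > 1 ? n3 - 2 : 0;
      const double fx = xc - i0, fy = yc - j0, fz = zc - k0;
      const int i1 = i0 + 1 < n1 ? i0 + 1 : i0;
      const int j1 = j0 + 1 < n2 ? j0 + 1 : j0;
      const int k1 = k0 + 1 < n3 ? k0 + 1 : k0;
      const double *pk0 = A + (size_t)k0 * n1 * n2;
      const double *pk1 = A + (size_t)k1 * n1 * n2;
      const double c00 = pk0[i0 + n1 * j0] +
        fx * (pk0[i1 + n1 * j0] - pk0[i0 + n1 * j0]);
      const double c10 = pk0[i0 + n1 * j1] +
        fx * (pk0[i1 + n1 * j1] - pk0[i0 + n1 * j1]);
      const double c01 = pk1[i0 + n1 * j0] +
        fx * (pk1[i1 + n1 * j0] - pk1[i0 + n1 * j0]);
      const double c11 = pk1[i0 + n1 * j1] +
        fx * (pk1[i1 + n1 * j1] - pk1[i0 + n1 * j1]);
      const double c0 = c00 + fy * (c10 - c00);
      const double c1 = c01 + fy * (c11 - c01);
      P[p] = c0 + fz * (c1 - c0);
    }
  return out;
}
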