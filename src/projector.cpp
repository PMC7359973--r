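#include <Rcpp.h>
using namespace Rcpp;

// Parallel-beam projection kernels.
//
// A volume (nx x ny x nz) is viewed at one gantry angle through a
// precomputed in-plane bilinear rotation: idx (npix x 4, 0-based linear
// indices into an nx*ny slice, -1 when outside) and w (npix x 4 weights)
// map the unrotated slice onto the camera-aligned frame. In that frame the
// detector sits at +y; rays run along y, so the projection is the
// attenuation-weighted sum over y. att is the per-voxel survival factor
// exp(-integral of mu from voxel to detector) in the rotated frame, laid
// out like the rotated volume. Column pointers are used throughout: the
// weight matrices are column-major with one column per bilinear corner.

// [[Rcpp::export]]
NumericVector rotate_gather(NumericVector vol, IntegerMatrix idx,
                            NumericMatrix w, int nz) {
  const int npix = idx.nrow();
  const int *i0 = &idx[0], *i1 = &idx[npix], *i2 = &idx[2 * npix],
            *i3 = &idx[3 * npix];
  const double *w0 = &w[0], *w1 = &w[npix], *w2 = &w[2 * npix],
               *w3 = &w[3 * npix];
  NumericVector out(static_cast<R_xlen_t>(npix) * nz);
  for (int z = 0; z < nz; ++z) {
    const double* v = &vol[static_cast<R_xlen_t>(z) * npix];
    double* o = &out[static_cast<R_xlen_t>(z) * npix];
    for (int p = 0; p < npix; ++p) {
      double a = 0.0;
      int j;
      j = i0[p]; if (j >= 0) a += w0[p] * v[j];
      j = i1[p]; if (j >= 0) a += w1[p] * v[j];
      j = i2[p]; if (j >= 0) a += w2[p] * v[j];
      j = i3[p]; if (j >= 0) a += w3[p] * v[j];
      o[p] = a;
    }
  }
  return out;
}

// adjoint of rotate_gather (scatter-add)
// [[Rcpp::export]]
NumericVector rotate_scatter(NumericVector rot, IntegerMatrix idx,
                             NumericMatrix w, int nz) {
  const int npix = idx.nrow();
  const int *i0 = &idx[0], *i1 = &idx[npix], *i2 = &idx[2 * npix],
            *i3 = &idx[3 * npix];
  const double *w0 = &w[0], *w1 = &w[npix], *w2 = &w[2 * npix],
               *w3 = &w[3 * npix];
  NumericVector out(static_cast<R_xlen_t>(npix) * nz);
  for (int z = 0; z < nz; ++z) {
    const double* r = &rot[static_cast<R_xlen_t>(z) * npix];
    double* o = &out[static_cast<R_xlen_t>(z) * npix];
    for (int p = 0; p < npix; ++p) {
      const double a = r[p];
      if (a == 0.0) continue;
      int j;
      j = i0[p]; if (j >= 0) o[j] += w0[p] * a;
      j = i1[p]; if (j >= 0) o[j] += w1[p] * a;
      j = i2[p]; if (j >= 0) o[j] += w2[p] * a;
      j = i3[p]; if (j >= 0) o[j] += w3[p] * a;
    }
  }
  return out;
}

// forward (push model): each source voxel p deposits its activity onto its
// rotated position by bilinear weights (idx/w map source -> camera frame),
// is attenuated at the deposit location and lands in the detector column
// above it: det(x(j), z) += w * vol(p) * att(j, z). Because each in-bounds
// source's weights sum to one, the unattenuated projection sum equals the
// volume sum exactly at every angle.
// [[Rcpp::export]]
NumericMatrix fp_angle(NumericVector vol, IntegerMatrix idx, NumericMatrix w,
                       NumericVector att, int nx, int ny, int nz) {
  const int npix = nx * ny;
  const int *i0 = &idx[0], *i1 = &idx[npix], *i2 = &idx[2 * npix],
            *i3 = &idx[3 * npix];
  const double *w0 = &w[0], *w1 = &w[npix], *w2 = &w[2 * npix],
               *w3 = &w[3 * npix];
  NumericMatrix det(nx, nz);
  for (int z = 0; z < nz; ++z) {
    const double* v = &vol[static_cast<R_xlen_t>(z) * npix];
    const double* a = &att[static_cast<R_xlen_t>(z) * npix];
    double* dcol = &det[static_cast<R_xlen_t>(z) * nx];
    for (int p = 0; p < npix; ++p) {
      const double s = v[p];
      if (s == 0.0) continue;
      int j;
      j = i0[p]; if (j >= 0) dcol[j % nx] += w0[p] * s * a[j];
      j = i1[p]; if (j >= 0) dcol[j % nx] += w1[p] * s * a[j];
      j = i2[p]; if (j >= 0) dcol[j % nx] += w2[p] * s * a[j];
      j = i3[p]; if (j >= 0) dcol[j % nx] += w3[p] * s * a[j];
    }
  }
  return det;
}

// exact adjoint of fp_angle: vol(p) = sum_k w_k * att(j_k) * det(x(j_k), z)
// [[Rcpp::export]]
NumericVector bp_angle(NumericMatrix det, IntegerMatrix idx, NumericMatrix w,
                       NumericVector att, int nx, int ny, int nz) {
  const int npix = nx * ny;
  const int *i0 = &idx[0], *i1 = &idx[npix], *i2 = &idx[2 * npix],
            *i3 = &idx[3 * npix];
  const double *w0 = &w[0], *w1 = &w[npix], *w2 = &w[2 * npix],
               *w3 = &w[3 * npix];
  NumericVector vol(static_cast<R_xlen_t>(npix) * nz);
  for (int z = 0; z < nz; ++z) {
    const double* a = &att[static_cast<R_xlen_t>(z) * npix];
    const double* dcol = &det[static_cast<R_xlen_t>(z) * nx];
    double* v = &vol[static_cast<R_xlen_t>(z) * npix];
    for (int p = 0; p < npix; ++p) {
      double s = 0.0;
      int j;
      j = i0[p]; if (j >= 0) s += w0[p] * a[j] * dcol[j % nx];
      j = i1[p]; if (j >= 0) s += w1[p] * a[j] * dcol[j % nx];
      j = i2[p]; if (j >= 0) s += w2[p] * a[j] * dcol[j % nx];
      j = i3[p]; if (j >= 0) s += w3[p] * a[j] * dcol[j % nx];
      v[p] = s;
    }
  }
  return vol;
}

// attenuation survival factors in the rotated frame: for each (x, z) column
// along y, att(x, y, z) = exp(-dy_cm * (sum_{y' >= y} mu(x, y', z)
// - 0.5 * mu(x, y, z))). Detector at +y; half-voxel self-attenuation.
// [[Rcpp::export]]
NumericVector atten_factors(NumericVector mu_rot, double dy_cm,
                            int nx, int ny, int nz) {
  const int npix = nx * ny;
  NumericVector att(static_cast<R_xlen_t>(npix) * nz);
  for (int z = 0; z < nz; ++z) {
    const double* m = &mu_rot[static_cast<R_xlen_t>(z) * npix];
    double* a = &att[static_cast<R_xlen_t>(z) * npix];
    for (int x = 0; x < nx; ++x) {
      double cum = 0.0;
      for (int y = ny - 1; y >= 0; --y) {
        const int p = y * nx + x;
        cum += m[p];
        a[p] = std::exp(-dy_cm * (cum - 0.5 * m[p]));
      }
    }
  }
  return att;
}
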