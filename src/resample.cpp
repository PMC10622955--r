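#include <Rcpp.h>
#include "sampling.h"
using namespace Rcpp;

// Affine resampling onto a target grid. `A` is a 4x4 matrix mapping 0-based
// target voxel indices (homogeneous) to 0-based source voxel coordinates.
// interp: 0 = trilinear, 1 = nearest neighbour. Out-of-field voxels are 0.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dim_in,
                                  NumericMatrix A, IntegerVector dim_out,
                                  int interp) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* src = vol.begin();
  double* dst = out.begin();
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
  std::size_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = a00 * i + a01 * j + a02 * k + a03;
        double y = a10 * i + a11 * j + a12 * k + a13;
        double z = a20 * i + a21 * j + a22 * k + a23;
        dst[idx] = interp == 1 ? sample_nearest(src, nx, ny, nz, x, y, z)
                               : sample_trilinear(src, nx, ny, nz, x, y, z);
      }
  out.attr("dim") = dim_out;
  return out;
}

// Rigid-body transform (rotation about one axis through the grid centre plus
// a voxel shift) with trilinear interpolation; used for training augmentation.
// [[Rcpp::export]]
NumericVector cpp_rigid_transform(NumericVector vol, IntegerVector dim,
                                  double angle_deg, int axis,
                                  double tx, double ty, double tz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  rigid_resample(vol.begin(), out.begin(), nx, ny, nz,
                 angle_deg * M_PI / 180.0, axis, tx, ty, tz);
  out.attr("dim") = dim;
  return out;
}
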