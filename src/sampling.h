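#ifndef BRAINAGER_SAMPLING_H
#define BRAINAGER_SAMPLING_H

#include <cmath>
#include <cstddef>

// 0-based voxel-coordinate samplers over an x-fastest (R array order) grid.
// Coordinates outside the source field of view return 0.

static inline double vox_at(const double* v, int nx, int ny, int nz,
                            int i, int j, int k) {
  return v[(std::size_t)i + (std::size_t)nx * ((std::size_t)j + (std::size_t)ny * k)];
}

static inline double sample_nearest(const double* v, int nx, int ny, int nz,
                                    double x, double y, double z) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return vox_at(v, nx, ny, nz, i, j, k);
}

static inline double sample_trilinear(const double* v, int nx, int ny, int nz,
                                      double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < nz ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c000 = vox_at(v, nx, ny, nz, x0, y0, z0);
  double c100 = vox_at(v, nx, ny, nz, x1, y0, z0);
  double c010 = vox_at(v, nx, ny, nz, x0, y1, z0);
  double c110 = vox_at(v, nx, ny, nz, x1, y1, z0);
  double c001 = vox_at(v, nx, ny, nz, x0, y0, z1);
  double c101 = vox_at(v, nx, ny, nz, x1, y0, z1);
  double c011 = vox_at(v, nx, ny, nz, x0, y1, z1);
  double c111 = vox_at(v, nx, ny, nz, x1, y1, z1);
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Rigid transform: for each output voxel, rotate by `angle` (radians) about
// `axis` (0=x,1=y,2=z) around the grid centre, then shift by (tx,ty,tz)
// voxels; sample the source trilinearly at the inverse-mapped location.
static inline void rigid_resample(const double* src, double* dst,
                                  int nx, int ny, int nz,
                                  double angle, int axis,
                                  double tx, double ty, double tz) {
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double ca = std::cos(angle), sa = std::sin(angle);
  std::size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        // inverse map: undo translation, then inverse rotation about centre
        double x = i - tx - cx, y = j - ty - cy, z = k - tz - cz;
        double xr, yr, zr;
        if (axis == 0) {        // rotation about x
          xr = x; yr = ca * y + sa * z; zr = -sa * y + ca * z;
        } else if (axis == 1) { // about y
          xr = ca * x - sa * z; yr = y; zr = sa * x + ca * z;
        } else {                // about z
          xr = ca * x + sa * y; yr = -sa * x + ca * y; zr = z;
        }
        dst[idx] = sample_trilinear(src, nx, ny, nz, xr + cx, yr + cy, zr + cz);
      }
    }
  }
}

#endif
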