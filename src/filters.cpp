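#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x), all 0-based here.

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + (size_t)ny * x);
}

// Median filter over a k x k x k window (k odd), restricted to in-mask
// voxels: only masked voxels are replaced, and only masked neighbours
// contribute to the window, so the filter never bleeds soft-tissue HU
// into the lung at the pleural boundary. Windows are clipped at the
// volume border.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector vol, LogicalVector mask,
                                 IntegerVector dim, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel size must be odd and positive");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int h = k / 2;
  NumericVector out = clone(vol);
  std::vector<double> buf;
  buf.reserve((size_t)k * k * k);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (!mask[i]) continue;
        buf.clear();
        int z0 = std::max(0, z - h), z1 = std::min(nz - 1, z + h);
        int y0 = std::max(0, y - h), y1 = std::min(ny - 1, y + h);
        int x0 = std::max(0, x - h), x1 = std::min(nx - 1, x + h);
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy)
            for (int zz = z0; zz <= z1; ++zz) {
              int j = idx3(zz, yy, xx, nz, ny);
              if (mask[j]) buf.push_back(vol[j]);
            }
        size_t m = buf.size();
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m / 2 - 1,
                           buf.begin() + m / 2);
          med = 0.5 * (med + buf[m / 2 - 1]);
        }
        out[i] = med;
      }
    }
  }
  return out;
}

// 26-connectivity connected-component labelling of a binary volume.
// Returns integer labels, 0 = background, components numbered from 1
// in scan order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int x = i / (nz * ny);
      int rem = i - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            int j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Generic binary dilation/erosion with an arbitrary structuring element
// given as an n x 3 matrix of (dz, dy, dx) voxel offsets. Voxels outside
// the volume are treated as background.
// [[Rcpp::export]]
LogicalVector cpp_binary_morph(LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offsets, bool dilate) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int nof = offsets.nrow();
  LogicalVector out(mask.size());
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        bool acc = !dilate;  // erode: AND starts true; dilate: OR starts false
        for (int o = 0; o < nof; ++o) {
          int zz = z + offsets(o, 0), yy = y + offsets(o, 1),
              xx = x + offsets(o, 2);
          bool v = (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 &&
                    xx < nx)
                       ? (bool)mask[idx3(zz, yy, xx, nz, ny)]
                       : false;
          if (dilate) {
            if (v) { acc = true; break; }
          } else {
            if (!v) { acc = false; break; }
          }
        }
        out[i] = acc;
      }
    }
  }
  return out;
}
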