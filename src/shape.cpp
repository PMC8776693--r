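#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximum pairwise Euclidean distance between points (rows of an n x 3
// matrix of world coordinates in mm). O(n^2) over boundary voxels.
// [[Rcpp::export]]
double cpp_max_pairwise_distance(NumericMatrix pts) {
  int n = pts.nrow();
  double best = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double dx = pts(a, 0) - pts(b, 0);
      double dy = pts(a, 1) - pts(b, 1);
      double dz = pts(a, 2) - pts(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

static inline double triarea(const double *p, const double *q,
                             const double *r) {
  double ux = q[0] - p[0], uy = q[1] - p[1], uz = q[2] - p[2];
  double vx = r[0] - p[0], vy = r[1] - p[1], vz = r[2] - p[2];
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Iso-surface area of a scalar field at threshold `iso` by marching
// tetrahedra: each grid cell is split into six tetrahedra sharing the main
// diagonal, with face diagonals consistent across neighbouring cells, and the
// iso-surface is triangulated from linearly interpolated edge crossings.
// `values` is d1 x d2 x d3 column-major; spacing gives voxel size in mm.
// The caller is expected to zero-pad so the surface closes.
// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector values, IntegerVector dims,
                           NumericVector spacing, double iso) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  // cube vertex offsets, vertex v has bits (x, y, z) = (v&1, v>>1&1, v>>2&1)
  static const int tets[6][4] = {{0, 1, 5, 7}, {0, 5, 4, 7}, {0, 4, 6, 7},
                                 {0, 6, 2, 7}, {0, 2, 3, 7}, {0, 3, 1, 7}};
  double area = 0.0;
  double v[8];
  double corner[8][3];
  for (int k = 0; k + 1 < d3; ++k)
    for (int j = 0; j + 1 < d2; ++j)
      for (int i = 0; i + 1 < d1; ++i) {
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          v[c] = values[ci + d1 * (cj + d2 * ck)];
          corner[c][0] = ci * spacing[0];
          corner[c][1] = cj * spacing[1];
          corner[c][2] = ck * spacing[2];
          if (v[c] > iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (v[tv[c]] > iso) in[nin++] = tv[c];
            else out[nout++] = tv[c];
          }
          if (nin == 0 || nin == 4) continue;
          double e[4][3];
          // interpolated crossing on edge (a inside, b outside)
          #define CROSS(slot, a, b)                                        \
            {                                                              \
              double tt = (iso - v[a]) / (v[b] - v[a]);                    \
              for (int d = 0; d < 3; ++d)                                  \
                e[slot][d] = corner[a][d] + tt * (corner[b][d] - corner[a][d]); \
            }
          if (nin == 1) {
            CROSS(0, in[0], out[0]); CROSS(1, in[0], out[1]); CROSS(2, in[0], out[2]);
            area += triarea(e[0], e[1], e[2]);
          } else if (nin == 3) {
            CROSS(0, in[0], out[0]); CROSS(1, in[1], out[0]); CROSS(2, in[2], out[0]);
            area += triarea(e[0], e[1], e[2]);
          } else {  // nin == 2: quad split into two triangles
            CROSS(0, in[0], out[0]); CROSS(1, in[0], out[1]);
            CROSS(2, in[1], out[1]); CROSS(3, in[1], out[0]);
            area += triarea(e[0], e[1], e[2]);
            area += triarea(e[0], e[2], e[3]);
          }
          #undef CROSS
        }
      }
  return area;
}
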