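#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Gray-level texture matrix accumulators. All functions take a 3D integer
// label array (0 = outside ROI, 1..ng inside) in column-major layout with
// dims d1 x d2 x d3, and count only voxel pairs/neighbourhoods fully inside
// the ROI. Direction sets are passed from R so the 13-direction convention
// lives in one place.

static inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

// Co-occurrence counts per direction, symmetrized: result is ng x ng x ndir.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector labels, IntegerVector dims, int ng,
                       IntegerMatrix offsets) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int ndir = offsets.nrow();
  NumericVector out(ng * ng * ndir);
  for (int dir = 0; dir < ndir; ++dir) {
    int oi = offsets(dir, 0), oj = offsets(dir, 1), ok = offsets(dir, 2);
    double *mat = &out[ng * ng * dir];
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          int a = labels[idx3(i, j, k, d1, d2)];
          if (a == 0) continue;
          int i2 = i + oi, j2 = j + oj, k2 = k + ok;
          if (i2 < 0 || i2 >= d1 || j2 < 0 || j2 >= d2 || k2 < 0 || k2 >= d3)
            continue;
          int b = labels[idx3(i2, j2, k2, d1, d2)];
          if (b == 0) continue;
          mat[(a - 1) + ng * (b - 1)] += 1.0;
          mat[(b - 1) + ng * (a - 1)] += 1.0;  // symmetrize
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, ndir);
  return out;
}

// Run-length counts pooled over directions: ng x max_run matrix.
// A run starts where the previous voxel along the direction is outside the
// volume, outside the ROI, or a different gray level.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector labels, IntegerVector dims, int ng,
                        IntegerMatrix offsets) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int maxdim = std::max(d1, std::max(d2, d3));
  int maxrun = 3 * maxdim;  // safe upper bound for any lattice direction
  NumericMatrix out(ng, maxrun);
  int ndir = offsets.nrow();
  for (int dir = 0; dir < ndir; ++dir) {
    int oi = offsets(dir, 0), oj = offsets(dir, 1), ok = offsets(dir, 2);
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          int a = labels[idx3(i, j, k, d1, d2)];
          if (a == 0) continue;
          int ip = i - oi, jp = j - oj, kp = k - ok;
          if (ip >= 0 && ip < d1 && jp >= 0 && jp < d2 && kp >= 0 && kp < d3 &&
              labels[idx3(ip, jp, kp, d1, d2)] == a)
            continue;  // not a run start
          int len = 1;
          int i2 = i + oi, j2 = j + oj, k2 = k + ok;
          while (i2 >= 0 && i2 < d1 && j2 >= 0 && j2 < d2 && k2 >= 0 &&
                 k2 < d3 && labels[idx3(i2, j2, k2, d1, d2)] == a) {
            ++len;
            i2 += oi; j2 += oj; k2 += ok;
          }
          out(a - 1, len - 1) += 1.0;
        }
  }
  return out;
}

// Size-zone counts: zones are 26-connected components of equal gray level.
// Returns ng x max_zone_size matrix.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector labels, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = d1 * d2 * d3;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones;  // (level, size)
  int maxsize = 1;
  std::vector<int> stack;
  for (int start = 0; start < n; ++start) {
    int lev = labels[start];
    if (lev == 0 || seen[start]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int ci = cur % d1, cj = (cur / d1) % d2, ck = cur / (d1 * d2);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = ci + di, j2 = cj + dj, k2 = ck + dk;
            if (i2 < 0 || i2 >= d1 || j2 < 0 || j2 >= d2 || k2 < 0 || k2 >= d3)
              continue;
            int nb = idx3(i2, j2, k2, d1, d2);
            if (!seen[nb] && labels[nb] == lev) {
              seen[nb] = 1;
              stack.push_back(nb);
            }
          }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix out(ng, maxsize);
  for (size_t z = 0; z < zones.size(); ++z)
    out(zones[z].first - 1, zones[z].second - 1) += 1.0;
  return out;
}

// Neighbourhood gray-tone difference sums: for each level i, s_i accumulates
// |i - mean 26-neighbour level| over ROI voxels of level i, the mean taken
// over in-ROI neighbours only. Voxels with no in-ROI neighbour contribute 0
// to s_i but are still counted in n_i.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector labels, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericVector s(ng);
  IntegerVector cnt(ng);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int a = labels[idx3(i, j, k, d1, d2)];
        if (a == 0) continue;
        double sum = 0.0;
        int nnb = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (i2 < 0 || i2 >= d1 || j2 < 0 || j2 >= d2 || k2 < 0 ||
                  k2 >= d3)
                continue;
              int b = labels[idx3(i2, j2, k2, d1, d2)];
              if (b == 0) continue;
              sum += b;
              ++nnb;
            }
        cnt[a - 1] += 1;
        if (nnb > 0) s[a - 1] += std::fabs(a - sum / nnb);
      }
  return List::create(_["s"] = s, _["n"] = cnt);
}
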