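// Gray-level texture matrix accumulators for 3D masked volumes.
// Voxels carry integer levels 1..Ng; level 0 marks out-of-mask voxels.
// Directions are integer offsets (dx, dy, dz) in voxel index units.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dims, int ng,
                       IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nd = offsets.nrow();
  NumericVector out(ng * ng * nd);
  for (int d = 0; d < nd; ++d) {
    int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    double *P = &out[d * ng * ng];
    for (int z = 0; z < nz; ++z) {
      int z2 = z + dz; if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int y2 = y + dy; if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          int x2 = x + dx; if (x2 < 0 || x2 >= nx) continue;
          int a = levels[idx3(x, y, z, nx, ny)];
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (a > 0 && b > 0) {
            // symmetric accumulation
            P[(a - 1) + ng * (b - 1)] += 1.0;
            P[(b - 1) + ng * (a - 1)] += 1.0;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, nd);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dims, int ng,
                        IntegerMatrix directions, int maxlen) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nd = directions.nrow();
  NumericVector out(ng * maxlen * nd);
  for (int d = 0; d < nd; ++d) {
    int dx = directions(d, 0), dy = directions(d, 1), dz = directions(d, 2);
    double *P = &out[d * ng * maxlen];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int lev = levels[idx3(x, y, z, nx, ny)];
          if (lev == 0) continue;
          // run starts here iff the predecessor is outside the grid/mask
          // or has a different level
          int px = x - dx, py = y - dy, pz = z - dz;
          bool start = true;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz) {
            if (levels[idx3(px, py, pz, nx, ny)] == lev) start = false;
          }
          if (!start) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
                 levels[idx3(cx, cy, cz, nx, ny)] == lev) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          if (len > maxlen) len = maxlen;
          P[(lev - 1) + ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, nd);
  return out;
}

// zones: 26-connected components of constant level; returns (level, size) rows
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] == 0) continue;
    int lev = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            int w = idx3(x2, y2, z2, nx, ny);
            if (!seen[w] && levels[w] == lev) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zl.push_back(lev);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  return out;
}

// dependence counts: for each in-mask voxel, the number of 26-neighbours in
// mask within |level difference| <= alpha; returns (level, count) rows
// [[Rcpp::export]]
IntegerMatrix cpp_gldm_deps(IntegerVector levels, IntegerVector dims, int alpha) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> vl, vc;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int lev = levels[idx3(x, y, z, nx, ny)];
        if (lev == 0) continue;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int l2 = levels[idx3(x2, y2, z2, nx, ny)];
              if (l2 > 0 && std::abs(l2 - lev) <= alpha) ++cnt;
            }
        vl.push_back(lev);
        vc.push_back(cnt);
      }
  IntegerMatrix out(vl.size(), 2);
  for (size_t i = 0; i < vl.size(); ++i) { out(i, 0) = vl[i]; out(i, 1) = vc[i]; }
  return out;
}

// neighbouring gray-tone difference: per level i, voxel count n_i and the
// accumulated |i - mean(neighbour levels)|; neighbours restricted to the mask
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);  // columns: n_i, s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int lev = levels[idx3(x, y, z, nx, ny)];
        if (lev == 0) continue;
        double sum = 0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int l2 = levels[idx3(x2, y2, z2, nx, ny)];
              if (l2 > 0) { sum += l2; ++cnt; }
            }
        if (cnt > 0) {
          out(lev - 1, 0) += 1.0;
          out(lev - 1, 1) += std::fabs(lev - sum / cnt);
        }
      }
  return out;
}
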