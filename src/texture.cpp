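// Grey-level texture matrix accumulation for 3-D discretized images.
// Images are integer arrays with levels 1..ng inside the mask and 0 outside.
// All matrices aggregate over the 13 unique 3-D offsets (26-connectivity),
// i.e. the "merged" aggregation of the IBSI framework.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static const int OFF[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export(name = ".glcm_cpp")]]
NumericMatrix glcm_cpp(IntegerVector img, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix P(ng, ng);
  for (int d = 0; d < 13; ++d) {
    int dx = OFF[d][0], dy = OFF[d][1], dz = OFF[d][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = img[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        int b = img[idx3(x2, y2, z2, nx, ny)];
        if (b == 0) continue;
        P(a - 1, b - 1) += 1.0;  // symmetric accumulation
        P(b - 1, a - 1) += 1.0;
      }
  }
  return P;
}

// [[Rcpp::export(name = ".glrlm_cpp")]]
NumericMatrix glrlm_cpp(IntegerVector img, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxrun = nx + ny + nz;
  NumericMatrix P(ng, maxrun);
  for (int d = 0; d < 13; ++d) {
    int dx = OFF[d][0], dy = OFF[d][1], dz = OFF[d][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = img[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        // run start: predecessor along -d is outside grid/mask or differs
        int xp = x - dx, yp = y - dy, zp = z - dz;
        bool start = xp < 0 || xp >= nx || yp < 0 || yp >= ny || zp < 0 || zp >= nz;
        if (!start && img[idx3(xp, yp, zp, nx, ny)] != a) start = true;
        if (!start) continue;
        int len = 1;
        int xc = x + dx, yc = y + dy, zc = z + dz;
        while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 && zc < nz &&
               img[idx3(xc, yc, zc, nx, ny)] == a) {
          ++len; xc += dx; yc += dy; zc += dz;
        }
        if (len > maxrun) len = maxrun;
        P(a - 1, len - 1) += 1.0;
      }
  }
  return P;
}

// [[Rcpp::export(name = ".glszm_cpp")]]
NumericMatrix glszm_cpp(IntegerVector img, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,int> > zones;  // (level, size)
  int maxzone = 1;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int i0 = idx3(x, y, z, nx, ny);
      int a = img[i0];
      if (a == 0 || seen[i0]) continue;
      // 26-connected flood fill of equal-level voxels
      int size = 0;
      std::queue<int> q;
      q.push(i0); seen[i0] = 1;
      while (!q.empty()) {
        int i = q.front(); q.pop();
        ++size;
        int zx = i % nx, zy = (i / nx) % ny, zz = i / (nx * ny);
        for (int dz2 = -1; dz2 <= 1; ++dz2)
          for (int dy2 = -1; dy2 <= 1; ++dy2)
            for (int dx2 = -1; dx2 <= 1; ++dx2) {
              if (!dx2 && !dy2 && !dz2) continue;
              int x2 = zx + dx2, y2 = zy + dy2, z2 = zz + dz2;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int j = idx3(x2, y2, z2, nx, ny);
              if (!seen[j] && img[j] == a) { seen[j] = 1; q.push(j); }
            }
      }
      zones.push_back(std::make_pair(a, size));
      if (size > maxzone) maxzone = size;
    }
  NumericMatrix P(ng, maxzone);
  for (size_t k = 0; k < zones.size(); ++k)
    P(zones[k].first - 1, zones[k].second - 1) += 1.0;
  return P;
}

// [[Rcpp::export(name = ".gldm_cpp")]]
NumericMatrix gldm_cpp(IntegerVector img, IntegerVector dims, int ng, int alpha) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix P(ng, 27);  // dependence 0..26 -> columns 1..27
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int a = img[idx3(x, y, z, nx, ny)];
      if (a == 0) continue;
      int dep = 0;
      for (int dz2 = -1; dz2 <= 1; ++dz2)
        for (int dy2 = -1; dy2 <= 1; ++dy2)
          for (int dx2 = -1; dx2 <= 1; ++dx2) {
            if (!dx2 && !dy2 && !dz2) continue;
            int x2 = x + dx2, y2 = y + dy2, z2 = z + dz2;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int b = img[idx3(x2, y2, z2, nx, ny)];
            if (b != 0 && std::abs(b - a) <= alpha) ++dep;
          }
      P(a - 1, dep) += 1.0;
    }
  return P;
}

// [[Rcpp::export(name = ".ngtdm_cpp")]]
NumericMatrix ngtdm_cpp(IntegerVector img, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);  // column 0: n_i, column 1: s_i
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int a = img[idx3(x, y, z, nx, ny)];
      if (a == 0) continue;
      double sum = 0.0; int cnt = 0;
      for (int dz2 = -1; dz2 <= 1; ++dz2)
        for (int dy2 = -1; dy2 <= 1; ++dy2)
          for (int dx2 = -1; dx2 <= 1; ++dx2) {
            if (!dx2 && !dy2 && !dz2) continue;
            int x2 = x + dx2, y2 = y + dy2, z2 = z + dz2;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int b = img[idx3(x2, y2, z2, nx, ny)];
            if (b != 0) { sum += b; ++cnt; }
          }
      out(a - 1, 0) += 1.0;
      if (cnt > 0) out(a - 1, 1) += std::fabs(a - sum / cnt);
    }
  return out;
}
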