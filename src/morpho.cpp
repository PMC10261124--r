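#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 3D morphological primitives shared by the instance-splitting stage.
// All arrays arrive as flat vectors with dims (X, Y, Z), R column-major:
// index = x + X * (y + Y * z), 0-based here.

static inline int idx3(int x, int y, int z, int X, int Y) {
  return x + X * (y + Y * z);
}

// Connected-component labeling of a binary volume.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dims,
                           int connectivity = 26) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  IntegerVector lab(n, 0);

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nn = (int)dx.size();

  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (X * Y), rem = cur % (X * Y);
      int y = rem / X, x = rem % X;
      for (int k = 0; k < nn; ++k) {
        int qx = x + dx[k], qy = y + dy[k], qz = z + dz[k];
        if (qx < 0 || qy < 0 || qz < 0 || qx >= X || qy >= Y || qz >= Z)
          continue;
        int q = idx3(qx, qy, qz, X, Y);
        if (mask[q] != 0 && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f is INF where no site.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb) {
  const int n = (int)f.size();
  const double INF = 1e20;
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance of each foreground voxel to the nearest
// background voxel (0 on background). Isotropic voxel spacing.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  const double INF = 1e20;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? INF : 0.0;

  int m = std::max(std::max(X, Y), Z);
  std::vector<double> f(m), d(m), zb(m + 1);
  std::vector<int> v(m);

  // pass along x
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      for (int x = 0; x < X; ++x) f[x] = out[idx3(x, y, z, X, Y)];
      f.resize(X); d.resize(X);
      dt1d(f, d, v, zb);
      for (int x = 0; x < X; ++x) out[idx3(x, y, z, X, Y)] = d[x];
      f.resize(m); d.resize(m);
    }
  // pass along y
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      for (int y = 0; y < Y; ++y) f[y] = out[idx3(x, y, z, X, Y)];
      f.resize(Y); d.resize(Y);
      dt1d(f, d, v, zb);
      for (int y = 0; y < Y; ++y) out[idx3(x, y, z, X, Y)] = d[y];
      f.resize(m); d.resize(m);
    }
  // pass along z
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      for (int z = 0; z < Z; ++z) f[z] = out[idx3(x, y, z, X, Y)];
      f.resize(Z); d.resize(Z);
      dt1d(f, d, v, zb);
      for (int z = 0; z < Z; ++z) out[idx3(x, y, z, X, Y)] = d[z];
      f.resize(m); d.resize(m);
    }
  // Border voxels with no background anywhere stay at INF only when the
  // mask is all-foreground; clamp to squared distance to volume border.
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= INF) {
      int z = (int)(i / ((R_xlen_t)X * Y)), rem = (int)(i % ((R_xlen_t)X * Y));
      int y = rem / X, x = rem % X;
      double b = 1.0 + std::min(std::min(std::min(x, X - 1 - x),
                                         std::min(y, Y - 1 - y)),
                                std::min(z, Z - 1 - z));
      out[i] = b * b;
    }
  return out;
}

struct WsNode {
  double elev;
  uint64_t order;
  int index;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;   // min-heap on elevation
    return a.order > b.order;                       // FIFO tie-break
  }
};

// Marker-controlled watershed: flood the elevation surface from labeled
// markers, restricted to mask foreground. 6-connected flooding; every
// reachable foreground voxel gets the label of the basin that reaches it
// first (lowest elevation, FIFO on ties) — deterministic.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector elev, IntegerVector markers,
                            IntegerVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  uint64_t counter = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (markers[i] != 0 && mask[i] != 0) {
      lab[i] = markers[i];
      pq.push(WsNode{elev[i], counter++, (int)i, markers[i]});
    }
  }
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};

  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int cur = nd.index;
    int z = cur / (X * Y), rem = cur % (X * Y);
    int y = rem / X, x = rem % X;
    for (int k = 0; k < 6; ++k) {
      int qx = x + dx[k], qy = y + dy[k], qz = z + dz[k];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= X || qy >= Y || qz >= Z)
        continue;
      int q = idx3(qx, qy, qz, X, Y);
      if (mask[q] != 0 && lab[q] == 0) {
        lab[q] = nd.label;
        // flood never descends below the level already reached
        double e = elev[q] > nd.elev ? elev[q] : nd.elev;
        pq.push(WsNode{e, counter++, q, nd.label});
      }
    }
  }
  return lab;
}
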