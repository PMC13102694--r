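#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Volumes are R arrays with dim (nz, ny, nx); element (z,y,x) sits at
// linear index z + nz*(y + ny*x), 0-based. Physical position of voxel
// center (z,y,x) is (z*dz, y*dy, x*dx) in micrometres.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 26-connected neighbour offsets
static const int NB[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
  {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
  {0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},{1,-1,-1},
  {1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},{1,1,0},{1,1,1}
};

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  // pts: n x 3 matrix of 0-based fractional voxel-index coordinates (z,y,x).
  // Coordinates are clamped to the volume bounds (boundary-clamp policy).
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double pz = pts(i, 0), py = pts(i, 1), px = pts(i, 2);
    if (pz < 0) pz = 0; if (pz > nz - 1) pz = nz - 1;
    if (py < 0) py = 0; if (py > ny - 1) py = ny - 1;
    if (px < 0) px = 0; if (px > nx - 1) px = nx - 1;
    int z0 = (int)std::floor(pz), y0 = (int)std::floor(py),
        x0 = (int)std::floor(px);
    int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
        x1 = std::min(x0 + 1, nx - 1);
    double fz = pz - z0, fy = py - y0, fx = px - x0;
    double c000 = vol[lin(z0, y0, x0, nz, ny)], c001 = vol[lin(z0, y0, x1, nz, ny)];
    double c010 = vol[lin(z0, y1, x0, nz, ny)], c011 = vol[lin(z0, y1, x1, nz, ny)];
    double c100 = vol[lin(z1, y0, x0, nz, ny)], c101 = vol[lin(z1, y0, x1, nz, ny)];
    double c110 = vol[lin(z1, y1, x0, nz, ny)], c111 = vol[lin(z1, y1, x1, nz, ny)];
    double c00 = c000 * (1 - fx) + c001 * fx;
    double c01 = c010 * (1 - fx) + c011 * fx;
    double c10 = c100 * (1 - fx) + c101 * fx;
    double c11 = c110 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c01 * fy;
    double c1 = c10 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// apply op to every line along `axis`: gather into a contiguous buffer,
// transform, scatter back
template <typename F>
static void for_each_line(std::vector<double> &vol, int nz, int ny, int nx,
                          int axis, F op) {
  int n[3] = {nz, ny, nx};
  int len = n[axis];
  int stride = axis == 0 ? 1 : (axis == 1 ? nz : nz * ny);
  std::vector<double> in(len), out(len);
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 2 ? ny : nx;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      int base;
      if (axis == 0) base = lin(0, i, j, nz, ny);
      else if (axis == 1) base = lin(i, 0, j, nz, ny);
      else base = lin(i, j, 0, nz, ny);
      for (int t = 0; t < len; ++t) in[t] = vol[base + t * stride];
      op(in, out);
      for (int t = 0; t < len; ++t) vol[base + t * stride] = out[t];
    }
}

static void blur_axis_inplace(std::vector<double> &vol, int nz, int ny,
                              int nx, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  for_each_line(vol, nz, ny, nx, axis,
    [&](std::vector<double> &in, std::vector<double> &out) {
      int len = (int)in.size();
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        if (t >= r && t + r < len) {
          const double *p = &in[t - r];
          for (int j = 0; j <= 2 * r; ++j) acc += k[j] * p[j];
        } else {
          for (int j = -r; j <= r; ++j) {
            int u = t + j;
            if (u < 0) u = 0; else if (u >= len) u = len - 1; // replicate
            acc += k[j + r] * in[u];
          }
        }
        out[t] = acc;
      }
    });
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dim,
                             NumericVector sigma_vox) {
  // separable Gaussian blur; sigma_vox = (sz, sy, sx) in voxel units
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis)
    blur_axis_inplace(a, nz, ny, nx, axis, sigma_vox[axis]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_box_mean(NumericVector vol, IntegerVector dim,
                           IntegerVector radius_vox) {
  // separable running-mean filter (edge-shrunk window), O(1) per voxel
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis) {
    int r = radius_vox[axis];
    if (r <= 0) continue;
    for_each_line(a, nz, ny, nx, axis,
      [&](std::vector<double> &in, std::vector<double> &out) {
        int len = (int)in.size();
        std::vector<double> cs(len + 1, 0.0);
        for (int t = 0; t < len; ++t) cs[t + 1] = cs[t] + in[t];
        for (int t = 0; t < len; ++t) {
          int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
          out[t] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
        }
      });
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_splat(NumericVector vol, IntegerVector dim,
                        NumericVector spacing, NumericMatrix pts,
                        NumericVector w, double sigma_um) {
  // Deposit, for each point (z,y,x in um), a unit-mass spherical Gaussian
  // of physical sigma sigma_um scaled by w[i]. Mass is normalised over the
  // in-bounds support so total added intensity equals sum(w).
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  NumericVector out = clone(vol);
  int rz = std::max(1, (int)std::ceil(3.0 * sigma_um / dz));
  int ry = std::max(1, (int)std::ceil(3.0 * sigma_um / dy));
  int rx = std::max(1, (int)std::ceil(3.0 * sigma_um / dx));
  double inv2s2 = 1.0 / (2.0 * sigma_um * sigma_um);
  for (int i = 0; i < pts.nrow(); ++i) {
    double pz = pts(i, 0) / dz, py = pts(i, 1) / dy, px = pts(i, 2) / dx;
    int z0 = std::max(0, (int)std::floor(pz) - rz),
        z1 = std::min(nz - 1, (int)std::ceil(pz) + rz);
    int y0 = std::max(0, (int)std::floor(py) - ry),
        y1 = std::min(ny - 1, (int)std::ceil(py) + ry);
    int x0 = std::max(0, (int)std::floor(px) - rx),
        x1 = std::min(nx - 1, (int)std::ceil(px) + rx);
    if (z1 < z0 || y1 < y0 || x1 < x0) continue;
    double norm = 0;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double ddz = (z - pz) * dz, ddy = (y - py) * dy, ddx = (x - px) * dx;
          norm += std::exp(-(ddz * ddz + ddy * ddy + ddx * ddx) * inv2s2);
        }
    if (norm <= 0) continue;
    double scale = w[i] / norm;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double ddz = (z - pz) * dz, ddy = (y - py) * dy, ddx = (x - px) * dx;
          out[lin(z, y, x, nz, ny)] +=
            scale * std::exp(-(ddz * ddz + ddy * ddy + ddx * ddx) * inv2s2);
        }
  }
  out.attr("dim") = dim;
  return out;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform on a sampled grid
static void dt1d(std::vector<double> &f, double step, std::vector<double> &d) {
  int n = (int)f.size();
  d.assign(n, 0);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qq = q * step;
    double s;
    while (true) {
      double vp = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vp * vp)) / (2 * qq - 2 * vp);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * step;
    while (zb[k + 1] < qq) ++k;
    double vp = v[k] * step;
    d[q] = (qq - vp) * (qq - vp) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  // Euclidean distance (um) from each foreground voxel to the nearest
  // background voxel, computed with physical anisotropic spacing.
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const double INF = 1e18;
  std::vector<double> g(mask.size());
  for (int i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;
  std::vector<double> line, out;
  // z axis
  line.resize(nz); out.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) line[z] = g[lin(z, y, x, nz, ny)];
      dt1d(line, spacing[0], out);
      for (int z = 0; z < nz; ++z) g[lin(z, y, x, nz, ny)] = out[z];
    }
  // y axis
  line.resize(ny); out.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = g[lin(z, y, x, nz, ny)];
      dt1d(line, spacing[1], out);
      for (int y = 0; y < ny; ++y) g[lin(z, y, x, nz, ny)] = out[y];
    }
  // x axis
  line.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) line[x] = g[lin(z, y, x, nz, ny)];
      dt1d(line, spacing[2], out);
      for (int x = 0; x < nx; ++x) g[lin(z, y, x, nz, ny)] = out[x];
    }
  NumericVector res(g.size());
  for (size_t i = 0; i < g.size(); ++i)
    res[i] = g[i] >= 1e17 ? 0.0 : std::sqrt(g[i]);
  res.attr("dim") = dim;
  return res;
}

// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim) {
  // 26-connected component labelling by BFS
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int c = stack.back(); stack.pop_back();
          int cx = c / (nz * ny), rem = c % (nz * ny);
          int cy = rem / nz, cz = rem % nz;
          for (int k = 0; k < 26; ++k) {
            int zz = cz + NB[k][0], yy = cy + NB[k][1], xx = cx + NB[k][2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int j = lin(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

struct WsNode {
  double h;
  long long order;
  int idx;
  bool operator<(const WsNode &o) const {
    if (h != o.h) return h > o.h;       // min-heap on height
    return order > o.order;             // FIFO tie-break -> deterministic
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector height, LogicalVector mask,
                            IntegerVector markers, IntegerVector dim) {
  // Marker-based watershed: flood `mask` from `markers` (label volume,
  // 0 = unlabelled) in ascending `height` order.
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab = clone(markers);
  std::priority_queue<WsNode> pq;
  long long order = 0;
  for (int i = 0; i < markers.size(); ++i)
    if (markers[i] > 0 && mask[i]) pq.push({height[i], order++, i});
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int c = nd.idx;
    int cx = c / (nz * ny), rem = c % (nz * ny);
    int cy = rem / nz, cz = rem % nz;
    for (int k = 0; k < 26; ++k) {
      int zz = cz + NB[k][0], yy = cy + NB[k][1], xx = cx + NB[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = lin(zz, yy, xx, nz, ny);
      if (mask[j] && lab[j] == 0) {
        lab[j] = lab[c];
        pq.push({height[j], order++, j});
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector field, LogicalVector mask,
                               IntegerVector dim) {
  // 1-based linear indices of voxels >= all 26 in-mask neighbours
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> out;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!mask[i]) continue;
        double v = field[i];
        bool ismax = true;
        for (int k = 0; k < 26 && ismax; ++k) {
          int zz = z + NB[k][0], yy = y + NB[k][1], xx = x + NB[k][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          int j = lin(zz, yy, xx, nz, ny);
          if (mask[j] && field[j] > v) ismax = false;
        }
        if (ismax) out.push_back(i + 1);
      }
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_geodesic_sweep(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing, int start) {
  // Dijkstra over the 26-connected voxel graph of `mask` with physical
  // edge lengths. start: 0-based linear index (-1 -> first mask voxel).
  // Returns distances (um, NA outside / unreached), farthest voxel (1-based)
  // and predecessor array (1-based, 0 at the source).
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = mask.size();
  if (start < 0) {
    for (int i = 0; i < n; ++i) if (mask[i]) { start = i; break; }
  }
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> pred(n, -1);
  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  dist[start] = 0;
  pq.push(QN(0.0, start));
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    int c = top.second;
    if (top.first > dist[c] + 1e-12) continue;
    int cx = c / (nz * ny), rem = c % (nz * ny);
    int cy = rem / nz, cz = rem % nz;
    for (int k = 0; k < 26; ++k) {
      int zz = cz + NB[k][0], yy = cy + NB[k][1], xx = cx + NB[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = lin(zz, yy, xx, nz, ny);
      if (!mask[j]) continue;
      double w = std::sqrt(NB[k][0] * NB[k][0] * dz * dz +
                           NB[k][1] * NB[k][1] * dy * dy +
                           NB[k][2] * NB[k][2] * dx * dx);
      if (dist[c] + w < dist[j] - 1e-12) {
        dist[j] = dist[c] + w;
        pred[j] = c;
        pq.push(QN(dist[j], j));
      }
    }
  }
  int far = start;
  double dmax = 0;
  for (int i = 0; i < n; ++i)
    if (mask[i] && std::isfinite(dist[i]) && dist[i] > dmax) {
      dmax = dist[i];
      far = i;
    }
  NumericVector dv(n, NA_REAL);
  IntegerVector pv(n, 0);
  for (int i = 0; i < n; ++i) {
    if (std::isfinite(dist[i])) dv[i] = dist[i];
    pv[i] = pred[i] + 1;
  }
  return List::create(_["dist"] = dv, _["farthest"] = far + 1,
                      _["pred"] = pv, _["max_dist"] = dmax);
}
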