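#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
#include <cmath>

using namespace Rcpp;

// Arrays are indexed (z, y, x) to match the stack convention used on the R side;
// R stores them column-major so z is the fastest-moving index.

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 26-connected labelling of a 3D logical array (BFS). A 2D array passed with
// nz = 1 reduces to 8-connected 2D labelling.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        int p = idx3(z0, y0, x0, nz, ny);
        if (!mask[p] || lab[p]) continue;
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back(); stack.pop_back();
          int z = q % nz, rest = q / nz, y = rest % ny, x = rest / ny;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (!dx && !dy && !dz) continue;
                int zz = z + dz, yy = y + dy, xx = x + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                  continue;
                int r = idx3(zz, yy, xx, nz, ny);
                if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Fill holes independently in each z slice: background pixels (4-connected in y/x)
// not reachable from the slice border become foreground.
// [[Rcpp::export(name = ".fill_holes_slices_cpp")]]
LogicalVector fill_holes_slices_cpp(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out = clone(mask);
  std::vector<char> open(ny * nx);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(open.begin(), open.end(), 0);
    stack.clear();
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1) continue;
        if (!mask[idx3(z, y, x, nz, ny)] && !open[y + ny * x]) {
          open[y + ny * x] = 1;
          stack.push_back(y + ny * x);
        }
      }
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      int y = q % ny, x = q / ny;
      const int dy[4] = {1, -1, 0, 0}, dx[4] = {0, 0, 1, -1};
      for (int d = 0; d < 4; ++d) {
        int yy = y + dy[d], xx = x + dx[d];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int r = yy + ny * xx;
        if (!mask[idx3(z, yy, xx, nz, ny)] && !open[r]) {
          open[r] = 1;
          stack.push_back(r);
        }
      }
    }
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        if (!open[y + ny * x]) out[idx3(z, y, x, nz, ny)] = TRUE;
  }
  return out;
}

// Strict local maxima within a 1-voxel radius (26-neighbourhood); border voxels
// compare against available neighbours only. Returns 1-based (z, y, x) indices.
// [[Rcpp::export(name = ".local_maxima_cpp")]]
IntegerMatrix local_maxima_cpp(NumericVector img, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double v = img[idx3(z, y, x, nz, ny)];
        if (v <= 0.0) continue;
        bool is_max = true;
        for (int dx = -1; dx <= 1 && is_max; ++dx)
          for (int dy = -1; dy <= 1 && is_max; ++dy)
            for (int dz = -1; dz <= 1 && is_max; ++dz) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              if (img[idx3(zz, yy, xx, nz, ny)] >= v) is_max = false;
            }
        if (is_max) hits.push_back(idx3(z, y, x, nz, ny));
      }
  IntegerMatrix out(hits.size(), 3);
  for (size_t i = 0; i < hits.size(); ++i) {
    int q = hits[i];
    out(i, 0) = q % nz + 1;
    out(i, 1) = (q / nz) % ny + 1;
    out(i, 2) = q / (nz * ny) + 1;
  }
  return out;
}

// Seeded propagation over a 2D support: every foreground pixel is assigned to the
// seed with the cheapest geodesic cost, where stepping between 8-neighbours p -> q
// costs sqrt((I(p) - I(q))^2 + reg * d^2) with d the Euclidean step length. The
// regularisation weight trades intensity homogeneity against plain distance; in a
// uniform-intensity corridor the boundary falls on the equidistant midline.
// [[Rcpp::export(name = ".propagate_cpp")]]
IntegerMatrix propagate_cpp(NumericMatrix intensity, IntegerMatrix seeds,
                            LogicalMatrix support, double reg) {
  int ny = intensity.nrow(), nx = intensity.ncol();
  IntegerMatrix lab(ny, nx);
  NumericMatrix cost(ny, nx);
  std::fill(cost.begin(), cost.end(), R_PosInf);
  typedef std::tuple<double, int, int> Node;  // cost, pixel, label
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if (seeds(y, x) > 0) {
        lab(y, x) = seeds(y, x);
        cost(y, x) = 0.0;
        pq.push(Node(0.0, y + ny * x, seeds(y, x)));
      }
  const int dy[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dx[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const double dd[8] = {1, 1, 1, 1, 2, 2, 2, 2};  // squared step lengths
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    double c = std::get<0>(nd);
    int p = std::get<1>(nd), l = std::get<2>(nd);
    int y = p % ny, x = p / ny;
    if (c > cost(y, x)) continue;
    for (int d = 0; d < 8; ++d) {
      int yy = y + dy[d], xx = x + dx[d];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      if (!support(yy, xx)) continue;
      double di = intensity(y, x) - intensity(yy, xx);
      double step = std::sqrt(di * di + reg * dd[d]);
      double nc = c + step;
      if (nc < cost(yy, xx)) {
        cost(yy, xx) = nc;
        lab(yy, xx) = l;
        pq.push(Node(nc, yy + ny * xx, l));
      }
    }
  }
  return lab;
}
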