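#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays with dim = c(ny, nx, nz): index = y + ny*x + ny*nx*z.

static inline R_xlen_t idx3(int y, int x, int z, int ny, int nx) {
  return (R_xlen_t)y + (R_xlen_t)ny * x + (R_xlen_t)ny * (R_xlen_t)nx * z;
}

// Connected-component labelling of a logical 3D array.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns integer array of labels (0 = background), labelled 1..n in
// first-encounter (column-major scan) order so results are deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;

  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int m = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dy, dx, dz});
      }

  int next = 0;
  std::queue<std::array<int, 3> > q;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = idx3(y, x, z, ny, nx);
        if (!mask[i] || labels[i]) continue;
        labels[i] = ++next;
        q.push({y, x, z});
        while (!q.empty()) {
          std::array<int, 3> v = q.front(); q.pop();
          for (size_t k = 0; k < offs.size(); ++k) {
            int yy = v[0] + offs[k][0], xx = v[1] + offs[k][1],
                zz = v[2] + offs[k][2];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            R_xlen_t j = idx3(yy, xx, zz, ny, nx);
            if (mask[j] && !labels[j]) { labels[j] = next; q.push({yy, xx, zz}); }
          }
        }
      }
  labels.attr("n_components") = next;
  return labels;
}

// Separable Gaussian blur with reflected boundaries; kernel truncated at
// 4 sigma. sigma in voxels; sigma = 0 returns the input unchanged.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dims,
                                double sigma) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out = clone(vol);
  out.attr("dim") = dims;
  if (sigma <= 0) return out;

  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= s;

  std::vector<double> buf(n);
  const int dimlen[3] = {ny, nx, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)ny, (R_xlen_t)ny * nx};

  for (int axis = 0; axis < 3; ++axis) {
    int len = dimlen[axis];
    R_xlen_t st = stride[axis];
    for (R_xlen_t i = 0; i < n; ++i) buf[i] = out[i];
    // iterate over all lines along `axis`
    for (R_xlen_t base = 0; base < n; ++base) {
      // position along axis of this element
      int pos = (int)((base / st) % len);
      if (pos != 0) continue;  // only start-of-line elements
      for (int p = 0; p < len; ++p) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int pp = p + j;
          if (pp < 0) pp = -pp - 1;            // reflect
          if (pp >= len) pp = 2 * len - pp - 1;
          acc += k[j + r] * buf[base + (R_xlen_t)pp * st];
        }
        out[base + (R_xlen_t)p * st] = acc;
      }
    }
  }
  return out;
}

// --- marching tetrahedra surface area ---------------------------------
// Each grid cube is split into 6 tetrahedra sharing the main diagonal;
// the level surface is triangulated by linear interpolation along tet
// edges. Voxel values are point samples at integer coordinates.

static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
static const double CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

static inline void edge_interp(const double *p1, const double *p2,
                               double v1, double v2, double level,
                               double *out) {
  double t = (level - v1) / (v2 - v1);
  for (int i = 0; i < 3; ++i) out[i] = p1[i] + t * (p2[i] - p1[i]);
}

static inline double tri_area(const double *a, const double *b,
                              const double *c) {
  double u[3], v[3], w[3];
  for (int i = 0; i < 3; ++i) { u[i] = b[i] - a[i]; v[i] = c[i] - a[i]; }
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// Surface area (in voxel units squared) of the `field > level` iso-surface.
// [[Rcpp::export]]
double cpp_mesh_area(NumericVector field, IntegerVector dims, double level) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  double total = 0;
  double pts[4][3], vals[4], q[4][3];
  for (int z = 0; z + 1 < nz; ++z)
    for (int x = 0; x + 1 < nx; ++x)
      for (int y = 0; y + 1 < ny; ++y) {
        double cv[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cv[c] = field[idx3(y + (int)CORNER[c][1], x + (int)CORNER[c][0],
                             z + (int)CORNER[c][2], ny, nx)];
          (cv[c] > level) ? (any_in = true) : (any_out = true);
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int nin = 0, in_i[4], out_i[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            vals[c] = cv[TETS[t][c]];
            for (int d = 0; d < 3; ++d) pts[c][d] = CORNER[TETS[t][c]][d];
            if (vals[c] > level) in_i[nin++] = c; else out_i[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in_i[0] : out_i[0];
            int m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != a) edge_interp(pts[a], pts[c], vals[a], vals[c],
                                      level, q[m++]);
            total += tri_area(q[0], q[1], q[2]);
          } else {  // 2 in, 2 out: quad split into two triangles
            int a = in_i[0], b = in_i[1], c = out_i[0], d = out_i[1];
            edge_interp(pts[a], pts[c], vals[a], vals[c], level, q[0]);
            edge_interp(pts[a], pts[d], vals[a], vals[d], level, q[1]);
            edge_interp(pts[b], pts[d], vals[b], vals[d], level, q[2]);
            edge_interp(pts[b], pts[c], vals[b], vals[c], level, q[3]);
            total += tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
          }
        }
      }
  return total;
}
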