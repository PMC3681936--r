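#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Seeded region growing ("wildfire"): 4-connected BFS over pixels whose
// intensity differs from the SEED pixel by at most tol. Row/col are 1-based.
// [[Rcpp::export(name = ".wildfire_fill_cpp")]]
LogicalMatrix wildfire_fill_cpp(NumericMatrix img, int seed_r, int seed_c,
                                double tol) {
  int nr = img.nrow(), nc = img.ncol();
  if (seed_r < 1 || seed_r > nr || seed_c < 1 || seed_c > nc)
    stop("seed outside image");
  LogicalMatrix mask(nr, nc);
  double s = img(seed_r - 1, seed_c - 1);
  std::queue<std::pair<int, int> > q;
  mask(seed_r - 1, seed_c - 1) = true;
  q.push(std::make_pair(seed_r - 1, seed_c - 1));
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 4; ++k) {
      int r = p.first + dr[k], c = p.second + dc[k];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      if (mask(r, c)) continue;
      if (std::fabs(img(r, c) - s) <= tol) {
        mask(r, c) = true;
        q.push(std::make_pair(r, c));
      }
    }
  }
  return mask;
}

// Ray-parity containment: for each query point count crossings of a fixed
// slightly-irrational ray with the triangle soup; odd => inside.
// faces are 1-based vertex indices.
// [[Rcpp::export(name = ".points_in_mesh_cpp")]]
LogicalVector points_in_mesh_cpp(NumericMatrix pts, NumericMatrix verts,
                                 IntegerMatrix faces) {
  int np = pts.nrow(), nf = faces.nrow();
  LogicalVector inside(np);
  // fixed irrational-ish direction avoids edge/vertex-coplanar degeneracies
  double dx = 0.57735026919, dy = 0.52573111212, dz = 0.62348980185;
  double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
  dx /= nrm; dy /= nrm; dz /= nrm;
  const double eps = 1e-12;
  for (int i = 0; i < np; ++i) {
    double ox = pts(i, 0), oy = pts(i, 1), oz = pts(i, 2);
    int crossings = 0;
    bool onsurf = false;
    for (int f = 0; f < nf; ++f) {
      int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
      double e1x = verts(b, 0) - verts(a, 0);
      double e1y = verts(b, 1) - verts(a, 1);
      double e1z = verts(b, 2) - verts(a, 2);
      double e2x = verts(c, 0) - verts(a, 0);
      double e2y = verts(c, 1) - verts(a, 1);
      double e2z = verts(c, 2) - verts(a, 2);
      // Moller-Trumbore
      double px = dy * e2z - dz * e2y;
      double py = dz * e2x - dx * e2z;
      double pz = dx * e2y - dy * e2x;
      double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tx = ox - verts(a, 0);
      double ty = oy - verts(a, 1);
      double tz = oz - verts(a, 2);
      double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double qx = ty * e1z - tz * e1y;
      double qy = tz * e1x - tx * e1z;
      double qz = tx * e1y - ty * e1x;
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (std::fabs(t) < 1e-9) { onsurf = true; break; }
      if (t > 0) ++crossings;
    }
    inside[i] = !onsurf && (crossings % 2 == 1);
  }
  return inside;
}
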