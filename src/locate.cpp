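// Uniform-grid point location in a tetrahedral mesh image.
//
// Queries are assigned the containing tet with barycentric coordinates; points
// outside every tet are flagged and assigned the candidate tet with the least
// barycentric deficit found in an expanding ring search (clamped coordinates).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline void barycentric(const double* v0, const double* v1,
                               const double* v2, const double* v3,
                               const double* p, double* b) {
  double a[9] = {v1[0] - v0[0], v2[0] - v0[0], v3[0] - v0[0],
                 v1[1] - v0[1], v2[1] - v0[1], v3[1] - v0[1],
                 v1[2] - v0[2], v2[2] - v0[2], v3[2] - v0[2]};
  double r[3] = {p[0] - v0[0], p[1] - v0[1], p[2] - v0[2]};
  double det = a[0] * (a[4] * a[8] - a[5] * a[7])
             - a[1] * (a[3] * a[8] - a[5] * a[6])
             + a[2] * (a[3] * a[7] - a[4] * a[6]);
  if (std::fabs(det) < 1e-300) { b[0] = b[1] = b[2] = b[3] = -1e30; return; }
  double inv = 1.0 / det;
  double x = (r[0] * (a[4] * a[8] - a[5] * a[7])
            - a[1] * (r[1] * a[8] - a[5] * r[2])
            + a[2] * (r[1] * a[7] - a[4] * r[2])) * inv;
  double y = (a[0] * (r[1] * a[8] - a[5] * r[2])
            - r[0] * (a[3] * a[8] - a[5] * a[6])
            + a[2] * (a[3] * r[2] - r[1] * a[6])) * inv;
  double z = (a[0] * (a[4] * r[2] - r[1] * a[7])
            - a[1] * (a[3] * r[2] - r[1] * a[6])
            + r[0] * (a[3] * a[7] - a[4] * a[6])) * inv;
  b[1] = x; b[2] = y; b[3] = z; b[0] = 1.0 - x - y - z;
}

// [[Rcpp::export(name = ".locate_points_cpp")]]
List locate_points_cpp(NumericMatrix verts, IntegerMatrix tets,
                       NumericMatrix pts, double inside_tol = 1e-9) {
  const int nt = tets.nrow(), np = pts.nrow();
  // grid over the mesh bounding box
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (int i = 0; i < verts.nrow(); ++i) {
      lo[d] = std::min(lo[d], verts(i, d));
      hi[d] = std::max(hi[d], verts(i, d));
    }
    double pad = 1e-9 + 1e-9 * (hi[d] - lo[d]);
    lo[d] -= pad; hi[d] += pad;
  }
  int ng = std::max(2, (int)std::floor(std::cbrt((double)nt / 4.0)));
  ng = std::min(ng, 96);
  double cell[3];
  for (int d = 0; d < 3; ++d) cell[d] = (hi[d] - lo[d]) / ng;

  std::vector<std::vector<int>> buckets((size_t)ng * ng * ng);
  std::vector<double> vx(verts.nrow()), vy(verts.nrow()), vz(verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }
  auto clampi = [&](int v) { return std::max(0, std::min(ng - 1, v)); };
  for (int t = 0; t < nt; ++t) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int c = 0; c < 4; ++c) {
      int v = tets(t, c) - 1;
      double q[3] = {vx[v], vy[v], vz[v]};
      for (int d = 0; d < 3; ++d) {
        tlo[d] = std::min(tlo[d], q[d]);
        thi[d] = std::max(thi[d], q[d]);
      }
    }
    int i0 = clampi((int)((tlo[0] - lo[0]) / cell[0]));
    int i1 = clampi((int)((thi[0] - lo[0]) / cell[0]));
    int j0 = clampi((int)((tlo[1] - lo[1]) / cell[1]));
    int j1 = clampi((int)((thi[1] - lo[1]) / cell[1]));
    int k0 = clampi((int)((tlo[2] - lo[2]) / cell[2]));
    int k1 = clampi((int)((thi[2] - lo[2]) / cell[2]));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k)
          buckets[((size_t)k * ng + j) * ng + i].push_back(t);
  }

  IntegerVector tet_out(np);
  LogicalVector inside(np);
  NumericMatrix bary(np, 4);

  for (int q = 0; q < np; ++q) {
    double p[3] = {pts(q, 0), pts(q, 1), pts(q, 2)};
    int ci = clampi((int)((p[0] - lo[0]) / cell[0]));
    int cj = clampi((int)((p[1] - lo[1]) / cell[1]));
    int ck = clampi((int)((p[2] - lo[2]) / cell[2]));
    int best_t = -1;
    double best_min = -1e31;
    double best_b[4] = {0, 0, 0, 0};
    bool found = false;
    for (int ring = 0; ring <= ng && !found; ++ring) {
      bool any_cell = false;
      for (int di = -ring; di <= ring && !found; ++di)
        for (int dj = -ring; dj <= ring && !found; ++dj)
          for (int dk = -ring; dk <= ring && !found; ++dk) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != ring) continue;
            int i = ci + di, j = cj + dj, k = ck + dk;
            if (i < 0 || j < 0 || k < 0 || i >= ng || j >= ng || k >= ng) continue;
            any_cell = true;
            const std::vector<int>& cand = buckets[((size_t)k * ng + j) * ng + i];
            int cell_contain = -1;
            double cell_b[4] = {0, 0, 0, 0};
            double cell_min = -1e31;
            for (int t : cand) {
              int a0 = tets(t, 0) - 1, a1 = tets(t, 1) - 1,
                  a2 = tets(t, 2) - 1, a3 = tets(t, 3) - 1;
              double w0[3] = {vx[a0], vy[a0], vz[a0]};
              double w1[3] = {vx[a1], vy[a1], vz[a1]};
              double w2[3] = {vx[a2], vy[a2], vz[a2]};
              double w3[3] = {vx[a3], vy[a3], vz[a3]};
              // snap: a query coinciding with a tet corner belongs to that
              // corner regardless of overlapping tets elsewhere (the image of
              // a PL map may wrap locally without any tet inverting, and the
              // corner assignment is the branch-independent answer)
              const double* ws[4] = {w0, w1, w2, w3};
              int hit = -1;
              for (int c = 0; c < 4 && hit < 0; ++c) {
                double dx = ws[c][0] - p[0], dy = ws[c][1] - p[1],
                       dz = ws[c][2] - p[2];
                if (dx * dx + dy * dy + dz * dz < 1e-24) hit = c;
              }
              if (hit >= 0) {
                best_t = t;
                best_min = 0.0;
                for (int c = 0; c < 4; ++c) best_b[c] = (c == hit) ? 1.0 : 0.0;
                found = true;
                break;
              }
              double b[4];
              barycentric(w0, w1, w2, w3, p, b);
              double mn = std::min({b[0], b[1], b[2], b[3]});
              if (mn > best_min) {
                best_min = mn;
                best_t = t;
                for (int c = 0; c < 4; ++c) best_b[c] = b[c];
              }
              // containment does not end the cell scan: a later candidate may
              // snap to a coincident corner, which takes precedence
              if (mn >= -inside_tol && cell_contain < 0) {
                cell_contain = t;
                cell_min = mn;
                for (int c = 0; c < 4; ++c) cell_b[c] = b[c];
              }
            }
            if (!found && cell_contain >= 0) {
              best_t = cell_contain;
              best_min = cell_min;
              for (int c = 0; c < 4; ++c) best_b[c] = cell_b[c];
              found = true;
            }
          }
      // after the first ring that had candidate tets, allow one extra ring
      if (!found && best_t >= 0 && ring >= 1 && any_cell) break;
    }
    if (best_t < 0) {
      tet_out[q] = NA_INTEGER;
      inside[q] = false;
      continue;
    }
    tet_out[q] = best_t + 1;
    inside[q] = best_min >= -inside_tol;
    if (!inside[q]) { // clamp and renormalize
      double s = 0;
      for (int c = 0; c < 4; ++c) {
        best_b[c] = std::max(0.0, best_b[c]);
        s += best_b[c];
      }
      if (s <= 0) { best_b[0] = 1; s = 1; }
      for (int c = 0; c < 4; ++c) best_b[c] /= s;
    }
    for (int c = 0; c < 4; ++c) bary(q, c) = best_b[c];
  }
  return List::create(_["tet"] = tet_out, _["bary"] = bary, _["inside"] = inside);
}
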