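// Closest point on a triangle mesh via a uniform grid over triangle bounding
// boxes. Used for remeshing back-projection and Hausdorff-type distances.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// Ericson, Real-Time Collision Detection, closest point on triangle abc to p.
inline vec3 closest_on_tri(const vec3& p, const vec3& a, const vec3& b,
                           const vec3& c) {
  const vec3 ab = b - a, ac = c - a, ap = p - a;
  const double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  const vec3 bp = p - b;
  const double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  const vec3 cp = p - c;
  const double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

struct TriGrid {
  double x0[3];
  double cell;
  int dims[3];
  std::vector<std::vector<int>> bins;

  int idx(int i, int j, int k) const {
    return (k * dims[1] + j) * dims[0] + i;
  }
  void clampc(const double* p, int* out) const {
    for (int d = 0; d < 3; ++d) {
      int c = int(std::floor((p[d] - x0[d]) / cell));
      if (c < 0) c = 0;
      if (c >= dims[d]) c = dims[d] - 1;
      out[d] = c;
    }
  }
};

TriGrid build_grid(const mat& V, const imat& F) {
  TriGrid g;
  const rowvec lo = min(V, 0), hi = max(V, 0);
  // cell sized to the average triangle bbox diagonal, bounded for sanity
  double avg = 0.0;
  for (uword f = 0; f < F.n_rows; ++f) {
    const rowvec a = V.row(F(f, 0)), b = V.row(F(f, 1)), c = V.row(F(f, 2));
    const rowvec tl = min(min(a, b), c), th = max(max(a, b), c);
    avg += norm(th - tl, 2);
  }
  avg = (F.n_rows > 0) ? avg / double(F.n_rows) : 1.0;
  if (avg <= 0.0) avg = 1.0;
  g.cell = avg;
  for (int d = 0; d < 3; ++d) {
    g.x0[d] = lo(d) - 1e-9;
    int n = int(std::ceil((hi(d) - lo(d)) / g.cell)) + 1;
    if (n < 1) n = 1;
    if (n > 256) n = 256;
    g.dims[d] = n;
  }
  // recompute cell so 256-capped dims still cover the bbox
  for (int d = 0; d < 3; ++d) {
    const double need = (hi(d) - g.x0[d]) / double(g.dims[d]);
    if (need > g.cell) g.cell = need + 1e-9;
  }
  g.bins.resize(size_t(g.dims[0]) * g.dims[1] * g.dims[2]);
  for (uword f = 0; f < F.n_rows; ++f) {
    const rowvec a = V.row(F(f, 0)), b = V.row(F(f, 1)), c = V.row(F(f, 2));
    const rowvec tl = min(min(a, b), c), th = max(max(a, b), c);
    int clo[3], chi[3];
    double plo[3] = {tl(0), tl(1), tl(2)}, phi[3] = {th(0), th(1), th(2)};
    g.clampc(plo, clo);
    g.clampc(phi, chi);
    for (int k = clo[2]; k <= chi[2]; ++k)
      for (int j = clo[1]; j <= chi[1]; ++j)
        for (int i = clo[0]; i <= chi[0]; ++i)
          g.bins[g.idx(i, j, k)].push_back(int(f));
  }
  return g;
}

} // namespace

// [[Rcpp::export(name = ".closest_on_mesh")]]
Rcpp::List closest_on_mesh(const arma::mat& P, const arma::mat& V,
                           const arma::imat& F) {
  const TriGrid g = build_grid(V, F);
  const uword nq = P.n_rows;
  vec dist(nq);
  mat proj(nq, 3);
  const int maxdim = std::max(g.dims[0], std::max(g.dims[1], g.dims[2]));
  for (uword q = 0; q < nq; ++q) {
    const vec3 p = P.row(q).t();
    double pq[3] = {p(0), p(1), p(2)};
    int cc[3];
    g.clampc(pq, cc);
    double best = datum::inf;
    vec3 bestp = {0, 0, 0};
    for (int r = 0; r <= maxdim; ++r) {
      // shell of cells at Chebyshev radius r around the query cell
      for (int k = cc[2] - r; k <= cc[2] + r; ++k) {
        if (k < 0 || k >= g.dims[2]) continue;
        for (int j = cc[1] - r; j <= cc[1] + r; ++j) {
          if (j < 0 || j >= g.dims[1]) continue;
          for (int i = cc[0] - r; i <= cc[0] + r; ++i) {
            if (i < 0 || i >= g.dims[0]) continue;
            const int ri = std::max(std::abs(i - cc[0]),
                            std::max(std::abs(j - cc[1]), std::abs(k - cc[2])));
            if (ri != r) continue;
            for (int f : g.bins[g.idx(i, j, k)]) {
              const vec3 a = V.row(F(f, 0)).t();
              const vec3 b = V.row(F(f, 1)).t();
              const vec3 c = V.row(F(f, 2)).t();
              const vec3 cp = closest_on_tri(p, a, b, c);
              const double d = norm(p - cp, 2);
              if (d < best) {
                best = d;
                bestp = cp;
              }
            }
          }
        }
      }
      // any triangle in a farther shell is at least (r * cell) away from the
      // query cell, minus one cell of slack for the query's offset inside it
      if (std::isfinite(best) && best <= double(r) * g.cell) break;
    }
    dist(q) = best;
    proj.row(q) = bestp.t();
  }
  return Rcpp::List::create(Rcpp::Named("distance") = dist,
                            Rcpp::Named("point") = proj);
}
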