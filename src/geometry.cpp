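#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Ray-parity and closest-point queries against a triangle soup.
// V: n x 3 vertex matrix, F: m x 3 one-based face index matrix.

static inline void tri_vertices(const NumericMatrix &V, const IntegerMatrix &F,
                                int f, double a[3], double b[3], double c[3]) {
  int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
  for (int k = 0; k < 3; ++k) {
    a[k] = V(i0, k); b[k] = V(i1, k); c[k] = V(i2, k);
  }
}

// Moller-Trumbore; returns t of intersection with ray p + t*d, or -1.
static inline double ray_tri(const double p[3], const double d[3],
                             const double a[3], const double b[3], const double c[3]) {
  const double EPS = 1e-12;
  double e1[3], e2[3], h[3], s[3], q[3];
  for (int k = 0; k < 3; ++k) { e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; }
  h[0] = d[1]*e2[2] - d[2]*e2[1];
  h[1] = d[2]*e2[0] - d[0]*e2[2];
  h[2] = d[0]*e2[1] - d[1]*e2[0];
  double det = e1[0]*h[0] + e1[1]*h[1] + e1[2]*h[2];
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  for (int k = 0; k < 3; ++k) s[k] = p[k] - a[k];
  double u = (s[0]*h[0] + s[1]*h[1] + s[2]*h[2]) * inv;
  if (u < 0.0 || u > 1.0) return -1.0;
  q[0] = s[1]*e1[2] - s[2]*e1[1];
  q[1] = s[2]*e1[0] - s[0]*e1[2];
  q[2] = s[0]*e1[1] - s[1]*e1[0];
  double v = (d[0]*q[0] + d[1]*q[1] + d[2]*q[2]) * inv;
  if (v < 0.0 || u + v > 1.0) return -1.0;
  double t = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) * inv;
  return t;
}

// [[Rcpp::export]]
LogicalVector cpp_ray_parity(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  LogicalVector inside(np);
  // skewed irrational direction: structured meshes align features with the
  // coordinate axes, so an (almost) axis-parallel ray would graze vertices
  double d[3] = {0.0377214563, 0.0523187642, 1.0};
  double dn = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  for (int k = 0; k < 3; ++k) d[k] /= dn;
  const double driftx = d[0] / d[2], drifty = d[1] / d[2];
  // precompute face bounding boxes in x,y for quick reject (ray ~ +z)
  std::vector<double> bxmin(nf), bxmax(nf), bymin(nf), bymax(nf), bzmax(nf);
  double a[3], b[3], c[3];
  for (int f = 0; f < nf; ++f) {
    tri_vertices(V, F, f, a, b, c);
    bxmin[f] = std::min(a[0], std::min(b[0], c[0]));
    bxmax[f] = std::max(a[0], std::max(b[0], c[0]));
    bymin[f] = std::min(a[1], std::min(b[1], c[1]));
    bymax[f] = std::max(a[1], std::max(b[1], c[1]));
    bzmax[f] = std::max(a[2], std::max(b[2], c[2]));
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    int crossings = 0;
    for (int f = 0; f < nf; ++f) {
      if (bzmax[f] < p[2]) continue;
      double span = bzmax[f] - p[2];      // max lateral drift of the ray
      double mx = driftx * span + 1e-3, my = drifty * span + 1e-3;
      if (p[0] < bxmin[f] - mx || p[0] > bxmax[f] + mx) continue;
      if (p[1] < bymin[f] - my || p[1] > bymax[f] + my) continue;
      tri_vertices(V, F, f, a, b, c);
      double t = ray_tri(p, d, a, b, c);
      if (t > 1e-12) ++crossings;
    }
    inside[i] = (crossings % 2) == 1;
  }
  return inside;
}

// closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
static inline void closest_on_tri(const double p[3], const double a[3],
                                  const double b[3], const double c[3], double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k]-a[k]; ac[k] = c[k]-a[k]; ap[k] = p[k]-a[k]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int k=0;k<3;++k) out[k]=a[k]; return; }
  double bp[3]; for (int k=0;k<3;++k) bp[k] = p[k]-b[k];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int k=0;k<3;++k) out[k]=b[k]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + v*ab[k];
    return;
  }
  double cp[3]; for (int k=0;k<3;++k) cp[k] = p[k]-c[k];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int k=0;k<3;++k) out[k]=c[k]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + w*ac[k];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + w*(c[k]-b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np);
  IntegerVector face(np);
  NumericMatrix Q(np, 3);
  double a[3], b[3], c[3], q[3];
  std::vector<double> bmin(3*nf), bmax(3*nf);
  for (int f = 0; f < nf; ++f) {
    tri_vertices(V, F, f, a, b, c);
    for (int k = 0; k < 3; ++k) {
      bmin[3*f+k] = std::min(a[k], std::min(b[k], c[k]));
      bmax[3*f+k] = std::max(a[k], std::max(b[k], c[k]));
    }
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    double best = R_PosInf; int bestf = 0; double bq[3] = {0,0,0};
    for (int f = 0; f < nf; ++f) {
      // lower bound: distance to face bbox
      double lb = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = 0.0;
        if (p[k] < bmin[3*f+k]) d = bmin[3*f+k] - p[k];
        else if (p[k] > bmax[3*f+k]) d = p[k] - bmax[3*f+k];
        lb += d*d;
      }
      if (lb >= best) continue;
      tri_vertices(V, F, f, a, b, c);
      closest_on_tri(p, a, b, c, q);
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) { double dd = p[k]-q[k]; d2 += dd*dd; }
      if (d2 < best) { best = d2; bestf = f; for (int k=0;k<3;++k) bq[k]=q[k]; }
    }
    dist[i] = std::sqrt(best);
    face[i] = bestf + 1;
    for (int k = 0; k < 3; ++k) Q(i,k) = bq[k];
  }
  return List::create(_["dist"] = dist, _["face"] = face, _["point"] = Q);
}

// 6-connected component labelling of a 3-D logical mask (column-major dims nx,ny,nz)
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      const int dx[6] = {-1,1,0,0,0,0}, dy[6] = {0,0,-1,1,0,0}, dz[6] = {0,0,0,0,-1,1};
      for (int k = 0; k < 6; ++k) {
        int xx = x+dx[k], yy = y+dy[k], zz = z+dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int w = xx + nx*(yy + ny*zz);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}
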