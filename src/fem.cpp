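#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Constant-strain (P1) tetrahedral elasticity kernels.
// nodes: n x 3 (mm); tets: m x 4 one-based; E per element; common Poisson ratio.
// Voigt order: xx, yy, zz, xy, yz, zx with engineering shear strains.

static inline double tet_grads(const NumericMatrix &nodes, const IntegerMatrix &tets,
                               int e, double g[4][3]) {
  // returns volume; g[i] = grad of shape function i
  int n0 = tets(e,0)-1, n1 = tets(e,1)-1, n2 = tets(e,2)-1, n3 = tets(e,3)-1;
  double x0[3], d1[3], d2[3], d3[3];
  for (int k = 0; k < 3; ++k) {
    x0[k] = nodes(n0,k);
    d1[k] = nodes(n1,k) - x0[k];
    d2[k] = nodes(n2,k) - x0[k];
    d3[k] = nodes(n3,k) - x0[k];
  }
  double J[3][3] = {{d1[0], d2[0], d3[0]}, {d1[1], d2[1], d3[1]}, {d1[2], d2[2], d3[2]}};
  double det = J[0][0]*(J[1][1]*J[2][2]-J[1][2]*J[2][1])
             - J[0][1]*(J[1][0]*J[2][2]-J[1][2]*J[2][0])
             + J[0][2]*(J[1][0]*J[2][1]-J[1][1]*J[2][0]);
  double inv[3][3];
  double id = 1.0 / det;
  inv[0][0] =  (J[1][1]*J[2][2]-J[1][2]*J[2][1])*id;
  inv[0][1] = -(J[0][1]*J[2][2]-J[0][2]*J[2][1])*id;
  inv[0][2] =  (J[0][1]*J[1][2]-J[0][2]*J[1][1])*id;
  inv[1][0] = -(J[1][0]*J[2][2]-J[1][2]*J[2][0])*id;
  inv[1][1] =  (J[0][0]*J[2][2]-J[0][2]*J[2][0])*id;
  inv[1][2] = -(J[0][0]*J[1][2]-J[0][2]*J[1][0])*id;
  inv[2][0] =  (J[1][0]*J[2][1]-J[1][1]*J[2][0])*id;
  inv[2][1] = -(J[0][0]*J[2][1]-J[0][1]*J[2][0])*id;
  inv[2][2] =  (J[0][0]*J[1][1]-J[0][1]*J[1][0])*id;
  // grad N_i (i=1..3) = row i of inv (d xi / d x); N0 = 1 - xi1 - xi2 - xi3
  for (int k = 0; k < 3; ++k) {
    g[1][k] = inv[0][k];
    g[2][k] = inv[1][k];
    g[3][k] = inv[2][k];
    g[0][k] = -g[1][k] - g[2][k] - g[3][k];
  }
  return det / 6.0;
}

static inline void dmat(double E, double nu, double D[6][6]) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu  = E / (2.0 * (1.0 + nu));
  for (int i = 0; i < 6; ++i) for (int j = 0; j < 6; ++j) D[i][j] = 0.0;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D[i][j] = lam;
    D[i][i] = lam + 2.0 * mu;
    D[i+3][i+3] = mu;
  }
}

static inline void bmat(const double g[4][3], double B[6][12]) {
  for (int i = 0; i < 6; ++i) for (int j = 0; j < 12; ++j) B[i][j] = 0.0;
  for (int a = 0; a < 4; ++a) {
    int c = 3 * a;
    B[0][c+0] = g[a][0];
    B[1][c+1] = g[a][1];
    B[2][c+2] = g[a][2];
    B[3][c+0] = g[a][1]; B[3][c+1] = g[a][0];
    B[4][c+1] = g[a][2]; B[4][c+2] = g[a][1];
    B[5][c+0] = g[a][2]; B[5][c+2] = g[a][0];
  }
}

// [[Rcpp::export]]
List cpp_assemble_tets(NumericMatrix nodes, IntegerMatrix tets,
                       NumericVector E, double nu) {
  int m = tets.nrow();
  IntegerVector ii(m * 144), jj(m * 144);
  NumericVector xx(m * 144);
  double g[4][3], B[6][12], D[6][6], DB[6][12], Ke[12][12];
  long idx = 0;
  for (int e = 0; e < m; ++e) {
    double vol = tet_grads(nodes, tets, e, g);
    if (vol <= 0.0) stop("inverted or degenerate tetrahedron at element %d", e + 1);
    bmat(g, B);
    dmat(E[e], nu, D);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 12; ++j) {
        double s = 0.0;
        for (int k = 0; k < 6; ++k) s += D[i][k] * B[k][j];
        DB[i][j] = s;
      }
    for (int i = 0; i < 12; ++i)
      for (int j = 0; j < 12; ++j) {
        double s = 0.0;
        for (int k = 0; k < 6; ++k) s += B[k][i] * DB[k][j];
        Ke[i][j] = s * vol;
      }
    int dof[12];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) dof[3*a+c] = 3 * (tets(e,a) - 1) + c;  // 0-based
    for (int i = 0; i < 12; ++i)
      for (int j = 0; j < 12; ++j) {
        ii[idx] = dof[i] + 1;
        jj[idx] = dof[j] + 1;
        xx[idx] = Ke[i][j];
        ++idx;
      }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}

// [[Rcpp::export]]
NumericMatrix cpp_tet_stress(NumericMatrix nodes, IntegerMatrix tets,
                             NumericVector u, NumericVector E, double nu) {
  int m = tets.nrow();
  NumericMatrix S(m, 6);
  double g[4][3], B[6][12], D[6][6];
  for (int e = 0; e < m; ++e) {
    tet_grads(nodes, tets, e, g);
    bmat(g, B);
    dmat(E[e], nu, D);
    double ue[12];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) ue[3*a+c] = u[3 * (tets(e,a) - 1) + c];
    double eps[6];
    for (int i = 0; i < 6; ++i) {
      double s = 0.0;
      for (int j = 0; j < 12; ++j) s += B[i][j] * ue[j];
      eps[i] = s;
    }
    for (int i = 0; i < 6; ++i) {
      double s = 0.0;
      for (int k = 0; k < 6; ++k) s += D[i][k] * eps[k];
      S(e, i) = s;
    }
  }
  return S;
}

// [[Rcpp::export]]
NumericVector cpp_tet_volumes(NumericMatrix nodes, IntegerMatrix tets) {
  int m = tets.nrow();
  NumericVector v(m);
  double g[4][3];
  for (int e = 0; e < m; ++e) v[e] = tet_grads(nodes, tets, e, g);
  return v;
}
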