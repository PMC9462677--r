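// Small-strain isoparametric tetrahedral element kernels (tet4 / tet10,
// VTK node ordering). Assembly returns lower-triangle COO triplets so the
// caller can build a symmetric sparse matrix without materialising both
// halves.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, xz),
// engineering shear strains
static arma::mat elastic_D(double E, double nu) {
  arma::mat D(6, 6, arma::fill::zeros);
  const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double mu  = E / (2.0 * (1.0 + nu));
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D(i, j) = lam;
    D(i, i) = lam + 2.0 * mu;
    D(3 + i, 3 + i) = mu;
  }
  return D;
}

// dN/d(L1,L2,L3) for tet10 at barycentric point (VTK ordering:
// corners 0..3, midsides 4=(0,1) 5=(1,2) 6=(0,2) 7=(0,3) 8=(1,3) 9=(2,3)).
// L4 = 1 - L1 - L2 - L3 is eliminated.
static void tet10_dN(const double L1, const double L2, const double L3,
                     arma::mat &dN) {
  const double L4 = 1.0 - L1 - L2 - L3;
  // corner derivatives wrt own barycentric coordinate: 4L - 1
  // dN/dxi_j = dN/dL_j - dN/dL4
  dN.zeros(10, 3);
  // corners
  dN(0, 0) = 4.0 * L1 - 1.0;
  dN(1, 1) = 4.0 * L2 - 1.0;
  dN(2, 2) = 4.0 * L3 - 1.0;
  const double d4 = -(4.0 * L4 - 1.0);
  dN(3, 0) = d4; dN(3, 1) = d4; dN(3, 2) = d4;
  // midsides: N = 4 La Lb
  // 4 = (0,1)
  dN(4, 0) = 4.0 * L2; dN(4, 1) = 4.0 * L1;
  // 5 = (1,2)
  dN(5, 1) = 4.0 * L3; dN(5, 2) = 4.0 * L2;
  // 6 = (0,2)
  dN(6, 0) = 4.0 * L3; dN(6, 2) = 4.0 * L1;
  // 7 = (0,3): N = 4 L1 L4 -> dN/dL1 = 4L4, dN/dL4 = 4L1
  dN(7, 0) = 4.0 * L4 - 4.0 * L1;
  dN(7, 1) = -4.0 * L1;
  dN(7, 2) = -4.0 * L1;
  // 8 = (1,3)
  dN(8, 0) = -4.0 * L2;
  dN(8, 1) = 4.0 * L4 - 4.0 * L2;
  dN(8, 2) = -4.0 * L2;
  // 9 = (2,3)
  dN(9, 0) = -4.0 * L3;
  dN(9, 1) = -4.0 * L3;
  dN(9, 2) = 4.0 * L4 - 4.0 * L3;
}

static void tet4_dN(arma::mat &dN) {
  dN.zeros(4, 3);
  dN(0, 0) = 1.0; dN(1, 1) = 1.0; dN(2, 2) = 1.0;
  dN(3, 0) = -1.0; dN(3, 1) = -1.0; dN(3, 2) = -1.0;
}

// B matrix (6 x 3n) from cartesian shape-function gradients (n x 3)
static void fill_B(const arma::mat &g, arma::mat &B) {
  const arma::uword n = g.n_rows;
  B.zeros(6, 3 * n);
  for (arma::uword a = 0; a < n; ++a) {
    const double gx = g(a, 0), gy = g(a, 1), gz = g(a, 2);
    B(0, 3 * a + 0) = gx;
    B(1, 3 * a + 1) = gy;
    B(2, 3 * a + 2) = gz;
    B(3, 3 * a + 0) = gy; B(3, 3 * a + 1) = gx;
    B(4, 3 * a + 1) = gz; B(4, 3 * a + 2) = gy;
    B(5, 3 * a + 0) = gz; B(5, 3 * a + 2) = gx;
  }
}

// 4-point Gauss rule on the tetrahedron (degree 2, exact for tet10
// stiffness with straight edges)
static const double GP_A = 0.5854101966249685;
static const double GP_B = 0.1381966011250105;

// [[Rcpp::export]]
List asm_stiffness_cpp(const NumericMatrix nodes_, const IntegerMatrix elems_,
                       const NumericVector Evec, const NumericVector nuvec) {
  const arma::mat nodes(nodes_.begin(), nodes_.nrow(), 3);
  const int ne = elems_.nrow();
  const int npe = elems_.ncol();              // 4 or 10
  if (npe != 4 && npe != 10)
    stop("elements must have 4 or 10 nodes per row");
  const int ndof = 3 * npe;
  const int ntri = ndof * (ndof + 1) / 2;
  std::vector<int> ti(static_cast<size_t>(ne) * ntri);
  std::vector<int> tj(static_cast<size_t>(ne) * ntri);
  std::vector<double> tx(static_cast<size_t>(ne) * ntri);

  arma::mat dN, g, B, Ke, corner(4, 3), X(npe, 3), J(3, 3), Jinv(3, 3);
  size_t pos = 0;
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < npe; ++a) {
      const int nid = elems_(e, a) - 1;
      X(a, 0) = nodes(nid, 0); X(a, 1) = nodes(nid, 1); X(a, 2) = nodes(nid, 2);
    }
    const arma::mat D = elastic_D(Evec[e], nuvec[e]);
    Ke.zeros(ndof, ndof);
    if (npe == 4) {
      tet4_dN(dN);
      J = X.t() * dN;                      // 3x3
      // the (L1,L2,L3 | node 4 at origin) parameterisation is
      // left-handed: det(J) = -6V for a positively oriented tet
      const double detJ = -arma::det(J);
      if (detJ <= 0.0)
        stop("inverted tet4 element at index %d (volume = %g)", e + 1, detJ / 6.0);
      g = dN * arma::inv(J);           // dN/dx = dN/dxi * dxi/dx
      fill_B(g, B);
      Ke = (detJ / 6.0) * (B.t() * D * B);
    } else {
      const double gp[4][3] = {
        {GP_A, GP_B, GP_B}, {GP_B, GP_A, GP_B},
        {GP_B, GP_B, GP_A}, {GP_B, GP_B, GP_B}};
      for (int q = 0; q < 4; ++q) {
        tet10_dN(gp[q][0], gp[q][1], gp[q][2], dN);
        J = X.t() * dN;
        const double detJ = -arma::det(J);   // left-handed parameterisation
        if (detJ <= 0.0)
          stop("inverted tet10 element at index %d (volume = %g)", e + 1, detJ / 6.0);
        g = dN * arma::inv(J);
        fill_B(g, B);
        Ke += (detJ / 6.0) * 0.25 * (B.t() * D * B);
      }
    }
    // lower-triangle triplets in global dof numbering (1-based)
    for (int p = 0; p < ndof; ++p) {
      const int gi = 3 * (elems_(e, p / 3) - 1) + (p % 3) + 1;
      for (int q = 0; q <= p; ++q) {
        const int gj = 3 * (elems_(e, q / 3) - 1) + (q % 3) + 1;
        if (gi >= gj) {
          ti[pos] = gi; tj[pos] = gj;
        } else {
          ti[pos] = gj; tj[pos] = gi;
        }
        tx[pos] = Ke(p, q);
        ++pos;
      }
    }
  }
  return List::create(_["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()));
}

// engineering small strains at the element centroid, rows = elements,
// cols = (xx, yy, zz, xy, yz, xz)
// [[Rcpp::export]]
NumericMatrix element_strains_cpp(const NumericMatrix nodes_,
                                  const IntegerMatrix elems_,
                                  const NumericMatrix U_) {
  const arma::mat nodes(nodes_.begin(), nodes_.nrow(), 3);
  const arma::mat U(U_.begin(), U_.nrow(), 3);
  const int ne = elems_.nrow();
  const int npe = elems_.ncol();
  NumericMatrix out(ne, 6);
  arma::mat dN, g, B, X(npe, 3), J(3, 3);
  arma::vec ue(3 * npe), eps;
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < npe; ++a) {
      const int nid = elems_(e, a) - 1;
      X.row(a) = nodes.row(nid);
      ue(3 * a + 0) = U(nid, 0);
      ue(3 * a + 1) = U(nid, 1);
      ue(3 * a + 2) = U(nid, 2);
    }
    if (npe == 4) tet4_dN(dN); else tet10_dN(0.25, 0.25, 0.25, dN);
    J = X.t() * dN;
    g = dN * arma::inv(J);
    fill_B(g, B);
    eps = B * ue;
    for (int k = 0; k < 6; ++k) out(e, k) = eps(k);
  }
  return out;
}

// signed volumes of the corner tetrahedra (first four nodes of each row)
// [[Rcpp::export]]
NumericVector tet_volumes_cpp(const NumericMatrix nodes_,
                              const IntegerMatrix elems_) {
  const arma::mat nodes(nodes_.begin(), nodes_.nrow(), 3);
  const int ne = elems_.nrow();
  NumericVector out(ne);
  for (int e = 0; e < ne; ++e) {
    const arma::rowvec a = nodes.row(elems_(e, 0) - 1);
    const arma::rowvec b = nodes.row(elems_(e, 1) - 1);
    const arma::rowvec c = nodes.row(elems_(e, 2) - 1);
    const arma::rowvec d = nodes.row(elems_(e, 3) - 1);
    const arma::rowvec u = b - a, v = c - a, w = d - a;
    out[e] = (u(0) * (v(1) * w(2) - v(2) * w(1)) -
              u(1) * (v(0) * w(2) - v(2) * w(0)) +
              u(2) * (v(0) * w(1) - v(1) * w(0))) / 6.0;
  }
  return out;
}
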