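// Isoparametric small-strain element kernels for the spine solver.
// Element kinds: 0 = tet4, 1 = tet10, 2 = wedge6, 3 = wedge15.
// Node orderings follow VTK conventions (tet10 edge order 01,12,02,03,13,23;
// wedge corner triangles bottom/top, then bottom/top/vertical mid-edges).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static int kind_nnode(int kind) {
  switch (kind) {
  case 0: return 4;
  case 1: return 10;
  case 2: return 6;
  case 3: return 15;
  }
  Rcpp::stop("unknown element kind id");
  return 0;
}

// quadrature points (rows: xi, eta, zeta, w)
static mat kind_quadrature(int kind) {
  if (kind == 0) {
    mat q(1, 4);
    q(0, 0) = 0.25; q(0, 1) = 0.25; q(0, 2) = 0.25; q(0, 3) = 1.0 / 6.0;
    return q;
  }
  if (kind == 1) {
    const double a = 0.5854101966249685, b = 0.1381966011250105;
    mat q(4, 4);
    q.row(0) = rowvec({b, b, b, 1.0 / 24.0});
    q.row(1) = rowvec({a, b, b, 1.0 / 24.0});
    q.row(2) = rowvec({b, a, b, 1.0 / 24.0});
    q.row(3) = rowvec({b, b, a, 1.0 / 24.0});
    return q;
  }
  // wedge rules: 3-point triangle x n-point Gauss in zeta
  const double tr[3][2] = {{1.0 / 6.0, 1.0 / 6.0},
                           {2.0 / 3.0, 1.0 / 6.0},
                           {1.0 / 6.0, 2.0 / 3.0}};
  const double tw = 1.0 / 6.0;
  if (kind == 2) {
    const double g = 1.0 / std::sqrt(3.0);
    mat q(6, 4);
    int r = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 2; ++j) {
        q(r, 0) = tr[i][0]; q(r, 1) = tr[i][1];
        q(r, 2) = (j == 0) ? -g : g;
        q(r, 3) = tw * 1.0;
        ++r;
      }
    return q;
  }
  if (kind == 3) {
    // quadratic prism needs >= 39 independent strain samples: 3x3 = 9 points
    const double gz[3] = {-std::sqrt(3.0 / 5.0), 0.0, std::sqrt(3.0 / 5.0)};
    const double gw[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
    mat q(9, 4);
    int r = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        q(r, 0) = tr[i][0]; q(r, 1) = tr[i][1];
        q(r, 2) = gz[j];
        q(r, 3) = tw * gw[j];
        ++r;
      }
    return q;
  }
  Rcpp::stop("unknown element kind id");
  return mat();
}

// shape values N (k) and derivatives dN (k x 3) at local point
static void shape_eval(int kind, double xi, double eta, double zeta,
                       vec& N, mat& dN) {
  if (kind == 0) {
    N = {1.0 - xi - eta - zeta, xi, eta, zeta};
    dN = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    return;
  }
  if (kind == 1) {
    double L[4] = {1.0 - xi - eta - zeta, xi, eta, zeta};
    rowvec dL[4] = {rowvec({-1, -1, -1}), rowvec({1, 0, 0}),
                    rowvec({0, 1, 0}), rowvec({0, 0, 1})};
    N.set_size(10); dN.set_size(10, 3);
    for (int i = 0; i < 4; ++i) {
      N(i) = L[i] * (2.0 * L[i] - 1.0);
      dN.row(i) = (4.0 * L[i] - 1.0) * dL[i];
    }
    const int ed[6][2] = {{0, 1}, {1, 2}, {0, 2}, {0, 3}, {1, 3}, {2, 3}};
    for (int e = 0; e < 6; ++e) {
      int i = ed[e][0], j = ed[e][1];
      N(4 + e) = 4.0 * L[i] * L[j];
      dN.row(4 + e) = 4.0 * (L[i] * dL[j] + L[j] * dL[i]);
    }
    return;
  }
  // wedges: triangle coords L1..L3 and zeta in [-1, 1]
  double L[3] = {1.0 - xi - eta, xi, eta};
  rowvec dL[3] = {rowvec({-1, -1, 0}), rowvec({1, 0, 0}), rowvec({0, 1, 0})};
  double t = zeta;
  rowvec dt({0, 0, 1});
  if (kind == 2) {
    N.set_size(6); dN.set_size(6, 3);
    for (int i = 0; i < 3; ++i) {
      N(i) = 0.5 * L[i] * (1.0 - t);
      dN.row(i) = 0.5 * ((1.0 - t) * dL[i] - L[i] * dt);
      N(3 + i) = 0.5 * L[i] * (1.0 + t);
      dN.row(3 + i) = 0.5 * ((1.0 + t) * dL[i] + L[i] * dt);
    }
    return;
  }
  if (kind == 3) {
    N.set_size(15); dN.set_size(15, 3);
    for (int i = 0; i < 3; ++i) {
      // bottom corner
      N(i) = 0.5 * L[i] * ((2.0 * L[i] - 1.0) * (1.0 - t) - (1.0 - t * t));
      dN.row(i) = 0.5 * (dL[i] * ((2.0 * L[i] - 1.0) * (1.0 - t) - (1.0 - t * t))
                         + L[i] * (2.0 * dL[i] * (1.0 - t)
                                   + (2.0 * L[i] - 1.0) * (-dt) + 2.0 * t * dt));
      // top corner
      N(3 + i) = 0.5 * L[i] * ((2.0 * L[i] - 1.0) * (1.0 + t) - (1.0 - t * t));
      dN.row(3 + i) = 0.5 * (dL[i] * ((2.0 * L[i] - 1.0) * (1.0 + t) - (1.0 - t * t))
                             + L[i] * (2.0 * dL[i] * (1.0 + t)
                                       + (2.0 * L[i] - 1.0) * dt + 2.0 * t * dt));
    }
    const int ed[3][2] = {{0, 1}, {1, 2}, {2, 0}};
    for (int e = 0; e < 3; ++e) {
      int i = ed[e][0], j = ed[e][1];
      N(6 + e) = 2.0 * L[i] * L[j] * (1.0 - t);
      dN.row(6 + e) = 2.0 * ((L[i] * dL[j] + L[j] * dL[i]) * (1.0 - t)
                             - L[i] * L[j] * dt);
      N(9 + e) = 2.0 * L[i] * L[j] * (1.0 + t);
      dN.row(9 + e) = 2.0 * ((L[i] * dL[j] + L[j] * dL[i]) * (1.0 + t)
                             + L[i] * L[j] * dt);
    }
    for (int i = 0; i < 3; ++i) {
      N(12 + i) = L[i] * (1.0 - t * t);
      dN.row(12 + i) = dL[i] * (1.0 - t * t) - 2.0 * t * L[i] * dt;
    }
    return;
  }
  Rcpp::stop("unknown element kind id");
}

static mat iso_D(double E, double nu) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu = E / (2.0 * (1.0 + nu));
  mat D(6, 6, fill::zeros);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D(i, j) = lam;
    D(i, i) = lam + 2.0 * mu;
    D(3 + i, 3 + i) = mu; // engineering shear
  }
  return D;
}

// Strain-displacement matrix from cartesian shape derivatives (k x 3).
// Strain order: xx, yy, zz, xy, yz, xz with engineering shear.
static mat build_B(const mat& dNdx) {
  int k = dNdx.n_rows;
  mat B(6, 3 * k, fill::zeros);
  for (int n = 0; n < k; ++n) {
    double dx = dNdx(n, 0), dy = dNdx(n, 1), dz = dNdx(n, 2);
    B(0, 3 * n + 0) = dx;
    B(1, 3 * n + 1) = dy;
    B(2, 3 * n + 2) = dz;
    B(3, 3 * n + 0) = dy; B(3, 3 * n + 1) = dx;
    B(4, 3 * n + 1) = dz; B(4, 3 * n + 2) = dy;
    B(5, 3 * n + 0) = dz; B(5, 3 * n + 2) = dx;
  }
  return B;
}

//' @noRd
// [[Rcpp::export(name = ".elem_stiffness_batch")]]
Rcpp::List elem_stiffness_batch(const arma::mat& nodes,
                                const arma::imat& conn, int kind,
                                const arma::vec& E, const arma::vec& nu) {
  int m = conn.n_rows, k = kind_nnode(kind);
  if ((int)conn.n_cols != k) Rcpp::stop("connectivity width does not match kind");
  mat q = kind_quadrature(kind);
  int nq = q.n_rows, nd = 3 * k;

  std::vector<vec> Ns(nq);
  std::vector<mat> dNs(nq);
  for (int iq = 0; iq < nq; ++iq)
    shape_eval(kind, q(iq, 0), q(iq, 1), q(iq, 2), Ns[iq], dNs[iq]);

  arma::ivec I(m * nd * nd), J(m * nd * nd);
  arma::vec X(m * nd * nd), vol(m), detj_min(m);
  mat coords(k, 3), Ke(nd, nd);
  uvec dofs(nd);

  for (int e = 0; e < m; ++e) {
    for (int n = 0; n < k; ++n) {
      int nid = conn(e, n) - 1;
      coords.row(n) = nodes.row(nid);
      for (int d = 0; d < 3; ++d) dofs(3 * n + d) = 3 * nid + d;
    }
    mat D = iso_D(E(e), nu(e));
    Ke.zeros();
    double v = 0.0, djmin = datum::inf;
    for (int iq = 0; iq < nq; ++iq) {
      mat Jm = dNs[iq].t() * coords; // 3x3, J(b,a) = sum dN/dxi_b * x_a
      double dj = det(Jm);
      if (dj < djmin) djmin = dj;
      if (dj <= 0) { djmin = dj; break; }
      mat dNdx = dNs[iq] * inv(Jm).t();
      mat B = build_B(dNdx);
      double w = q(iq, 3) * dj;
      Ke += B.t() * D * B * w;
      v += w;
    }
    vol(e) = v;
    detj_min(e) = djmin;
    std::size_t off = (std::size_t)e * nd * nd, c = 0;
    for (int a = 0; a < nd; ++a)
      for (int b = 0; b < nd; ++b) {
        I(off + c) = dofs(a) + 1;
        J(off + c) = dofs(b) + 1;
        X(off + c) = Ke(a, b);
        ++c;
      }
  }
  return Rcpp::List::create(Rcpp::Named("i") = I, Rcpp::Named("j") = J,
                            Rcpp::Named("x") = X, Rcpp::Named("vol") = vol,
                            Rcpp::Named("detj_min") = detj_min);
}

//' @noRd
// [[Rcpp::export(name = ".elem_strain_batch")]]
arma::mat elem_strain_batch(const arma::mat& nodes, const arma::imat& conn,
                            int kind, const arma::vec& u) {
  int m = conn.n_rows, k = kind_nnode(kind);
  mat q = kind_quadrature(kind);
  int nq = q.n_rows;
  std::vector<vec> Ns(nq);
  std::vector<mat> dNs(nq);
  for (int iq = 0; iq < nq; ++iq)
    shape_eval(kind, q(iq, 0), q(iq, 1), q(iq, 2), Ns[iq], dNs[iq]);

  mat out(m, 7, fill::zeros);
  mat coords(k, 3);
  vec ue(3 * k);
  for (int e = 0; e < m; ++e) {
    for (int n = 0; n < k; ++n) {
      int nid = conn(e, n) - 1;
      coords.row(n) = nodes.row(nid);
      for (int d = 0; d < 3; ++d) ue(3 * n + d) = u(3 * nid + d);
    }
    vec eps(6, fill::zeros);
    double v = 0.0;
    for (int iq = 0; iq < nq; ++iq) {
      mat Jm = dNs[iq].t() * coords;
      double dj = det(Jm);
      mat dNdx = dNs[iq] * inv(Jm).t();
      mat B = build_B(dNdx);
      double w = q(iq, 3) * dj;
      eps += (B * ue) * w;
      v += w;
    }
    eps /= v;
    for (int c = 0; c < 6; ++c) out(e, c) = eps(c);
    out(e, 6) = v;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".elem_volume_batch")]]
arma::vec elem_volume_batch(const arma::mat& nodes, const arma::imat& conn,
                            int kind) {
  int m = conn.n_rows, k = kind_nnode(kind);
  mat q = kind_quadrature(kind);
  int nq = q.n_rows;
  std::vector<vec> Ns(nq);
  std::vector<mat> dNs(nq);
  for (int iq = 0; iq < nq; ++iq)
    shape_eval(kind, q(iq, 0), q(iq, 1), q(iq, 2), Ns[iq], dNs[iq]);
  vec vol(m, fill::zeros);
  mat coords(k, 3);
  for (int e = 0; e < m; ++e) {
    for (int n = 0; n < k; ++n) coords.row(n) = nodes.row(conn(e, n) - 1);
    double v = 0.0;
    for (int iq = 0; iq < nq; ++iq) {
      mat Jm = dNs[iq].t() * coords;
      v += q(iq, 3) * det(Jm);
    }
    vol(e) = v;
  }
  return vol;
}

// principal strains of symmetric tensors given as (xx,yy,zz,xy,yz,xz) with
// engineering shear; returns eigenvalues sorted descending
//' @noRd
// [[Rcpp::export(name = ".principal_batch")]]
arma::mat principal_batch(const arma::mat& strain6) {
  int m = strain6.n_rows;
  mat out(m, 3);
  mat T(3, 3);
  vec ev;
  for (int e = 0; e < m; ++e) {
    T(0, 0) = strain6(e, 0); T(1, 1) = strain6(e, 1); T(2, 2) = strain6(e, 2);
    T(0, 1) = T(1, 0) = 0.5 * strain6(e, 3);
    T(1, 2) = T(2, 1) = 0.5 * strain6(e, 4);
    T(0, 2) = T(2, 0) = 0.5 * strain6(e, 5);
    eig_sym(ev, T); // ascending
    out(e, 0) = ev(2); out(e, 1) = ev(1); out(e, 2) = ev(0);
  }
  return out;
}
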