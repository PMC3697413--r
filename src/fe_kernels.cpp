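// Finite-element kernels: 8-node hexahedra, 2x2x2 Gauss quadrature,
// transversely isotropic hyperelastic passive stress plus active fiber
// tension, total-Lagrangian residual and tangent assembly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Local node coordinates, standard hexahedron ordering (bottom face CCW,
// then top face CCW).
static const double XI_NODE[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}
};

static void hex_shape(const vec &xi, vec &N, mat &dN) {
  // N: 8, dN: 8x3 (d/dxi)
  for (int a = 0; a < 8; ++a) {
    const double sa = XI_NODE[a][0], sb = XI_NODE[a][1], sc = XI_NODE[a][2];
    const double f1 = 1.0 + sa * xi(0), f2 = 1.0 + sb * xi(1), f3 = 1.0 + sc * xi(2);
    N(a) = 0.125 * f1 * f2 * f3;
    dN(a, 0) = 0.125 * sa * f2 * f3;
    dN(a, 1) = 0.125 * f1 * sb * f3;
    dN(a, 2) = 0.125 * f1 * f2 * sc;
  }
}

// 2x2x2 Gauss points
static void gauss_points(mat &pts, vec &wts) {
  const double g = 1.0 / std::sqrt(3.0);
  pts.set_size(8, 3);
  wts.set_size(8);
  int k = 0;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int l = 0; l < 2; ++l) {
        pts(k, 0) = (i == 0 ? -g : g);
        pts(k, 1) = (j == 0 ? -g : g);
        pts(k, 2) = (l == 0 ? -g : g);
        wts(k) = 1.0;
        ++k;
      }
}

// Passive strain energy.
// pp = (mu, c1, c2, kappa)
static double passive_energy(const mat &F, const vec &a0, const vec &pp) {
  const double mu = pp(0), c1 = pp(1), c2 = pp(2), kappa = pp(3);
  const double J = det(F);
  if (J <= 0.0) Rcpp::stop("non-positive Jacobian determinant in strain energy");
  mat C = F.t() * F;
  const double I1 = trace(C);
  const double I1bar = std::pow(J, -2.0 / 3.0) * I1;
  double W = 0.5 * mu * (I1bar - 3.0);
  const double lam = std::sqrt(as_scalar(a0.t() * C * a0));
  if (lam > 1.0) W += c1 * (std::exp(c2 * (lam - 1.0) * (lam - 1.0)) - 1.0);
  const double lnJ = std::log(J);
  W += 0.5 * kappa * lnJ * lnJ;
  return W;
}

// Active fiber tension (kPa) from sarcomere length.
// ap = (Tmax, Ca0, Ca0max, B, l0, lr)
static double active_tension_c(double lam, double activation, const vec &ap) {
  if (activation <= 0.0) return 0.0;
  const double Tmax = ap(0), Ca0 = ap(1), Ca0max = ap(2), B = ap(3),
               l0 = ap(4), lr = ap(5);
  const double l = lam * lr;
  if (l <= l0) return 0.0;
  const double denom = std::exp(B * (l - l0)) - 1.0;
  const double eca50 = Ca0max / std::sqrt(denom);
  return Tmax * Ca0 * Ca0 / (Ca0 * Ca0 + eca50 * eca50) * activation;
}

// First Piola-Kirchhoff stress, passive + active.
static mat pk1_total(const mat &F, const vec &a0, const vec &pp,
                     const vec &ap, double activation) {
  const double mu = pp(0), c1 = pp(1), c2 = pp(2), kappa = pp(3);
  const double J = det(F);
  if (J <= 0.0) Rcpp::stop("non-positive Jacobian determinant in stress");
  mat C = F.t() * F;
  mat invC = inv_sympd(0.5 * (C + C.t()));
  const double I1 = trace(C);
  mat I3 = eye(3, 3);
  // isochoric neo-Hookean matrix
  mat S = mu * std::pow(J, -2.0 / 3.0) * (I3 - (I1 / 3.0) * invC);
  // exponential fiber reinforcement, tension only
  const double lam = std::sqrt(as_scalar(a0.t() * C * a0));
  if (lam > 1.0) {
    const double dWdl =
        c1 * std::exp(c2 * (lam - 1.0) * (lam - 1.0)) * 2.0 * c2 * (lam - 1.0);
    S += (dWdl / lam) * (a0 * a0.t());
  }
  // volumetric penalty
  S += kappa * std::log(J) * invC;
  mat P = F * S;
  // active stress: Cauchy Ta (ahat x ahat), push-forward of a0
  const double Ta = active_tension_c(lam, activation, ap);
  if (Ta > 0.0) {
    vec fa = F * a0;                      // |fa| = lam
    mat sig_act = (Ta / (lam * lam)) * (fa * fa.t());
    P += J * sig_act * inv(F).t();
  }
  return P;
}

// [[Rcpp::export(name = ".cppPassiveEnergy")]]
double cpp_passive_energy(const arma::mat &F, const arma::vec &a0,
                          const arma::vec &pp) {
  return passive_energy(F, a0, pp);
}

// [[Rcpp::export(name = ".cppPK1")]]
arma::mat cpp_pk1(const arma::mat &F, const arma::vec &a0, const arma::vec &pp,
                  const arma::vec &ap, double activation) {
  return pk1_total(F, a0, pp, ap, activation);
}

// [[Rcpp::export(name = ".cppCauchy")]]
arma::mat cpp_cauchy(const arma::mat &F, const arma::vec &a0,
                     const arma::vec &pp, const arma::vec &ap,
                     double activation) {
  mat P = pk1_total(F, a0, pp, ap, activation);
  mat sig = P * F.t() / det(F);
  return 0.5 * (sig + sig.t());
}

// dP/dF at a quadrature point by central differences; A is 9x9 with
// column-major 3x3 flattening (index i + 3*J).
static void dPdF(const mat &F, const vec &a0, const vec &pp, const vec &ap,
                 double activation, mat &A) {
  const double h = 1e-6 * std::max(1.0, norm(F, "fro"));
  mat Fp = F, Fm = F;
  for (int c = 0; c < 9; ++c) {
    const int i = c % 3, J = c / 3;
    Fp(i, J) += h;
    Fm(i, J) -= h;
    mat Pp = pk1_total(Fp, a0, pp, ap, activation);
    mat Pm = pk1_total(Fm, a0, pp, ap, activation);
    mat D = (Pp - Pm) / (2.0 * h);
    A.col(c) = vectorise(D);
    Fp(i, J) = F(i, J);
    Fm(i, J) = F(i, J);
  }
}

// Assemble internal force and (optionally) tangent triplets.
// nodes: N x 3 reference coords; elems: E x 8 (1-based node ids);
// disp: N x 3; fibers: (E*8) x 3 reference fiber per quadrature point
// (element-major, gp fastest); activation: scalar.
// [[Rcpp::export(name = ".cppAssemble")]]
Rcpp::List fe_assemble(const arma::mat &nodes, const arma::imat &elems,
                       const arma::mat &disp, const arma::mat &fibers,
                       double activation, const arma::vec &pp,
                       const arma::vec &ap, bool tangent) {
  const int nel = elems.n_rows, nn = nodes.n_rows;
  mat gp;
  vec gw;
  gauss_points(gp, gw);

  // precompute shape gradients at each gp
  std::vector<mat> dN_gp(8);
  vec Nv(8);
  for (int q = 0; q < 8; ++q) {
    mat dN(8, 3);
    hex_shape(gp.row(q).t(), Nv, dN);
    dN_gp[q] = dN;
  }

  mat fint(nn, 3, fill::zeros);
  const int ntrip = tangent ? nel * 24 * 24 : 0;
  Rcpp::IntegerVector ti(ntrip), tj(ntrip);
  Rcpp::NumericVector tx(ntrip);
  int pos = 0;

  mat A(9, 9);
  for (int e = 0; e < nel; ++e) {
    mat Xe(8, 3), ue(8, 3);
    for (int a = 0; a < 8; ++a) {
      const int nid = elems(e, a) - 1;
      Xe.row(a) = nodes.row(nid);
      ue.row(a) = disp.row(nid);
    }
    mat Ke;
    if (tangent) Ke = zeros(24, 24);
    mat fe(8, 3, fill::zeros);
    for (int q = 0; q < 8; ++q) {
      mat Jref = Xe.t() * dN_gp[q]; // dX/dxi
      const double detJ = det(Jref);
      if (detJ <= 0.0)
        Rcpp::stop("element %d has non-positive reference Jacobian", e + 1);
      mat dNdX = dN_gp[q] * inv(Jref); // 8x3
      mat F = eye(3, 3) + ue.t() * dNdX;
      if (det(F) <= 0.0)
        Rcpp::stop("inverted element %d (det F <= 0) at quadrature point %d",
                   e + 1, q + 1);
      vec a0 = fibers.row(e * 8 + q).t();
      mat P = pk1_total(F, a0, pp, ap, activation);
      const double wv = gw(q) * detJ;
      fe += wv * dNdX * P.t();
      if (tangent) {
        dPdF(F, a0, pp, ap, activation, A);
        // K[3a+i,3b+k] += dN_a/dX_J A[(i,J),(k,L)] dN_b/dX_L wv
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b)
            for (int i = 0; i < 3; ++i)
              for (int k = 0; k < 3; ++k) {
                double s = 0.0;
                for (int J = 0; J < 3; ++J)
                  for (int L = 0; L < 3; ++L)
                    s += dNdX(a, J) * A(i + 3 * J, k + 3 * L) * dNdX(b, L);
                Ke(3 * a + i, 3 * b + k) += s * wv;
              }
      }
    }
    for (int a = 0; a < 8; ++a)
      fint.row(elems(e, a) - 1) += fe.row(a);
    if (tangent) {
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b)
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              ti[pos] = 3 * (elems(e, a) - 1) + i + 1;
              tj[pos] = 3 * (elems(e, b) - 1) + k + 1;
              tx[pos] = Ke(3 * a + i, 3 * b + k);
              ++pos;
            }
    }
  }
  return Rcpp::List::create(Rcpp::Named("fint") = fint,
                            Rcpp::Named("i") = ti, Rcpp::Named("j") = tj,
                            Rcpp::Named("x") = tx);
}

// Deformation gradients at the 8 quadrature points of every element.
// Returns (E*8) x 9 (column-major flattened F), element-major.
// [[Rcpp::export(name = ".cppDefGrad")]]
arma::mat fe_defgrad(const arma::mat &nodes, const arma::imat &elems,
                     const arma::mat &disp) {
  const int nel = elems.n_rows;
  mat gp;
  vec gw;
  gauss_points(gp, gw);
  std::vector<mat> dN_gp(8);
  vec Nv(8);
  for (int q = 0; q < 8; ++q) {
    mat dN(8, 3);
    hex_shape(gp.row(q).t(), Nv, dN);
    dN_gp[q] = dN;
  }
  mat out(nel * 8, 9);
  for (int e = 0; e < nel; ++e) {
    mat Xe(8, 3), ue(8, 3);
    for (int a = 0; a < 8; ++a) {
      const int nid = elems(e, a) - 1;
      Xe.row(a) = nodes.row(nid);
      ue.row(a) = disp.row(nid);
    }
    for (int q = 0; q < 8; ++q) {
      mat Jref = Xe.t() * dN_gp[q];
      mat dNdX = dN_gp[q] * inv(Jref);
      mat F = eye(3, 3) + ue.t() * dNdX;
      out.row(e * 8 + q) = vectorise(F).t();
    }
  }
  return out;
}

// Quadrature data: reference positions of the 8 Gauss points per element,
// integration weights (w * detJ), and the shape-function values N (8x8,
// row = gp, col = node) shared by all elements.
// [[Rcpp::export(name = ".cppQuadrature")]]
Rcpp::List fe_quadrature(const arma::mat &nodes, const arma::imat &elems) {
  const int nel = elems.n_rows;
  mat gp;
  vec gw;
  gauss_points(gp, gw);
  mat Nmat(8, 8);
  std::vector<mat> dN_gp(8);
  for (int q = 0; q < 8; ++q) {
    vec Nv(8);
    mat dN(8, 3);
    hex_shape(gp.row(q).t(), Nv, dN);
    Nmat.row(q) = Nv.t();
    dN_gp[q] = dN;
  }
  mat pts(nel * 8, 3);
  vec wts(nel * 8);
  for (int e = 0; e < nel; ++e) {
    mat Xe(8, 3);
    for (int a = 0; a < 8; ++a)
      Xe.row(a) = nodes.row(elems(e, a) - 1);
    for (int q = 0; q < 8; ++q) {
      pts.row(e * 8 + q) = Nmat.row(q) * Xe;
      mat Jref = Xe.t() * dN_gp[q];
      wts(e * 8 + q) = gw(q) * det(Jref);
    }
  }
  return Rcpp::List::create(Rcpp::Named("points") = pts,
                            Rcpp::Named("weights") = wts,
                            Rcpp::Named("N") = Nmat);
}
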