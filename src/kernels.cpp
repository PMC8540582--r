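#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Compiled kernels: Neo-Hookean element assembly over linear tetrahedra and
// brute-force surface distance queries (closest point on triangle, generalized
// winding number). vec() ordering is column-major: index(i,j) = i + 3*j.

// [[Rcpp::export]]
List fem_assemble_cpp(const arma::mat& pos,       // 3 x nnode deformed positions
                      const IntegerMatrix& tets,  // ne x 4, 1-based node indices
                      const arma::cube& basis,    // 3 x 3 x ne, Bm = inv(Dm)
                      const arma::vec& w,         // ne rest volumes (mm^3)
                      double mu, double lambda,
                      bool want_hessian, bool project_spd) {
  const int ne = tets.nrow();
  const int nn = pos.n_cols;
  double energy = 0.0;
  arma::vec grad(3 * (size_t)nn, arma::fill::zeros);

  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_hessian) {
    ti.reserve((size_t)ne * 144);
    tj.reserve((size_t)ne * 144);
    tx.reserve((size_t)ne * 144);
  }

  arma::mat H9(9, 9);
  arma::mat Z(9, 12);
  arma::mat K(12, 12);
  arma::vec eval;
  arma::mat evec;

  for (int e = 0; e < ne; ++e) {
    const int a = tets(e, 0) - 1, b = tets(e, 1) - 1,
              c = tets(e, 2) - 1, d = tets(e, 3) - 1;
    arma::mat33 Ds;
    Ds.col(0) = pos.col(b) - pos.col(a);
    Ds.col(1) = pos.col(c) - pos.col(a);
    Ds.col(2) = pos.col(d) - pos.col(a);
    const arma::mat33 Bm = basis.slice(e);
    const arma::mat33 F = Ds * Bm;
    const double J = arma::det(F);
    if (!(J > 0.0) || !std::isfinite(J)) {
      return List::create(_["evaluable"] = false,
                          _["bad_element"] = e + 1,
                          _["det_f"] = J);
    }
    const double logJ = std::log(J);
    energy += w(e) * (0.5 * mu * (arma::accu(F % F) - 3.0)
                      - mu * logJ + 0.5 * lambda * logJ * logJ);

    const arma::mat33 FinvT = arma::inv(F).t();
    const arma::mat33 P = mu * (F - FinvT) + lambda * logJ * FinvT;
    const arma::mat33 G = w(e) * P * Bm.t();  // force grads on nodes b, c, d
    for (int i = 0; i < 3; ++i) {
      grad(3 * (size_t)a + i) -= G(i, 0) + G(i, 1) + G(i, 2);
      grad(3 * (size_t)b + i) += G(i, 0);
      grad(3 * (size_t)c + i) += G(i, 1);
      grad(3 * (size_t)d + i) += G(i, 2);
    }

    if (!want_hessian) continue;

    // dP_ij/dF_kl = mu d_ik d_jl + (mu - lambda logJ) FinvT_il FinvT_kj
    //              + lambda FinvT_ij FinvT_kl
    const double coef = mu - lambda * logJ;
    for (int l = 0; l < 3; ++l)
      for (int k = 0; k < 3; ++k)
        for (int j = 0; j < 3; ++j)
          for (int i = 0; i < 3; ++i) {
            double v = coef * FinvT(i, l) * FinvT(k, j)
                     + lambda * FinvT(i, j) * FinvT(k, l);
            if (i == k && j == l) v += mu;
            H9(i + 3 * j, k + 3 * l) = v;
          }

    // Z maps the 12 nodal displacement components to vec(dF)
    Z.zeros();
    for (int j = 0; j < 3; ++j) {
      const double colsum = Bm(0, j) + Bm(1, j) + Bm(2, j);
      for (int i = 0; i < 3; ++i) {
        Z(i + 3 * j, i) = -colsum;
        Z(i + 3 * j, i + 3) = Bm(0, j);
        Z(i + 3 * j, i + 6) = Bm(1, j);
        Z(i + 3 * j, i + 9) = Bm(2, j);
      }
    }
    K = w(e) * (Z.t() * H9 * Z);
    K = 0.5 * (K + K.t());
    if (project_spd) {
      arma::eig_sym(eval, evec, K);
      bool any_neg = false;
      for (arma::uword q = 0; q < eval.n_elem; ++q)
        if (eval(q) < 0.0) { eval(q) = 0.0; any_neg = true; }
      if (any_neg) K = evec * arma::diagmat(eval) * evec.t();
    }

    const int nodes[4] = {a, b, c, d};
    int dof[12];
    for (int m = 0; m < 4; ++m)
      for (int i = 0; i < 3; ++i) dof[3 * m + i] = 3 * nodes[m] + i + 1;
    for (int cc = 0; cc < 12; ++cc)
      for (int rr = 0; rr < 12; ++rr) {
        ti.push_back(dof[rr]);
        tj.push_back(dof[cc]);
        tx.push_back(K(rr, cc));
      }
  }

  List out = List::create(_["evaluable"] = true,
                          _["energy"] = energy,
                          _["gradient"] = grad);
  if (want_hessian) {
    out["hi"] = wrap(ti);
    out["hj"] = wrap(tj);
    out["hx"] = wrap(tx);
  }
  return out;
}

static arma::vec3 closest_on_tri(const arma::vec3& p, const arma::vec3& a,
                                 const arma::vec3& b, const arma::vec3& c) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  const arma::vec3 ab = b - a, ac = c - a, ap = p - a;
  const double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  const arma::vec3 bp = p - b;
  const double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  const arma::vec3 cp = p - c;
  const double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double wv = d2 / (d2 - d6);
    return a + wv * ac;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double wv = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + wv * (c - b);
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, wv = vc * denom;
  return a + ab * v + ac * wv;
}

// [[Rcpp::export]]
List closest_point_cpp(const arma::mat& P,        // 3 x np query points
                       const arma::mat& V,        // 3 x nv surface vertices
                       const IntegerMatrix& F) {  // nf x 3, 1-based
  const int np = P.n_cols, nf = F.nrow();
  arma::vec dist(np);
  arma::mat point(3, np);
  IntegerVector face(np);
  for (int q = 0; q < np; ++q) {
    const arma::vec3 p = P.col(q);
    double best = std::numeric_limits<double>::infinity();
    arma::vec3 bp;
    int bf = NA_INTEGER;
    for (int f = 0; f < nf; ++f) {
      const arma::vec3 cp = closest_on_tri(p, V.col(F(f, 0) - 1),
                                           V.col(F(f, 1) - 1),
                                           V.col(F(f, 2) - 1));
      const double d2 = arma::dot(p - cp, p - cp);
      if (d2 < best) { best = d2; bp = cp; bf = f + 1; }
    }
    dist(q) = std::sqrt(best);
    point.col(q) = bp;
    face[q] = bf;
  }
  return List::create(_["dist"] = dist, _["point"] = point, _["face"] = face);
}

// [[Rcpp::export]]
arma::vec winding_number_cpp(const arma::mat& P, const arma::mat& V,
                             const IntegerMatrix& F) {
  // Generalized winding number: sum of signed solid angles / 4*pi
  // (van Oosterom & Strackee solid-angle formula per triangle).
  const int np = P.n_cols, nf = F.nrow();
  arma::vec wn(np, arma::fill::zeros);
  for (int q = 0; q < np; ++q) {
    const arma::vec3 p = P.col(q);
    double total = 0.0;
    for (int f = 0; f < nf; ++f) {
      const arma::vec3 a = V.col(F(f, 0) - 1) - p;
      const arma::vec3 b = V.col(F(f, 1) - 1) - p;
      const arma::vec3 c = V.col(F(f, 2) - 1) - p;
      const double la = arma::norm(a), lb = arma::norm(b), lc = arma::norm(c);
      const double det = arma::dot(a, arma::cross(b, c));
      const double den = la * lb * lc + arma::dot(a, b) * lc
                       + arma::dot(b, c) * la + arma::dot(c, a) * lb;
      total += 2.0 * std::atan2(det, den);
    }
    wn(q) = total / (4.0 * M_PI);
  }
  return wn;
}
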