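// Quadratic-tetrahedron total-Lagrangian FEM kernels: hyperelastic material
// point evaluations, sparse tangent/residual assembly and nodal strain
// recovery.  Geometry is straight-sided (subparametric): the Jacobian of the
// reference map is constant per element and computed from the 4 vertices.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::mat::fixed<3, 3> mat33;
typedef arma::vec::fixed<3> vec3;

namespace {

struct Mat {
  int type;          // 1 = Ogden raw stretches, 2 = Ogden isochoric, 3 = StVK
  double p1, p2, p3; // Ogden: mu1, alpha1, d1;  StVK: lambda, mu, unused
};

// First Piola-Kirchhoff stress and energy density.  Returns false when the
// deformation state is inadmissible (det F <= 0).
bool pk1_point(const mat33 &F, const Mat &m, mat33 &P, double &psi) {
  const double J = arma::det(F);
  if (!(J > 1e-6) || !(J < 1e6) || !F.is_finite()) return false;
  if (m.type == 3) { // St. Venant-Kirchhoff (silicon / linearized tissue)
    const double lam = m.p1, mu = m.p2;
    mat33 E = 0.5 * (F.t() * F - arma::eye(3, 3));
    const double trE = arma::trace(E);
    mat33 S = lam * trE * arma::eye(3, 3) + 2.0 * mu * E;
    P = F * S;
    psi = 0.5 * lam * trE * trE + mu * arma::accu(E % E);
    return true;
  }
  const double mu = m.p1, alpha = m.p2, d1 = m.p3;
  mat33 C = F.t() * F;
  vec3 ev;
  mat33 N;
  if (!arma::eig_sym(ev, N, C)) return false;
  vec3 lam;
  for (int i = 0; i < 3; ++i) lam(i) = std::sqrt(std::max(ev(i), 1e-24));
  // stretches far outside the model's validity produce ~1e40-scale powers
  // of the stiff Ogden exponent (denormal-poisoned linear algebra);
  // treat such states as inadmissible so the step is cut back instead
  if (lam(0) < 0.35 || lam(2) > 3.0) return false;
  const double dvol = (2.0 / d1) * (J - 1.0);
  vec3 dpsi; // dPsi/dlambda_i
  double dev;
  if (m.type == 1) { // raw principal stretches, exactly as printed
    dev = 0.0;
    for (int i = 0; i < 3; ++i) dev += std::pow(lam(i), -alpha);
    for (int i = 0; i < 3; ++i)
      dpsi(i) = -mu * std::pow(lam(i), -alpha - 1.0) + dvol * J / lam(i);
    psi = (mu / alpha) * (dev - 3.0) + (1.0 / d1) * (J - 1.0) * (J - 1.0);
  } else {           // isochoric stretches lambda_bar = J^(-1/3) lambda
    const double Jb = std::cbrt(J);
    vec3 lb = lam / Jb;
    double spow = 0.0; // sum lb^-alpha
    dev = 0.0;
    for (int i = 0; i < 3; ++i) {
      spow += std::pow(lb(i), -alpha);
      dev += std::pow(lb(i), -alpha);
    }
    for (int i = 0; i < 3; ++i)
      dpsi(i) = -mu / Jb * std::pow(lb(i), -alpha - 1.0) +
                (mu / (3.0 * lam(i))) * spow + dvol * J / lam(i);
    psi = (mu / alpha) * (dev - 3.0) + (1.0 / d1) * (J - 1.0) * (J - 1.0);
  }
  mat33 S(arma::fill::zeros);
  for (int i = 0; i < 3; ++i)
    S += (dpsi(i) / lam(i)) * (N.col(i) * N.col(i).t());
  P = F * S;
  return true;
}

// Material tangent A_iJkL = dP_iJ/dF_kL by forward differences on pk1_point.
bool tangent_fd(const mat33 &F, const Mat &m, const mat33 &P0, double A[3][3][3][3]) {
  const double h = 1e-7 * (1.0 + arma::norm(F, "fro"));
  mat33 Fp, Pp;
  double psi;
  for (int k = 0; k < 3; ++k)
    for (int L = 0; L < 3; ++L) {
      Fp = F;
      Fp(k, L) += h;
      if (!pk1_point(Fp, m, Pp, psi)) return false;
      for (int i = 0; i < 3; ++i)
        for (int J = 0; J < 3; ++J) A[i][J][k][L] = (Pp(i, J) - P0(i, J)) / h;
    }
  return true;
}

// 4-point Gauss rule on the reference tetrahedron (degree 2).
const double QA = 0.5854101966249685, QB = 0.1381966011250105;
const double GP[4][4] = {{QA, QB, QB, QB}, {QB, QA, QB, QB}, {QB, QB, QA, QB}, {QB, QB, QB, QA}};
const int EDGE[6][2] = {{0, 1}, {0, 2}, {0, 3}, {1, 2}, {1, 3}, {2, 3}};

// Shape-function gradients of the 10 nodes at barycentric point lam (4),
// given gradients gl (4 x 3) of the barycentric coordinates.
void tet10_grads(const double lam[4], const arma::mat &gl, arma::mat &G) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 3; ++j) G(i, j) = (4.0 * lam[i] - 1.0) * gl(i, j);
  for (int e = 0; e < 6; ++e) {
    int a = EDGE[e][0], b = EDGE[e][1];
    for (int j = 0; j < 3; ++j)
      G(4 + e, j) = 4.0 * (lam[a] * gl(b, j) + lam[b] * gl(a, j));
  }
}

// Constant barycentric gradients and volume from the 4 vertex coordinates.
// Returns false for non-positive Jacobian.
bool bary_grads(const arma::mat &Xe, arma::mat &gl, double &vol) {
  mat33 D;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) D(i, j) = Xe(j + 1, i) - Xe(0, i);
  const double det = arma::det(D);
  if (!(det > 0)) return false;
  vol = det / 6.0;
  mat33 Di = arma::inv(D);
  for (int k = 0; k < 3; ++k)
    for (int j = 0; j < 3; ++j) gl(k + 1, j) = Di(k, j);
  for (int j = 0; j < 3; ++j) gl(0, j) = -gl(1, j) - gl(2, j) - gl(3, j);
  return true;
}

Mat mat_from_row(const arma::mat &matpar, int region) {
  Mat m;
  m.type = static_cast<int>(matpar(region - 1, 0));
  m.p1 = matpar(region - 1, 1);
  m.p2 = matpar(region - 1, 2);
  m.p3 = matpar(region - 1, 3);
  return m;
}

} // namespace

// Single-point stress evaluation (exposed for verification tests).
// [[Rcpp::export(name = ".pk1_stress_cpp")]]
List pk1_stress_cpp(const arma::mat &F, int type, double p1, double p2, double p3) {
  Mat m{type, p1, p2, p3};
  mat33 Ff = F, P;
  double psi;
  if (!pk1_point(Ff, m, P, psi)) stop("inadmissible deformation state: det(F) <= 0");
  return List::create(_["P"] = arma::mat(P), _["psi"] = psi);
}

// Sparsity pattern of the upper triangle of the reduced tangent, plus a
// per-element slot table mapping local dof pairs to positions in the CSC
// value array.  dofmap: length 3*nnode, 0-based free-dof index or -1.
// [[Rcpp::export(name = ".fem_pattern_cpp")]]
List fem_pattern_cpp(const IntegerMatrix &T10, const IntegerVector &dofmap, int nfree) {
  const R_xlen_t ne = T10.nrow();
  const int npair = 465; // 30*31/2
  std::vector<uint64_t> keys;
  keys.reserve(static_cast<size_t>(ne) * 200);
  for (R_xlen_t e = 0; e < ne; ++e) {
    int gd[30];
    for (int a = 0; a < 10; ++a) {
      const int n = T10(e, a) - 1;
      for (int i = 0; i < 3; ++i) gd[3 * a + i] = dofmap[3 * n + i];
    }
    for (int p = 0; p < 30; ++p) {
      if (gd[p] < 0) continue;
      for (int q = p; q < 30; ++q) {
        if (gd[q] < 0) continue;
        uint32_t r = std::min(gd[p], gd[q]), c = std::max(gd[p], gd[q]);
        keys.push_back((static_cast<uint64_t>(c) << 32) | r);
      }
    }
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  const size_t nnz = keys.size();
  IntegerVector pi(nnz), pp(nfree + 1);
  {
    size_t k = 0;
    for (int c = 0; c <= nfree; ++c) pp[c] = 0;
    for (size_t s = 0; s < nnz; ++s) {
      pi[s] = static_cast<int>(keys[s] & 0xffffffffu);
      pp[(keys[s] >> 32) + 1]++;
      (void)k;
    }
    for (int c = 0; c < nfree; ++c) pp[c + 1] += pp[c];
  }
  IntegerVector slot(ne * static_cast<R_xlen_t>(npair));
  for (R_xlen_t e = 0; e < ne; ++e) {
    int gd[30];
    for (int a = 0; a < 10; ++a) {
      const int n = T10(e, a) - 1;
      for (int i = 0; i < 3; ++i) gd[3 * a + i] = dofmap[3 * n + i];
    }
    R_xlen_t base = e * npair;
    int idx = 0;
    for (int p = 0; p < 30; ++p)
      for (int q = p; q < 30; ++q, ++idx) {
        if (gd[p] < 0 || gd[q] < 0) { slot[base + idx] = -1; continue; }
        uint32_t r = std::min(gd[p], gd[q]), c = std::max(gd[p], gd[q]);
        uint64_t key = (static_cast<uint64_t>(c) << 32) | r;
        const uint64_t *lo = std::lower_bound(keys.data(), keys.data() + nnz, key);
        slot[base + idx] = static_cast<int>(lo - keys.data());
      }
  }
  return List::create(_["i"] = pi, _["p"] = pp, _["slot"] = slot, _["nnz"] = static_cast<double>(nnz));
}

// Assemble internal-force residual (on free dofs), total strain energy and,
// optionally, the symmetrized tangent values into Kx (zeroed here).
// u: full displacement vector (3*nnode) including prescribed entries.
// [[Rcpp::export(name = ".fem_assemble_cpp")]]
List fem_assemble_cpp(const arma::mat &X, const IntegerMatrix &T10,
                      const IntegerVector &region, const arma::mat &matpar,
                      const arma::vec &u, const IntegerVector &dofmap, int nfree,
                      const IntegerVector &slot, NumericVector Kx, bool want_tangent) {
  const R_xlen_t ne = T10.nrow();
  const int npair = 465;
  arma::vec res(nfree, arma::fill::zeros);
  double energy = 0.0;
  bool ok = true;
  if (want_tangent) std::fill(Kx.begin(), Kx.end(), 0.0);

  arma::mat gl(4, 3), G(10, 3), Xe(10, 3), Ue(10, 3);
  double A[3][3][3][3];
  arma::mat Ke(30, 30);

  for (R_xlen_t e = 0; e < ne && ok; ++e) {
    int nid[10];
    for (int a = 0; a < 10; ++a) {
      nid[a] = T10(e, a) - 1;
      for (int j = 0; j < 3; ++j) {
        Xe(a, j) = X(nid[a], j);
        Ue(a, j) = u[3 * nid[a] + j];
      }
    }
    double vol;
    if (!bary_grads(Xe, gl, vol)) { ok = false; break; }
    const Mat m = mat_from_row(matpar, region[e]);
    const double w = vol / 4.0;
    if (want_tangent) Ke.zeros();
    arma::vec fe(30, arma::fill::zeros);
    for (int gp = 0; gp < 4 && ok; ++gp) {
      tet10_grads(GP[gp], gl, G);
      mat33 F(arma::fill::eye);
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i)
          for (int J = 0; J < 3; ++J) F(i, J) += Ue(a, i) * G(a, J);
      mat33 P;
      double psi;
      if (!pk1_point(F, m, P, psi)) { ok = false; break; }
      energy += w * psi;
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i)
          fe[3 * a + i] += w * (P(i, 0) * G(a, 0) + P(i, 1) * G(a, 1) + P(i, 2) * G(a, 2));
      if (want_tangent) {
        if (!tangent_fd(F, m, P, A)) { ok = false; break; }
        mat33 B;
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k) {
            for (int J = 0; J < 3; ++J)
              for (int L = 0; L < 3; ++L) B(J, L) = A[i][J][k][L];
            arma::mat H = G * B * G.t(); // 10 x 10
            for (int a = 0; a < 10; ++a)
              for (int b = 0; b < 10; ++b) Ke(3 * a + i, 3 * b + k) += w * H(a, b);
          }
      }
    }
    if (!ok) break;
    // non-finite or absurd entries (near-inverted elements with the stiff
    // Ogden exponent) poison the sparse factorization; fail the assembly
    // so the load step is bisected instead
    if (!fe.is_finite() || (want_tangent && !Ke.is_finite())) { ok = false; break; }
    for (int a = 0; a < 10; ++a)
      for (int i = 0; i < 3; ++i) {
        const int g = dofmap[3 * nid[a] + i];
        if (g >= 0) res[g] += fe[3 * a + i];
      }
    if (want_tangent) {
      const R_xlen_t base = e * npair;
      int idx = 0;
      for (int p = 0; p < 30; ++p)
        for (int q = p; q < 30; ++q, ++idx) {
          const int s = slot[base + idx];
          if (s >= 0) Kx[s] += 0.5 * (Ke(p, q) + Ke(q, p));
        }
    }
    if ((e & 0x3fff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["res"] = res, _["energy"] = energy, _["ok"] = ok);
}

// Nodal Hencky strain recovery.  F is evaluated at each node of every
// element in the requested regions; log-strain tensors are averaged over
// adjacent elements.  Returns the 6 tensor components (xx,yy,zz,xy,yz,xz),
// the von Mises equivalent strain (1/(1+nu) * sqrt(0.5*sum (e_i-e_j)^2))
// from principal values of the averaged tensor, and the element count.
// [[Rcpp::export(name = ".strain_recover_cpp")]]
List strain_recover_cpp(const arma::mat &X, const IntegerMatrix &T10,
                        const IntegerVector &region, const IntegerVector &use_region,
                        const arma::vec &u, double nu_eff) {
  const R_xlen_t ne = T10.nrow(), nn = X.n_rows;
  std::vector<bool> keep(256, false);
  for (int r : use_region) if (r >= 0 && r < 256) keep[r] = true;

  arma::mat eps(nn, 6, arma::fill::zeros);
  arma::ivec cnt(nn, arma::fill::zeros);
  arma::mat gl(4, 3), G(10, 3), Xe(10, 3), Ue(10, 3);

  // barycentric coordinates of the 10 nodes
  double LN[10][4];
  for (int a = 0; a < 10; ++a) for (int j = 0; j < 4; ++j) LN[a][j] = 0.0;
  for (int a = 0; a < 4; ++a) LN[a][a] = 1.0;
  for (int e = 0; e < 6; ++e) {
    LN[4 + e][EDGE[e][0]] = 0.5;
    LN[4 + e][EDGE[e][1]] = 0.5;
  }

  for (R_xlen_t e = 0; e < ne; ++e) {
    if (!keep[region[e]]) continue;
    int nid[10];
    for (int a = 0; a < 10; ++a) {
      nid[a] = T10(e, a) - 1;
      for (int j = 0; j < 3; ++j) {
        Xe(a, j) = X(nid[a], j);
        Ue(a, j) = u[3 * nid[a] + j];
      }
    }
    double vol;
    if (!bary_grads(Xe, gl, vol)) stop("inverted element in strain recovery");
    for (int a = 0; a < 10; ++a) {
      tet10_grads(LN[a], gl, G);
      mat33 F(arma::fill::eye);
      for (int b = 0; b < 10; ++b)
        for (int i = 0; i < 3; ++i)
          for (int J = 0; J < 3; ++J) F(i, J) += Ue(b, i) * G(b, J);
      mat33 C = F.t() * F;
      vec3 ev;
      mat33 N;
      if (!arma::eig_sym(ev, N, C)) stop("eigendecomposition failed in strain recovery");
      mat33 H(arma::fill::zeros);
      for (int i = 0; i < 3; ++i) {
        double le = 0.5 * std::log(std::max(ev(i), 1e-24));
        H += le * (N.col(i) * N.col(i).t());
      }
      const int n = nid[a];
      eps(n, 0) += H(0, 0); eps(n, 1) += H(1, 1); eps(n, 2) += H(2, 2);
      eps(n, 3) += H(0, 1); eps(n, 4) += H(1, 2); eps(n, 5) += H(0, 2);
      cnt[n] += 1;
    }
  }
  arma::vec vm(nn, arma::fill::zeros);
  for (R_xlen_t n = 0; n < nn; ++n) {
    if (cnt[n] == 0) continue;
    for (int j = 0; j < 6; ++j) eps(n, j) /= cnt[n];
    mat33 H = {{eps(n, 0), eps(n, 3), eps(n, 5)},
               {eps(n, 3), eps(n, 1), eps(n, 4)},
               {eps(n, 5), eps(n, 4), eps(n, 2)}};
    vec3 p;
    if (!arma::eig_sym(p, H)) stop("eigendecomposition failed in strain recovery");
    double s = (p(0) - p(1)) * (p(0) - p(1)) + (p(1) - p(2)) * (p(1) - p(2)) +
               (p(2) - p(0)) * (p(2) - p(0));
    vm[n] = std::sqrt(0.5 * s) / (1.0 + nu_eff);
  }
  return List::create(_["eps"] = eps, _["von_mises"] = arma::vec(vm),
                      _["n_contrib"] = arma::ivec(cnt));
}

// Signed volumes (positive-Jacobian check) of 4-node tets.
// [[Rcpp::export(name = ".tet_volumes_cpp")]]
NumericVector tet_volumes_cpp(const arma::mat &V, const IntegerMatrix &T) {
  const R_xlen_t ne = T.nrow();
  NumericVector vol(ne);
  for (R_xlen_t e = 0; e < ne; ++e) {
    mat33 D;
    const int v0 = T(e, 0) - 1;
    for (int j = 0; j < 3; ++j) {
      const int vj = T(e, j + 1) - 1;
      for (int i = 0; i < 3; ++i) D(i, j) = V(vj, i) - V(v0, i);
    }
    vol[e] = arma::det(D) / 6.0;
  }
  return vol;
}

// Enable flush-to-zero / denormals-are-zero floating point modes.
// Near-singular tangent states can fill partial factorizations with
// subnormal values whose arithmetic is pathologically slow; treating
// them as zero is numerically harmless at this package's scales.
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::export(name = ".set_ftz_cpp")]]
void set_ftz_cpp() {
#if defined(__SSE2__) || defined(__x86_64__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}
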