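#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// 7-point finite-difference operator for div(eps grad phi) - kappa2 phi with
// harmonic-mean face dielectrics, applied to interior nodes only (Dirichlet
// shell handled by the caller via the initial phi array). Solved with
// Jacobi-preconditioned conjugate gradients; the operator is symmetric
// positive definite after negation.

static inline double hmean(double a, double b) {
  return 2.0 * a * b / (a + b);
}

// [[Rcpp::export]]
List cg_lpbe(NumericVector eps, NumericVector kappa2, NumericVector rhs,
             NumericVector phi_bc, IntegerVector dims, NumericVector h,
             double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const double ihx2 = 1.0 / (h[0] * h[0]);
  const double ihy2 = 1.0 / (h[1] * h[1]);
  const double ihz2 = 1.0 / (h[2] * h[2]);

  std::vector<double> phi(eps.size());
  for (R_xlen_t t = 0; t < ntot; ++t) phi[t] = phi_bc[t];

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  // A x at interior node: sum_f w_f (x_c - x_nb) + kappa2_c x_c,
  // with x treated as zero outside the interior (vin = false includes the
  // Dirichlet contribution separately).
  std::vector<double> diag((size_t)ntot, 1.0);
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        R_xlen_t c = i + sy * j + sz * k;
        double e = eps[c];
        double d = kappa2[c];
        d += hmean(e, eps[c - sx]) * ihx2 + hmean(e, eps[c + sx]) * ihx2;
        d += hmean(e, eps[c - sy]) * ihy2 + hmean(e, eps[c + sy]) * ihy2;
        d += hmean(e, eps[c - sz]) * ihz2 + hmean(e, eps[c + sz]) * ihz2;
        diag[c] = d;
      }

  // interior-only matvec: out = A * v (v must vanish on the boundary shell)
  auto matvec = [&](const std::vector<double>& v, std::vector<double>& out) {
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          R_xlen_t c = i + sy * j + sz * k;
          double e = eps[c], vc = v[c], acc = kappa2[c] * vc;
          acc += hmean(e, eps[c - sx]) * ihx2 * (vc - v[c - sx]);
          acc += hmean(e, eps[c + sx]) * ihx2 * (vc - v[c + sx]);
          acc += hmean(e, eps[c - sy]) * ihy2 * (vc - v[c - sy]);
          acc += hmean(e, eps[c + sy]) * ihy2 * (vc - v[c + sy]);
          acc += hmean(e, eps[c - sz]) * ihz2 * (vc - v[c - sz]);
          acc += hmean(e, eps[c + sz]) * ihz2 * (vc - v[c + sz]);
          out[c] = acc;
        }
  };

  auto interior_dot = [&](const std::vector<double>& a,
                          const std::vector<double>& b) {
    double s = 0.0;
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j) {
        R_xlen_t base = sy * j + sz * k;
        for (int i = 1; i < nx - 1; ++i) s += a[base + i] * b[base + i];
      }
    return s;
  };

  // effective RHS: b - A * phi_bc (boundary values folded in); x starts at 0
  std::vector<double> bc_only((size_t)ntot, 0.0), tmp((size_t)ntot, 0.0);
  for (R_xlen_t t = 0; t < ntot; ++t) bc_only[t] = phi_bc[t];
  // zero interior of bc_only
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) bc_only[i + sy * j + sz * k] = 0.0;
  matvec(bc_only, tmp);
  std::vector<double> b((size_t)ntot, 0.0);
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        R_xlen_t c = i + sy * j + sz * k;
        b[c] = rhs[c] - tmp[c];
      }

  double bnorm = std::sqrt(interior_dot(b, b));
  std::vector<double> x((size_t)ntot, 0.0), r = b, z((size_t)ntot, 0.0),
      p((size_t)ntot, 0.0), Ap((size_t)ntot, 0.0);

  bool converged = false;
  int it = 0;
  double relres = 0.0;
  if (bnorm == 0.0) {
    converged = true;
  } else {
    for (R_xlen_t t = 0; t < ntot; ++t) z[t] = r[t] / diag[t];
    // keep boundary entries of work vectors at zero
    p = z;
    double rz = interior_dot(r, z);
    for (it = 1; it <= maxit; ++it) {
      matvec(p, Ap);
      double pAp = interior_dot(p, Ap);
      double alpha = rz / pAp;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            R_xlen_t c = i + sy * j + sz * k;
            x[c] += alpha * p[c];
            r[c] -= alpha * Ap[c];
          }
      relres = std::sqrt(interior_dot(r, r)) / bnorm;
      if (relres <= tol) { converged = true; break; }
      double rz_new = 0.0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            R_xlen_t c = i + sy * j + sz * k;
            z[c] = r[c] / diag[c];
            rz_new += r[c] * z[c];
          }
      double beta = rz_new / rz;
      rz = rz_new;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            R_xlen_t c = i + sy * j + sz * k;
            p[c] = z[c] + beta * p[c];
          }
    }
  }

  NumericVector phi_out(ntot);
  for (R_xlen_t t = 0; t < ntot; ++t) phi_out[t] = phi_bc[t];
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        R_xlen_t c = i + sy * j + sz * k;
        phi_out[c] = x[c];
      }

  return List::create(_["phi"] = phi_out, _["iterations"] = it,
                      _["residual"] = relres, _["converged"] = converged);
}
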