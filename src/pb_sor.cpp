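#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation sweep for the finite-difference
// linearized Poisson-Boltzmann equation on a regular grid.
//
// Discrete equation at interior node 0 with face dielectrics e_f:
//   sum_f e_f (phi_f - phi_0) - kap2h2_0 * phi_0 + rhs_0 = 0
// where rhs = 4 pi k_e q_node / h and kap2h2 = eps_out * kappa_bar^2 * h^2
// on nodes in the solvent region.  Boundary nodes hold Dirichlet values.
//
// Face arrays are full-size flattened (i fastest): epsx[idx] is the face
// between node (i,j,k) and (i+1,j,k); entries with i == nx-1 are unused.
//
// [[Rcpp::export]]
List pb_sor_solve(NumericVector phi, NumericVector epsx, NumericVector epsy,
                  NumericVector epsz, NumericVector kap2h2,
                  NumericVector rhs, int nx, int ny, int nz,
                  double omega, double tol, int max_iter, int check_every) {
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *kk = REAL(kap2h2), *b = REAL(rhs);
  const int sx = 1, sy = nx, sz = nx * ny;

  // norm of the source for the relative residual
  double bnorm = 0.0;
  for (int n = 0; n < nx * ny * nz; ++n) bnorm += b[n] * b[n];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;

  double resid = R_PosInf;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((j + k + 1 + color) & 1);
          int base = j * sy + k * sz;
          for (int i = istart; i < nx - 1; i += 2) {
            int n = base + i;
            double exm = ex[n - sx], exp_ = ex[n];
            double eym = ey[n - sy], eyp = ey[n];
            double ezm = ez[n - sz], ezp = ez[n];
            double diag = exm + exp_ + eym + eyp + ezm + ezp + kk[n];
            double nb = exm * p[n - sx] + exp_ * p[n + sx]
                      + eym * p[n - sy] + eyp * p[n + sy]
                      + ezm * p[n - sz] + ezp * p[n + sz];
            double pnew = (nb + b[n]) / diag;
            p[n] += omega * (pnew - p[n]);
          }
        }
      }
    }
    if (iter % check_every == 0 || iter == max_iter) {
      double rn = 0.0;
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int base = j * sy + k * sz;
          for (int i = 1; i < nx - 1; ++i) {
            int n = base + i;
            double exm = ex[n - sx], exp_ = ex[n];
            double eym = ey[n - sy], eyp = ey[n];
            double ezm = ez[n - sz], ezp = ez[n];
            double diag = exm + exp_ + eym + eyp + ezm + ezp + kk[n];
            double r = exm * p[n - sx] + exp_ * p[n + sx]
                     + eym * p[n - sy] + eyp * p[n + sy]
                     + ezm * p[n - sz] + ezp * p[n + sz]
                     - diag * p[n] + b[n];
            rn += r * r;
          }
        }
      }
      resid = std::sqrt(rn) / bnorm;
      if (resid < tol) break;
    }
  }
  return List::create(_["iterations"] = iter,
                      _["residual"] = resid,
                      _["converged"] = resid < tol);
}
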