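#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation for the 7-point finite-difference
// discretization of  div(eps grad phi) - eps_s kappa^2 phi = -4 pi C rho.
// Boundary nodes are held fixed at their (analytic) values in phi0.
//
// phi0:      initial potential, length nx*ny*nz (x fastest)
// epsX/Y/Z:  edge-midpoint dielectric arrays, dims (nx-1,ny,nz) etc.
// kappaTerm: eps_s * kappa^2 * h^2 per node (zero inside solute+Stern)
// srcTerm:   4*pi*C*q/h per node (trilinearly spread charges)
// [[Rcpp::export(name = ".sorRelax")]]
List sorRelax(NumericVector phi0, IntegerVector dims,
              NumericVector epsX, NumericVector epsY, NumericVector epsZ,
              NumericVector kappaTerm, NumericVector srcTerm,
              double omega, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi0);
  double *p = phi.begin();
  const double *ex = epsX.begin(), *ey = epsY.begin(), *ez = epsZ.begin();
  const double *kt = kappaTerm.begin(), *src = srcTerm.begin();
  const int sx = 1, sy = nx, sz = nx * ny;
  const int nxm = nx - 1, nym = ny - 1;
  double resid = R_PosInf;
  int it = 0;
  bool conv = false;
  for (it = 1; it <= maxit; ++it) {
    resid = 0.0;
    for (int color = 0; color < 2; ++color) {
      // within one color all neighbours belong to the other color, so the
      // update order inside a color is immaterial (exactly parallelisable)
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int i0 = 1 + (((1 + j + k) & 1) != color ? 1 : 0);
          for (int i = i0; i < nx - 1; i += 2) {
            const int idx = i + nx * j + sz * k;
            const int ej = j + ny * k;
            const double exm = ex[(i - 1) + nxm * ej];
            const double exp_ = ex[i + nxm * ej];
            const double eym = ey[i + nx * ((j - 1) + nym * k)];
            const double eyp = ey[i + nx * (j + nym * k)];
            const double ezm = ez[i + nx * (j + ny * (k - 1))];
            const double ezp = ez[i + nx * (j + ny * k)];
            const double num = exm * p[idx - sx] + exp_ * p[idx + sx]
                             + eym * p[idx - sy] + eyp * p[idx + sy]
                             + ezm * p[idx - sz] + ezp * p[idx + sz]
                             + src[idx];
            const double diag = exm + exp_ + eym + eyp + ezm + ezp + kt[idx];
            const double nv = (1.0 - omega) * p[idx] + omega * num / diag;
            const double d = std::fabs(nv - p[idx]);
            if (d > resid) resid = d;
            p[idx] = nv;
          }
        }
      }
    }
    if (!std::isfinite(resid))
      stop("NaN encountered during SOR iteration (sweep %d)", it);
    if (resid < tol) { conv = true; break; }
  }
  if (it > maxit) it = maxit;
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["residual"] = resid, _["converged"] = conv);
}

// Screened-Coulomb (Debye-Hueckel) potential of a set of point charges,
// evaluated at arbitrary points: phi = sum_a C q_a exp(-kappa r)/(eps_s r).
// Used for the grid boundary condition and as the long-range fallback force
// field when an atom leaves the solved box.
// [[Rcpp::export(name = ".dhPotential")]]
NumericVector dhPotential(NumericMatrix pts, NumericMatrix atoms,
                          double kCoulomb, double epsSolvent, double kappa) {
  const int np = pts.nrow(), na = atoms.nrow();
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    double acc = 0.0;
    for (int ia = 0; ia < na; ++ia) {
      const double dx = pts(ip, 0) - atoms(ia, 0);
      const double dy = pts(ip, 1) - atoms(ia, 1);
      const double dz = pts(ip, 2) - atoms(ia, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-6) r = 1e-6;
      acc += kCoulomb * atoms(ia, 3) * std::exp(-kappa * r) / (epsSolvent * r);
    }
    out[ip] = acc;
  }
  return out;
}
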