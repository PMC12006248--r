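#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Red-black SOR for div(sigma grad phi) = 0 on a regular 2-D/3-D grid.
//
// Cells flagged in `fixed` hold Dirichlet data (electrode interiors,
// optionally the outer boundary layer); other boundary faces are zero-flux
// (face conductance of a missing neighbour is zero). `sigma` has length 1
// (homogeneous fast path) or one value per cell (harmonic-mean face
// conductances).
//
// Cells cut by the true electrode surface use a Shortley-Weller stencil:
// `irr` maps each such cell to a row of `theta` / `bval` giving, per
// direction (-x,+x,-y,+y,-z,+z), the fractional distance to the surface
// and the surface potential there. This removes the first-order bias a
// rasterized Dirichlet blob would otherwise give the conductor radius.

struct Stencil {
  const double *phi;
  const double *sg;      // nullptr for homogeneous
  const int *fx;
  const int *irr;        // 0 = regular, else 1-based row in theta/bval
  const double *theta;   // n_irr x 6, column-major
  const double *bval;
  R_xlen_t n_irr;
  int nx, ny, nz;
  R_xlen_t sx, sy, sz;

  inline double hmean(double a, double b) const {
    return (a + b > 0.0) ? 2.0 * a * b / (a + b) : 0.0;
  }

  // Gauss-Seidel target value num/den for free cell c at (i,j,k).
  inline void local(R_xlen_t c, int i, int j, int k,
                    double &num, double &den) const {
    num = 0.0; den = 0.0;
    const double s0 = sg ? sg[c] : 1.0;
    const int row = irr[c];
    const bool have[6] = {i > 0, i < nx - 1, j > 0, j < ny - 1,
                          nz > 1 && k > 0, nz > 1 && k < nz - 1};
    const R_xlen_t step[6] = {-sx, sx, -sy, sy, -sz, sz};
    if (row == 0) {
      for (int d = 0; d < 6; ++d) {
        if (!have[d]) continue;
        R_xlen_t nb = c + step[d];
        double w = sg ? hmean(s0, sg[nb]) : 1.0;
        num += w * phi[nb]; den += w;
      }
    } else {
      const R_xlen_t r = row - 1;
      for (int ax = 0; ax < 3; ++ax) {
        int dm = 2 * ax, dp = 2 * ax + 1;
        if (!have[dm] && !have[dp]) continue;
        double tm = have[dm] ? theta[r + n_irr * dm] : 1.0;
        double tp = have[dp] ? theta[r + n_irr * dp] : 1.0;
        double vm = 0.0, vp = 0.0, wsm = 0.0, wsp = 0.0;
        if (have[dm]) {
          vm = (tm < 1.0) ? bval[r + n_irr * dm] : phi[c + step[dm]];
          double sf = sg ? (tm < 1.0 ? s0 : hmean(s0, sg[c + step[dm]])) : 1.0;
          wsm = sf * 2.0 / (tm * (tm + tp));
        }
        if (have[dp]) {
          vp = (tp < 1.0) ? bval[r + n_irr * dp] : phi[c + step[dp]];
          double sf = sg ? (tp < 1.0 ? s0 : hmean(s0, sg[c + step[dp]])) : 1.0;
          wsp = sf * 2.0 / (tp * (tm + tp));
        }
        num += wsm * vm + wsp * vp;
        den += wsm + wsp;
      }
    }
  }
};

// [[Rcpp::export(name = ".sor_solve")]]
List sor_solve(NumericVector phi0, IntegerVector dims, NumericVector sigma,
               LogicalVector fixed, IntegerVector irr, NumericMatrix theta,
               NumericMatrix bval, double tol, int maxit, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (phi0.size() != n || fixed.size() != n || irr.size() != n)
    stop("grid size mismatch");
  const bool homog = sigma.size() == 1;
  if (!homog && sigma.size() != n)
    stop("sigma must have length 1 or one value per cell");

  std::vector<double> phi(phi0.begin(), phi0.end());
  Stencil st;
  st.phi = phi.data();
  st.sg = homog ? nullptr : REAL(sigma);
  st.fx = LOGICAL(fixed);
  st.irr = INTEGER(irr);
  st.theta = REAL(theta);
  st.bval = REAL(bval);
  st.n_irr = theta.nrow();
  st.nx = nx; st.ny = ny; st.nz = nz;
  st.sx = 1; st.sy = nx; st.sz = (R_xlen_t)nx * ny;

  double vmin = R_PosInf, vmax = R_NegInf;
  for (R_xlen_t c = 0; c < n; ++c)
    if (st.fx[c]) { vmin = std::min(vmin, phi[c]); vmax = std::max(vmax, phi[c]); }
  for (R_xlen_t r = 0; r < st.n_irr; ++r)
    for (int d = 0; d < 6; ++d)
      if (st.theta[r + st.n_irr * d] < 1.0) {
        double v = st.bval[r + st.n_irr * d];
        vmin = std::min(vmin, v); vmax = std::max(vmax, v);
      }
  const double vspan = (vmax > vmin) ? (vmax - vmin) : 1.0;

  double res = R_PosInf;
  int it;
  for (it = 1; it <= maxit; ++it) {
    for (int color = 0; color < 2; ++color) {
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          int i0 = ((j + k + color) & 1);
          R_xlen_t base = (R_xlen_t)j * st.sy + (R_xlen_t)k * st.sz;
          for (int i = i0; i < nx; i += 2) {
            R_xlen_t c = base + i;
            if (st.fx[c]) continue;
            double num, den;
            st.local(c, i, j, k, num, den);
            if (den > 0.0) {
              // plain GS at cut cells keeps the irregular stencil stable
              double w = st.irr[c] ? 1.0 : omega;
              phi[c] += w * (num / den - phi[c]);
            }
          }
        }
    }
    if (it % 25 == 0 || it == maxit) {
      res = 0.0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            R_xlen_t c = (R_xlen_t)i + (R_xlen_t)j * st.sy + (R_xlen_t)k * st.sz;
            if (st.fx[c]) continue;
            double num, den;
            st.local(c, i, j, k, num, den);
            if (den > 0.0) {
              double r = std::fabs(num / den - phi[c]) / vspan;
              if (r > res) res = r;
            }
          }
      if (res <= tol) break;
      Rcpp::checkUserInterrupt();
    }
  }

  return List::create(_["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["residual"] = res,
                      _["iterations"] = std::min(it, maxit),
                      _["converged"] = res <= tol);
}

// Connected-component labelling of a binary 2-D mask with 4- or
// 8-connectivity (flood fill with an explicit stack).
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + nr * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int q = 0; q < connectivity; ++q) {
          int r2 = pr + dr8[q], c2 = pc + dc8[q];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + nr * c2);
          }
        }
      }
    }
  return lab;
}
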