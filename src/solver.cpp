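// Steady incompressible axisymmetric Navier-Stokes, SIMPLE pressure-velocity
// coupling on a colocated body-fitted structured grid (x = axial, r = radial).
//
// Conventions:
//  - Node coordinates Xn, Rn are (nx+1) x (ny+1) matrices in metres,
//    i = axial index, j = radial index; j = 0 lies on the symmetry axis,
//    j = ny on the lumen wall.
//  - All face "areas" and cell "volumes" are per radian of azimuth: the
//    area vector of a wall-plane segment a->b is rbar * (dr, -dx) rotated
//    to point owner -> neighbour, and V = \int\int r dx dr over the cell.
//    The azimuthal 2*pi cancels everywhere it matters.
//  - Boundary conditions: plug inlet (u = u_in, v = 0) at i = 0, no-slip
//    wall at j = ny, symmetry axis at j = 0 (zero-area faces, natural),
//    outlet at i = nx with zero gauge pressure and zero-gradient velocity
//    rescaled each outer iteration for exact global mass conservation.
//  - Convection: first-order upwind implicit everywhere, with a deferred
//    second-order-upwind correction blended in after `first_order_iters`
//    outer iterations; diffusion: over-relaxed decomposition with explicit
//    non-orthogonal correction. Gradients: weighted least squares.
//  - Residuals are L1 imbalance norms normalised by their value at outer
//    iteration 10 (documented package convention).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec2 {
  double x, r;
};

inline double dot(const Vec2& a, const Vec2& b) { return a.x * b.x + a.r * b.r; }

struct Solver {
  int nx, ny, ncell;
  double rho, mu, u_in;

  // geometry
  std::vector<double> cx, cr, vol;        // cell centroid, volume per radian
  // x-faces: id = i*ny + j, i = 0..nx (i=0 inlet, i=nx outlet)
  // y-faces: id = i*(ny+1) + j, j = 0..ny (j=0 axis, j=ny wall)
  std::vector<double> xfAx, xfAr, xfCx, xfCr;   // area vector (+x oriented), centre
  std::vector<double> yfAx, yfAr, yfCx, yfCr;   // area vector (+r oriented), centre
  std::vector<double> xfGdiff, xfW, xfDx, xfDr; // internal-face metrics (d = cN - cP)
  std::vector<double> yfGdiff, yfW, yfDx, yfDr;
  std::vector<double> inGdiff, inDbx, inDbr;    // inlet boundary-face metrics
  std::vector<double> outGdiff, outDbx, outDbr; // outlet
  std::vector<double> wallGdiff, wallDbx, wallDbr; // wall

  // least-squares gradient structures (velocity set incl. inlet+wall Dirichlet
  // faces; pressure set incl. outlet Dirichlet face)
  struct Lsq { double ixx, ixr, irr; };
  std::vector<Lsq> lsqV, lsqP;

  // fields
  std::vector<double> u, v, p, mdotx, mdoty;
  std::vector<double> gux, gur, gvx, gvr, gpx, gpr;
  std::vector<double> Du;  // V / aP_relaxed for Rhie-Chow / correction

  inline int cid(int i, int j) const { return i * ny + j; }
  inline int xf(int i, int j) const { return i * ny + j; }
  inline int yf(int i, int j) const { return i * (ny + 1) + j; }

  void setup(const NumericMatrix& Xn, const NumericMatrix& Rn) {
    ncell = nx * ny;
    cx.assign(ncell, 0.0); cr.assign(ncell, 0.0); vol.assign(ncell, 0.0);
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        // corners counter-clockwise in (x, r)
        double px[4] = {Xn(i, j), Xn(i + 1, j), Xn(i + 1, j + 1), Xn(i, j + 1)};
        double pr[4] = {Rn(i, j), Rn(i + 1, j), Rn(i + 1, j + 1), Rn(i, j + 1)};
        // planar area + centroid, and volume per radian = \int r dA
        double A = 0.0, Cx = 0.0, Cr = 0.0, Vr = 0.0;
        for (int t = 0; t < 2; ++t) {
          int a = 0, b = t + 1, c = t + 2;
          double atri = 0.5 * ((px[b] - px[a]) * (pr[c] - pr[a]) -
                               (px[c] - px[a]) * (pr[b] - pr[a]));
          A += atri;
          Cx += atri * (px[a] + px[b] + px[c]) / 3.0;
          Cr += atri * (pr[a] + pr[b] + pr[c]) / 3.0;
          Vr += atri * (pr[a] + pr[b] + pr[c]) / 3.0;
        }
        int c0 = cid(i, j);
        cx[c0] = Cx / A; cr[c0] = Cr / A; vol[c0] = Vr;
      }
    }
    int nxf = (nx + 1) * ny, nyf = nx * (ny + 1);
    xfAx.assign(nxf, 0); xfAr.assign(nxf, 0); xfCx.assign(nxf, 0); xfCr.assign(nxf, 0);
    yfAx.assign(nyf, 0); yfAr.assign(nyf, 0); yfCx.assign(nyf, 0); yfCr.assign(nyf, 0);
    xfGdiff.assign(nxf, 0); xfW.assign(nxf, 0); xfDx.assign(nxf, 0); xfDr.assign(nxf, 0);
    yfGdiff.assign(nyf, 0); yfW.assign(nyf, 0); yfDx.assign(nyf, 0); yfDr.assign(nyf, 0);
    inGdiff.assign(ny, 0); inDbx.assign(ny, 0); inDbr.assign(ny, 0);
    outGdiff.assign(ny, 0); outDbx.assign(ny, 0); outDbr.assign(ny, 0);
    wallGdiff.assign(nx, 0); wallDbx.assign(nx, 0); wallDbr.assign(nx, 0);

    for (int i = 0; i <= nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        int f = xf(i, j);
        double dx = Xn(i, j + 1) - Xn(i, j), dr = Rn(i, j + 1) - Rn(i, j);
        double rb = 0.5 * (Rn(i, j + 1) + Rn(i, j));
        xfAx[f] = rb * dr;  xfAr[f] = -rb * dx;  // points +x
        xfCx[f] = 0.5 * (Xn(i, j + 1) + Xn(i, j));
        xfCr[f] = 0.5 * (Rn(i, j + 1) + Rn(i, j));
        if (i > 0 && i < nx) {
          int P = cid(i - 1, j), N = cid(i, j);
          double ddx = cx[N] - cx[P], ddr = cr[N] - cr[P];
          double AdotD = xfAx[f] * ddx + xfAr[f] * ddr;
          xfGdiff[f] = (xfAx[f] * xfAx[f] + xfAr[f] * xfAr[f]) / AdotD;
          double dP = std::hypot(xfCx[f] - cx[P], xfCr[f] - cr[P]);
          double dN = std::hypot(xfCx[f] - cx[N], xfCr[f] - cr[N]);
          xfW[f] = dN / (dP + dN);  // weight on owner P
          xfDx[f] = ddx; xfDr[f] = ddr;
        } else if (i == 0) {
          // inlet: outward area = -A; d_b = face centre - cell centre
          int P = cid(0, j);
          double ax = -xfAx[f], ar = -xfAr[f];
          double dbx = xfCx[f] - cx[P], dbr = xfCr[f] - cr[P];
          inGdiff[j] = (ax * ax + ar * ar) / (ax * dbx + ar * dbr);
          inDbx[j] = dbx; inDbr[j] = dbr;
        } else {
          int P = cid(nx - 1, j);
          double ax = xfAx[f], ar = xfAr[f];
          double dbx = xfCx[f] - cx[P], dbr = xfCr[f] - cr[P];
          outGdiff[j] = (ax * ax + ar * ar) / (ax * dbx + ar * dbr);
          outDbx[j] = dbx; outDbr[j] = dbr;
        }
      }
    }
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j <= ny; ++j) {
        int f = yf(i, j);
        double dx = Xn(i + 1, j) - Xn(i, j), dr = Rn(i + 1, j) - Rn(i, j);
        double rb = 0.5 * (Rn(i + 1, j) + Rn(i, j));
        yfAx[f] = -rb * dr;  yfAr[f] = rb * dx;  // points +r
        yfCx[f] = 0.5 * (Xn(i + 1, j) + Xn(i, j));
        yfCr[f] = 0.5 * (Rn(i + 1, j) + Rn(i, j));
        if (j > 0 && j < ny) {
          int P = cid(i, j - 1), N = cid(i, j);
          double ddx = cx[N] - cx[P], ddr = cr[N] - cr[P];
          double AdotD = yfAx[f] * ddx + yfAr[f] * ddr;
          yfGdiff[f] = (yfAx[f] * yfAx[f] + yfAr[f] * yfAr[f]) / AdotD;
          double dP = std::hypot(yfCx[f] - cx[P], yfCr[f] - cr[P]);
          double dN = std::hypot(yfCx[f] - cx[N], yfCr[f] - cr[N]);
          yfW[f] = dN / (dP + dN);
          yfDx[f] = ddx; yfDr[f] = ddr;
        } else if (j == ny) {
          int P = cid(i, ny - 1);
          double ax = yfAx[f], ar = yfAr[f];
          double dbx = yfCx[f] - cx[P], dbr = yfCr[f] - cr[P];
          wallGdiff[i] = (ax * ax + ar * ar) / (ax * dbx + ar * dbr);
          wallDbx[i] = dbx; wallDbr[i] = dbr;
        }
        // j == 0: axis, zero area (Rn = 0), nothing to store
      }
    }

    // least-squares gradient normal matrices (inverse stored)
    lsqV.assign(ncell, Lsq{0, 0, 0});
    lsqP.assign(ncell, Lsq{0, 0, 0});
    auto addpt = [](double sxx[3], double dx, double dr) {
      double w = 1.0 / (dx * dx + dr * dr);
      sxx[0] += w * dx * dx; sxx[1] += w * dx * dr; sxx[2] += w * dr * dr;
    };
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        int c = cid(i, j);
        double sv[3] = {0, 0, 0}, sp[3] = {0, 0, 0};
        if (i > 0)       { double dx = cx[cid(i-1,j)]-cx[c], dr = cr[cid(i-1,j)]-cr[c]; addpt(sv,dx,dr); addpt(sp,dx,dr); }
        if (i < nx - 1)  { double dx = cx[cid(i+1,j)]-cx[c], dr = cr[cid(i+1,j)]-cr[c]; addpt(sv,dx,dr); addpt(sp,dx,dr); }
        if (j > 0)       { double dx = cx[cid(i,j-1)]-cx[c], dr = cr[cid(i,j-1)]-cr[c]; addpt(sv,dx,dr); addpt(sp,dx,dr); }
        if (j < ny - 1)  { double dx = cx[cid(i,j+1)]-cx[c], dr = cr[cid(i,j+1)]-cr[c]; addpt(sv,dx,dr); addpt(sp,dx,dr); }
        if (i == 0)      addpt(sv, inDbx[j], inDbr[j]);          // inlet Dirichlet (velocity)
        if (j == ny - 1) addpt(sv, wallDbx[i], wallDbr[i]);      // wall Dirichlet (velocity)
        if (i == nx - 1) addpt(sp, outDbx[j], outDbr[j]);        // outlet Dirichlet (pressure)
        auto inv = [](double s[3], Lsq& L) {
          double det = s[0] * s[2] - s[1] * s[1];
          L.ixx = s[2] / det; L.ixr = -s[1] / det; L.irr = s[0] / det;
        };
        inv(sv, lsqV[c]); inv(sp, lsqP[c]);
      }
    }
  }

  // weighted LSQ gradient of a cell field; `mode`: 0 = velocity-u, 1 = velocity-v,
  // 2 = pressure (selects boundary set and Dirichlet values)
  void gradient(const std::vector<double>& phi, int mode,
                std::vector<double>& gx, std::vector<double>& gr) {
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        int c = cid(i, j);
        double bx = 0.0, br = 0.0;
        auto acc = [&](double dx, double dr, double dphi) {
          double w = 1.0 / (dx * dx + dr * dr);
          bx += w * dx * dphi; br += w * dr * dphi;
        };
        if (i > 0)      acc(cx[cid(i-1,j)]-cx[c], cr[cid(i-1,j)]-cr[c], phi[cid(i-1,j)]-phi[c]);
        if (i < nx - 1) acc(cx[cid(i+1,j)]-cx[c], cr[cid(i+1,j)]-cr[c], phi[cid(i+1,j)]-phi[c]);
        if (j > 0)      acc(cx[cid(i,j-1)]-cx[c], cr[cid(i,j-1)]-cr[c], phi[cid(i,j-1)]-phi[c]);
        if (j < ny - 1) acc(cx[cid(i,j+1)]-cx[c], cr[cid(i,j+1)]-cr[c], phi[cid(i,j+1)]-phi[c]);
        const Lsq* L;
        if (mode == 2) {
          if (i == nx - 1) acc(outDbx[j], outDbr[j], 0.0 - phi[c]);
          L = &lsqP[c];
        } else {
          double bval = (mode == 0) ? u_in : 0.0;
          if (i == 0)      acc(inDbx[j], inDbr[j], bval - phi[c]);
          if (j == ny - 1) acc(wallDbx[i], wallDbr[i], 0.0 - phi[c]);
          L = &lsqV[c];
        }
        gx[c] = L->ixx * bx + L->ixr * br;
        gr[c] = L->ixr * bx + L->irr * br;
      }
    }
  }

  // Jacobi-preconditioned CG for the pressure-correction equation.
  // Matrix: diag ap, off-diagonals -axf (x internal faces), -ayf (y internal).
  void cgSolve(const std::vector<double>& ap,
               const std::vector<double>& axfc, const std::vector<double>& ayfc,
               const std::vector<double>& rhs, std::vector<double>& sol,
               double reltol, int maxit) {
    std::vector<double> res(ncell), z(ncell), d(ncell), q(ncell);
    std::fill(sol.begin(), sol.end(), 0.0);
    double bnorm = 0.0;
    for (int c = 0; c < ncell; ++c) { res[c] = rhs[c]; bnorm += rhs[c] * rhs[c]; }
    bnorm = std::sqrt(bnorm);
    if (bnorm < 1e-300) return;
    auto matvec = [&](const std::vector<double>& xv, std::vector<double>& yv) {
      for (int i = 0; i < nx; ++i)
        for (int j = 0; j < ny; ++j) {
          int c = cid(i, j);
          double s = ap[c] * xv[c];
          if (i > 0)      s -= axfc[xf(i, j)]     * xv[cid(i - 1, j)];
          if (i < nx - 1) s -= axfc[xf(i + 1, j)] * xv[cid(i + 1, j)];
          if (j > 0)      s -= ayfc[yf(i, j)]     * xv[cid(i, j - 1)];
          if (j < ny - 1) s -= ayfc[yf(i, j + 1)] * xv[cid(i, j + 1)];
          yv[c] = s;
        }
    };
    double rz = 0.0;
    for (int c = 0; c < ncell; ++c) { z[c] = res[c] / ap[c]; d[c] = z[c]; rz += res[c] * z[c]; }
    for (int it = 0; it < maxit; ++it) {
      matvec(d, q);
      double dq = 0.0;
      for (int c = 0; c < ncell; ++c) dq += d[c] * q[c];
      if (dq <= 0.0) break;
      double alpha = rz / dq, rn = 0.0;
      for (int c = 0; c < ncell; ++c) {
        sol[c] += alpha * d[c];
        res[c] -= alpha * q[c];
        rn += res[c] * res[c];
      }
      if (std::sqrt(rn) < reltol * bnorm) break;
      double rznew = 0.0;
      for (int c = 0; c < ncell; ++c) { z[c] = res[c] / ap[c]; rznew += res[c] * z[c]; }
      double beta = rznew / rz; rz = rznew;
      for (int c = 0; c < ncell; ++c) d[c] = z[c] + beta * d[c];
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".simple_solve_cpp")]]
List simple_solve_cpp(NumericMatrix Xn, NumericMatrix Rn,
                      double rho, double mu, double u_in,
                      double tol, int max_iter,
                      double relax_u, double relax_p,
                      int first_order_iters,
                      int gs_sweeps, double cg_reltol, int cg_maxit) {
  Solver S;
  S.nx = Xn.nrow() - 1; S.ny = Xn.ncol() - 1;
  S.rho = rho; S.mu = mu; S.u_in = u_in;
  S.setup(Xn, Rn);
  const int nx = S.nx, ny = S.ny, ncell = S.ncell;

  S.u.assign(ncell, u_in); S.v.assign(ncell, 0.0); S.p.assign(ncell, 0.0);
  S.gux.assign(ncell, 0); S.gur.assign(ncell, 0);
  S.gvx.assign(ncell, 0); S.gvr.assign(ncell, 0);
  S.gpx.assign(ncell, 0); S.gpr.assign(ncell, 0);
  S.Du.assign(ncell, 0.0);
  S.mdotx.assign((nx + 1) * ny, 0.0);
  S.mdoty.assign(nx * (ny + 1), 0.0);

  // fixed inlet mass fluxes (out of cell (0,j): negative)
  std::vector<double> mdotIn(ny);
  double qIn = 0.0;
  for (int j = 0; j < ny; ++j) {
    mdotIn[j] = -rho * u_in * S.xfAx[S.xf(0, j)];  // u_in * outward area (-Ax)
    qIn += -mdotIn[j];
  }
  // initial interior fluxes from the plug profile
  for (int i = 1; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      S.mdotx[S.xf(i, j)] = rho * u_in * S.xfAx[S.xf(i, j)];
  for (int j = 0; j < ny; ++j) S.mdotx[S.xf(nx, j)] = rho * u_in * S.xfAx[S.xf(nx, j)];

  std::vector<double> aP(ncell), aW(ncell), aE(ncell), aS_(ncell), aN(ncell);
  std::vector<double> bu(ncell), bv(ncell), aPu(ncell), aPv(ncell);
  std::vector<double> app(ncell), bp(ncell), pc(ncell);
  std::vector<double> axfc((nx + 1) * ny, 0.0), ayfc(nx * (ny + 1), 0.0);
  std::vector<double> gpcx(ncell), gpcr(ncell);
  std::vector<double> resHist;  // triples (continuity, xmom, rmom)
  double normC = -1, normU = -1, normV = -1;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    double lambda = (iter > first_order_iters) ? 1.0 : 0.0;
    S.gradient(S.u, 0, S.gux, S.gur);
    S.gradient(S.v, 1, S.gvx, S.gvr);
    S.gradient(S.p, 2, S.gpx, S.gpr);

    std::fill(aP.begin(), aP.end(), 0.0);
    std::fill(aW.begin(), aW.end(), 0.0);
    std::fill(aE.begin(), aE.end(), 0.0);
    std::fill(aS_.begin(), aS_.end(), 0.0);
    std::fill(aN.begin(), aN.end(), 0.0);
    std::fill(bu.begin(), bu.end(), 0.0);
    std::fill(bv.begin(), bv.end(), 0.0);

    // --- internal x-faces ---
    for (int i = 1; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        int f = S.xf(i, j), P = S.cid(i - 1, j), N = S.cid(i, j);
        double m = S.mdotx[f], D = mu * S.xfGdiff[f];
        double cP = D + std::max(-m, 0.0);  // coef on phi_N in P's eq (as -cP)
        double cN = D + std::max(m, 0.0);
        aP[P] += D + std::max(m, 0.0);  aE[P] = -cP;
        aP[N] += D + std::max(-m, 0.0); aW[N] = -cN;
        // deferred SOU convection + non-orthogonal diffusion corrections
        double Tx = S.xfAx[f] - S.xfDx[f] * S.xfGdiff[f];
        double Tr = S.xfAr[f] - S.xfDr[f] * S.xfGdiff[f];
        double w = S.xfW[f];
        for (int comp = 0; comp < 2; ++comp) {
          const std::vector<double>& phi = comp ? S.v : S.u;
          const std::vector<double>& gx = comp ? S.gvx : S.gux;
          const std::vector<double>& gr = comp ? S.gvr : S.gur;
          std::vector<double>& b = comp ? bv : bu;
          double corr = 0.0;
          if (lambda > 0.0) {
            int up = (m >= 0.0) ? P : N;
            double phiHo = phi[up] + gx[up] * (S.xfCx[f] - S.cx[up]) +
                           gr[up] * (S.xfCr[f] - S.cr[up]);
            double fluxImpl = std::max(m, 0.0) * phi[P] + std::min(m, 0.0) * phi[N];
            corr += lambda * (fluxImpl - m * phiHo);
          }
          double gbx = w * gx[P] + (1 - w) * gx[N];
          double gbr = w * gr[P] + (1 - w) * gr[N];
          corr += mu * (gbx * Tx + gbr * Tr);
          b[P] += corr; b[N] -= corr;
        }
      }
    }
    // --- internal y-faces ---
    for (int i = 0; i < nx; ++i) {
      for (int j = 1; j < ny; ++j) {
        int f = S.yf(i, j), P = S.cid(i, j - 1), N = S.cid(i, j);
        double m = S.mdoty[f], D = mu * S.yfGdiff[f];
        double cP = D + std::max(-m, 0.0);
        double cN = D + std::max(m, 0.0);
        aP[P] += D + std::max(m, 0.0);  aN[P] = -cP;
        aP[N] += D + std::max(-m, 0.0); aS_[N] = -cN;
        double Tx = S.yfAx[f] - S.yfDx[f] * S.yfGdiff[f];
        double Tr = S.yfAr[f] - S.yfDr[f] * S.yfGdiff[f];
        double w = S.yfW[f];
        for (int comp = 0; comp < 2; ++comp) {
          const std::vector<double>& phi = comp ? S.v : S.u;
          const std::vector<double>& gx = comp ? S.gvx : S.gux;
          const std::vector<double>& gr = comp ? S.gvr : S.gur;
          std::vector<double>& b = comp ? bv : bu;
          double corr = 0.0;
          if (lambda > 0.0) {
            int up = (m >= 0.0) ? P : N;
            double phiHo = phi[up] + gx[up] * (S.yfCx[f] - S.cx[up]) +
                           gr[up] * (S.yfCr[f] - S.cr[up]);
            double fluxImpl = std::max(m, 0.0) * phi[P] + std::min(m, 0.0) * phi[N];
            corr += lambda * (fluxImpl - m * phiHo);
          }
          double gbx = w * gx[P] + (1 - w) * gx[N];
          double gbr = w * gr[P] + (1 - w) * gr[N];
          corr += mu * (gbx * Tx + gbr * Tr);
          b[P] += corr; b[N] -= corr;
        }
      }
    }
    // --- boundary faces ---
    for (int j = 0; j < ny; ++j) {
      // inlet: Dirichlet (u_in, 0); fixed inflow mdotIn[j] (negative)
      int P = S.cid(0, j);
      double m = mdotIn[j], Db = mu * S.inGdiff[j];
      bu[P] += -std::min(m, 0.0) * u_in;            // upwind boundary value
      aP[P] += Db; bu[P] += Db * u_in;              // diffusion to Dirichlet face
      // v: boundary value 0 -> only diagonal
      // non-orthogonal boundary correction
      double ax = -S.xfAx[S.xf(0, j)], ar = -S.xfAr[S.xf(0, j)];
      double Tx = ax - S.inDbx[j] * S.inGdiff[j], Tr = ar - S.inDbr[j] * S.inGdiff[j];
      bu[P] += mu * (S.gux[P] * Tx + S.gur[P] * Tr);
      bv[P] += mu * (S.gvx[P] * Tx + S.gvr[P] * Tr);
      // outlet: zero-gradient velocity, outflow upwinds phi_P
      int Q = S.cid(nx - 1, j);
      double mo = S.mdotx[S.xf(nx, j)];
      aP[Q] += std::max(mo, 0.0);
    }
    for (int i = 0; i < nx; ++i) {
      // wall: no-slip Dirichlet 0
      int P = S.cid(i, ny - 1);
      double Db = mu * S.wallGdiff[i];
      aP[P] += Db;
      double ax = S.yfAx[S.yf(i, ny)], ar = S.yfAr[S.yf(i, ny)];
      double Tx = ax - S.wallDbx[i] * S.wallGdiff[i], Tr = ar - S.wallDbr[i] * S.wallGdiff[i];
      bu[P] += mu * (S.gux[P] * Tx + S.gur[P] * Tr);
      bv[P] += mu * (S.gvx[P] * Tx + S.gvr[P] * Tr);
    }
    // pressure gradient source and axisymmetric v sink
    for (int c = 0; c < ncell; ++c) {
      bu[c] -= S.gpx[c] * S.vol[c];
      bv[c] -= S.gpr[c] * S.vol[c];
      aPu[c] = aP[c];
      aPv[c] = aP[c] + mu * S.vol[c] / (S.cr[c] * S.cr[c]);
    }

    // unrelaxed residuals (L1)
    double resU = 0.0, resV = 0.0;
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        int c = S.cid(i, j);
        double ru = aPu[c] * S.u[c] - bu[c], rv = aPv[c] * S.v[c] - bv[c];
        if (i > 0)      { ru += aW[c]  * S.u[S.cid(i-1,j)]; rv += aW[c]  * S.v[S.cid(i-1,j)]; }
        if (i < nx - 1) { ru += aE[c]  * S.u[S.cid(i+1,j)]; rv += aE[c]  * S.v[S.cid(i+1,j)]; }
        if (j > 0)      { ru += aS_[c] * S.u[S.cid(i,j-1)]; rv += aS_[c] * S.v[S.cid(i,j-1)]; }
        if (j < ny - 1) { ru += aN[c]  * S.u[S.cid(i,j+1)]; rv += aN[c]  * S.v[S.cid(i,j+1)]; }
        resU += std::fabs(ru); resV += std::fabs(rv);
      }

    // implicit under-relaxation + Gauss-Seidel sweeps
    for (int c = 0; c < ncell; ++c) {
      aPu[c] /= relax_u; bu[c] += (1.0 - relax_u) * aPu[c] * S.u[c];
      aPv[c] /= relax_u; bv[c] += (1.0 - relax_u) * aPv[c] * S.v[c];
      S.Du[c] = S.vol[c] / aPu[c];
    }
    for (int sweep = 0; sweep < gs_sweeps; ++sweep) {
      bool fwd = (sweep % 2 == 0);
      for (int ii = 0; ii < nx; ++ii) {
        int i = fwd ? ii : nx - 1 - ii;
        for (int jj = 0; jj < ny; ++jj) {
          int j = fwd ? jj : ny - 1 - jj;
          int c = S.cid(i, j);
          double su = bu[c], sv = bv[c];
          if (i > 0)      { su -= aW[c]  * S.u[S.cid(i-1,j)]; sv -= aW[c]  * S.v[S.cid(i-1,j)]; }
          if (i < nx - 1) { su -= aE[c]  * S.u[S.cid(i+1,j)]; sv -= aE[c]  * S.v[S.cid(i+1,j)]; }
          if (j > 0)      { su -= aS_[c] * S.u[S.cid(i,j-1)]; sv -= aS_[c] * S.v[S.cid(i,j-1)]; }
          if (j < ny - 1) { su -= aN[c]  * S.u[S.cid(i,j+1)]; sv -= aN[c]  * S.v[S.cid(i,j+1)]; }
          S.u[c] = su / aPu[c];
          S.v[c] = sv / aPv[c];
        }
      }
    }

    // --- Rhie-Chow mass fluxes ---
    S.gradient(S.p, 2, S.gpx, S.gpr);
    for (int i = 1; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        int f = S.xf(i, j), P = S.cid(i - 1, j), N = S.cid(i, j);
        double w = S.xfW[f];
        double ub = w * S.u[P] + (1 - w) * S.u[N];
        double vb = w * S.v[P] + (1 - w) * S.v[N];
        double Db = w * S.Du[P] + (1 - w) * S.Du[N];
        double gpdx = (w * S.gpx[P] + (1 - w) * S.gpx[N]) * S.xfDx[f] +
                      (w * S.gpr[P] + (1 - w) * S.gpr[N]) * S.xfDr[f];
        S.mdotx[f] = rho * (ub * S.xfAx[f] + vb * S.xfAr[f] +
                            Db * S.xfGdiff[f] * (S.p[P] - S.p[N] + gpdx));
      }
    for (int i = 0; i < nx; ++i)
      for (int j = 1; j < ny; ++j) {
        int f = S.yf(i, j), P = S.cid(i, j - 1), N = S.cid(i, j);
        double w = S.yfW[f];
        double ub = w * S.u[P] + (1 - w) * S.u[N];
        double vb = w * S.v[P] + (1 - w) * S.v[N];
        double Db = w * S.Du[P] + (1 - w) * S.Du[N];
        double gpdx = (w * S.gpx[P] + (1 - w) * S.gpx[N]) * S.yfDx[f] +
                      (w * S.gpr[P] + (1 - w) * S.gpr[N]) * S.yfDr[f];
        S.mdoty[f] = rho * (ub * S.yfAx[f] + vb * S.yfAr[f] +
                            Db * S.yfGdiff[f] * (S.p[P] - S.p[N] + gpdx));
      }
    // outlet: zero-gradient velocity, rescaled for exact global conservation
    double qOut = 0.0;
    for (int j = 0; j < ny; ++j) {
      int f = S.xf(nx, j), P = S.cid(nx - 1, j);
      double m = rho * (S.u[P] * S.xfAx[f] + S.v[P] * S.xfAr[f]);
      S.mdotx[f] = std::max(m, 0.0);
      qOut += S.mdotx[f];
    }
    double scale = (qOut > 1e-30) ? (qIn / qOut) : 0.0;
    for (int j = 0; j < ny; ++j) S.mdotx[S.xf(nx, j)] *= scale;

    // --- continuity residual and pressure correction ---
    double resC = 0.0;
    std::fill(app.begin(), app.end(), 0.0);
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        int c = S.cid(i, j);
        // net out-flux of mass from the cell
        double out = 0.0;
        out += S.mdotx[S.xf(i + 1, j)];          // east, +x out
        out -= (i == 0) ? -mdotIn[j] : S.mdotx[S.xf(i, j)];  // west in
        out += S.mdoty[S.yf(i, j + 1)];          // north (+r out; wall face mdot 0)
        out -= S.mdoty[S.yf(i, j)];              // south in (axis face 0)
        bp[c] = -out;
        resC += std::fabs(out);
      }
    // wall fluxes are zero by construction (never assigned); axis faces are
    // never assigned either (zero area)
    for (int i = 1; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        int f = S.xf(i, j), P = S.cid(i - 1, j), N = S.cid(i, j);
        double w = S.xfW[f];
        double Db = w * S.Du[P] + (1 - w) * S.Du[N];
        double a = rho * Db * S.xfGdiff[f];
        axfc[f] = a; app[P] += a; app[N] += a;
      }
    for (int i = 0; i < nx; ++i)
      for (int j = 1; j < ny; ++j) {
        int f = S.yf(i, j), P = S.cid(i, j - 1), N = S.cid(i, j);
        double w = S.yfW[f];
        double Db = w * S.Du[P] + (1 - w) * S.Du[N];
        double a = rho * Db * S.yfGdiff[f];
        ayfc[f] = a; app[P] += a; app[N] += a;
      }
    for (int j = 0; j < ny; ++j) {  // outlet p' = 0 Dirichlet
      int P = S.cid(nx - 1, j);
      app[P] += rho * S.Du[P] * S.outGdiff[j];
    }
    S.cgSolve(app, axfc, ayfc, bp, pc, cg_reltol, cg_maxit);

    // corrections
    S.gradient(pc, 2, gpcx, gpcr);
    for (int c = 0; c < ncell; ++c) {
      S.p[c] += relax_p * pc[c];
      S.u[c] -= S.Du[c] * gpcx[c];
      S.v[c] -= S.Du[c] * gpcr[c];
    }
    for (int i = 1; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        int f = S.xf(i, j);
        S.mdotx[f] += axfc[f] * (pc[S.cid(i - 1, j)] - pc[S.cid(i, j)]);
      }
    for (int i = 0; i < nx; ++i)
      for (int j = 1; j < ny; ++j) {
        int f = S.yf(i, j);
        S.mdoty[f] += ayfc[f] * (pc[S.cid(i, j - 1)] - pc[S.cid(i, j)]);
      }
    for (int j = 0; j < ny; ++j) {
      int f = S.xf(nx, j), P = S.cid(nx - 1, j);
      S.mdotx[f] += rho * S.Du[P] * S.outGdiff[j] * pc[P];
    }

    resHist.push_back(resC); resHist.push_back(resU); resHist.push_back(resV);
    if (iter == 10) {
      normC = std::max(resC, 1e-300);
      normU = std::max(resU, 1e-300);
      normV = std::max(resV, 1e-300);
    }
    if (iter > std::max(first_order_iters + 10, 60) && normC > 0) {
      if (resC / normC < tol && resU / normU < tol && resV / normV < tol) {
        converged = true;
        break;
      }
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }
  int niter = converged ? iter : max_iter;
  if (normC < 0) {  // fewer than 10 iterations recorded (tiny runs)
    normC = std::max(resHist[0], 1e-300);
    normU = std::max(resHist[1], 1e-300);
    normV = std::max(resHist[2], 1e-300);
  }

  // outputs
  NumericMatrix Um(nx, ny), Vm(nx, ny), Pm(nx, ny), Cxm(nx, ny), Crm(nx, ny), Volm(nx, ny);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      int c = S.cid(i, j);
      Um(i, j) = S.u[c]; Vm(i, j) = S.v[c]; Pm(i, j) = S.p[c];
      Cxm(i, j) = S.cx[c]; Crm(i, j) = S.cr[c]; Volm(i, j) = S.vol[c];
    }
  // volumetric flux (m^3/s per radian * rho ... report full m^3/s through 2*pi)
  NumericVector stationFlux(nx + 1);
  for (int i = 0; i <= nx; ++i) {
    double q = 0.0;
    for (int j = 0; j < ny; ++j)
      q += (i == 0) ? -mdotIn[j] : S.mdotx[S.xf(i, j)];
    stationFlux[i] = 2.0 * M_PI * q / rho;
  }
  int nrec = (int)resHist.size() / 3;
  NumericMatrix RH(nrec, 3);
  for (int k = 0; k < nrec; ++k) {
    RH(k, 0) = resHist[3 * k]     / normC;
    RH(k, 1) = resHist[3 * k + 1] / normU;
    RH(k, 2) = resHist[3 * k + 2] / normV;
  }
  return List::create(
    _["u"] = Um, _["v"] = Vm, _["p"] = Pm,
    _["cell_x"] = Cxm, _["cell_r"] = Crm, _["cell_volume"] = Volm,
    _["station_flux"] = stationFlux,
    _["residual_history"] = RH,
    _["iterations"] = niter,
    _["converged"] = converged);
}
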