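// Compiled core of the thrombosis simulator: a staggered-grid (MAC)
// incompressible flow solver with the thrombus Brinkman-type resistance
// sink, scalar shear fields, conservative upwind finite-volume transport of
// the mobile species, and the fused reaction/deposition/embolization update
// of the coupled driver. Planar x-y and axisymmetric z-r grids share one
// metric (radius weights are 1 in planar mode).
//
// Discretization notes:
//  * momentum: first-order upwind convection, central diffusion, implicit
//    Patankar treatment of the C2*f(phi) sink, SIMPLE pressure correction
//    with under-relaxation; dt <= 0 solves to steady state.
//  * transport: explicit first-order upwind + central diffusion, strictly
//    conservative (face-flux form); deposited species never advect.
//  * reactions: donor-bounded (Patankar-type) transfer amounts computed
//    from start-of-step values, so platelet count is conserved exactly and
//    states stay non-negative for any dt.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const int NSP = 10;
// species order used throughout
enum { iRP = 0, iAP, iAPR, iAPS, iPT, iTB, iAT, iRPD, iAPD, iAPSd };

struct GridC {
  int nx, ny, axisym;
  std::vector<double> xf, yf, xc, yc, dx, dy, rc, rf;
  std::vector<int> solid;                 // nx*ny
  int wbc, ebc, sbc, nbc;                 // 0 wall,1 inlet,2 pressure,3 symmetry,4 axis
  double w_p, e_p;                        // pressure values
  std::vector<double> w_uprof;            // inlet profile (ny)
  int w_conc_dirichlet;                   // inlet concentration on west side
  // per-cell wall-surface precomputation (reactive walls)
  std::vector<double> adh_rpdb, adh_apdb; // S=1 adhesion rates, 1/s
  std::vector<double> wall_area;          // wall face area per cell
  std::vector<double> tau_char;           // embolization char. stress, dyne/cm2
  std::vector<double> port_kex;           // ADP port exchange rate, 1/s
  double port_conc;

  inline int id(int i, int j) const { return i + nx * j; }
  inline int idu(int i, int j) const { return i + (nx + 1) * j; }
  inline int idv(int i, int j) const { return i + nx * j; }
  inline bool sol(int i, int j) const {
    if (i < 0 || i >= nx || j < 0 || j >= ny) return false;
    return solid[id(i, j)] != 0;
  }
};

static GridC load_grid(const List& g) {
  GridC G;
  G.nx = as<int>(g["nx"]); G.ny = as<int>(g["ny"]);
  G.axisym = as<int>(g["axisym"]);
  G.xf = as<std::vector<double>>(g["xf"]);
  G.yf = as<std::vector<double>>(g["yf"]);
  G.xc = as<std::vector<double>>(g["xc"]);
  G.yc = as<std::vector<double>>(g["yc"]);
  G.dx = as<std::vector<double>>(g["dx"]);
  G.dy = as<std::vector<double>>(g["dy"]);
  G.rc = as<std::vector<double>>(g["rc"]);
  G.rf = as<std::vector<double>>(g["rf"]);
  G.solid = as<std::vector<int>>(g["solid"]);
  G.wbc = as<int>(g["wbc"]); G.ebc = as<int>(g["ebc"]);
  G.sbc = as<int>(g["sbc"]); G.nbc = as<int>(g["nbc"]);
  G.w_p = as<double>(g["w_p"]); G.e_p = as<double>(g["e_p"]);
  G.w_uprof = as<std::vector<double>>(g["w_uprof"]);
  G.w_conc_dirichlet = as<int>(g["w_conc_dirichlet"]);
  G.adh_rpdb = as<std::vector<double>>(g["adh_rpdb"]);
  G.adh_apdb = as<std::vector<double>>(g["adh_apdb"]);
  G.wall_area = as<std::vector<double>>(g["wall_area"]);
  G.tau_char = as<std::vector<double>>(g["tau_char"]);
  G.port_kex = as<std::vector<double>>(g["port_kex"]);
  G.port_conc = as<double>(g["port_conc"]);
  return G;
}

static inline double hindrance_f(double phi) {
  if (phi < 0) phi = 0;
  if (phi > 1) phi = 1;
  return phi * (1.0 + 6.5 * phi);
}

// ---------------------------------------------------------------------------
// Flow solver: transient/steady SIMPLE on the staggered grid.
// ---------------------------------------------------------------------------
struct FlowOpts {
  double dt;        // <= 0: steady
  int max_outer;
  double tol;       // normalized mass residual target
  double du_tol;    // normalized momentum-update target
  double alpha_u, alpha_p;
  int p_sweeps;
  int m_sweeps;     // momentum Gauss-Seidel sweeps per outer iteration
};

struct FlowResult { int iters; double res; bool converged; double Qin; };

static FlowResult flow_solve(const GridC& G, const std::vector<double>& phi,
                             double C2, double mu, double rho0,
                             std::vector<double>& u, std::vector<double>& v,
                             std::vector<double>& p, const FlowOpts& opt) {
  const int nx = G.nx, ny = G.ny;
  const int nu = (nx + 1) * ny, nv = nx * (ny + 1), nc = nx * ny;
  std::vector<double> apu(nu, 1.0), apv(nv, 1.0);
  std::vector<double> u0 = u, v0 = v;        // transient old values
  std::vector<double> pc(nc, 0.0);
  std::vector<char> ufix(nu, 0), vfix(nv, 0);

  // mark fixed-velocity faces (walls, inlets, solid-adjacent, symmetry)
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i <= nx; ++i) {
      bool fix = false; double val = 0.0;
      bool csolW = G.sol(i - 1, j), csolE = G.sol(i, j);
      if (i == 0) {
        if (G.wbc == 1) { fix = true; val = G.w_uprof[j]; }
        else if (G.wbc == 0) { fix = true; }
        if (csolE) { fix = true; val = 0.0; }
      } else if (i == nx) {
        if (G.ebc == 0) fix = true;
        if (csolW) { fix = true; val = 0.0; }
      } else if (csolW || csolE) { fix = true; }
      if (fix) { ufix[G.idu(i, j)] = 1; u[G.idu(i, j)] = val; }
    }
  }
  for (int j = 0; j <= ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      bool fix = false;
      bool csolS = G.sol(i, j - 1), csolN = G.sol(i, j);
      if (j == 0) fix = true;                       // wall or axis: v = 0
      else if (j == ny) fix = true;                 // wall or symmetry: v = 0
      else if (csolS || csolN) fix = true;
      if (fix) { vfix[G.idv(i, j)] = 1; v[G.idv(i, j)] = 0.0; }
    }
  }

  double Qscale = 0.0;   // inlet volumetric flux scale for normalization
  {
    for (int j = 0; j < ny; ++j) {
      double A = G.dy[j] * G.rc[j];
      double uin = (G.wbc == 1) ? G.w_uprof[j] : 0.0;
      Qscale += std::fabs(uin) * A;
    }
    if (Qscale <= 0) {
      // pressure-driven: scale from an unobstructed Poiseuille estimate
      double H = G.yf[ny] - G.yf[0], L = G.xf[nx] - G.xf[0];
      double dP = std::fabs(G.w_p - G.e_p);
      double Um = dP * H * H / (8.0 * mu * std::max(L, 1e-12));
      for (int j = 0; j < ny; ++j) Qscale += Um * G.dy[j] * G.rc[j];
    }
    if (Qscale <= 0) Qscale = 1e-12;
  }

  const bool transient = opt.dt > 0;
  double Uref = 0.0;   // velocity scale for the momentum-update criterion
  {
    double Atot = 0.0;
    for (int j = 0; j < ny; ++j) Atot += G.dy[j] * G.rc[j];
    Uref = Qscale / std::max(Atot, 1e-30);
    if (Uref <= 0) Uref = 1e-12;
  }
  double res = 1e30, dumax = 1e30; int it = 0;
  for (it = 0; it < opt.max_outer; ++it) {
    dumax = 0.0;
    for (int ms = 0; ms < opt.m_sweeps; ++ms) {
    // ---- u momentum (x direction) -------------------------------------
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i <= nx; ++i) {
        int k = G.idu(i, j);
        if (ufix[k]) { apu[k] = 1e300; continue; }
        double phiW = (i > 0) ? phi[G.id(i - 1, j)] : phi[G.id(0, j)];
        double phiE = (i < nx) ? phi[G.id(i, j)] : phi[G.id(nx - 1, j)];
        double phif = 0.5 * (phiW + phiE);
        double rho = rho0 * std::max(1.0 - phif, 0.05);
        double xw = (i > 0) ? G.xc[i - 1] : G.xf[0];
        double xe = (i < nx) ? G.xc[i] : G.xf[nx];
        double dxu = std::max(xe - xw, 1e-30);
        double A = G.dy[j] * G.rc[j];
        double Vol = dxu * G.dy[j] * G.rc[j];
        double aE = 0, aW = 0, aN = 0, aS = 0, b = 0, aP = 0;
        double uE = 0, uW = 0, uN = 0, uS = 0;
        // east/west neighbours (normal direction)
        if (i < nx) {
          double De = mu * A / G.dx[i];
          double Fe = rho * A * 0.5 * (u[k] + u[G.idu(i + 1, j)]);
          aE = De + std::max(-Fe, 0.0); aP += De + std::max(Fe, 0.0);
          uE = u[G.idu(i + 1, j)];
        }
        if (i > 0) {
          double Dw = mu * A / G.dx[i - 1];
          double Fw = rho * A * 0.5 * (u[G.idu(i - 1, j)] + u[k]);
          aW = Dw + std::max(Fw, 0.0); aP += Dw + std::max(-Fw, 0.0);
          uW = u[G.idu(i - 1, j)];
        }
        // north link (tangential)
        {
          bool wallN;
          double An = dxu * G.rf[j + 1];
          if (j == ny - 1) wallN = (G.nbc == 0);
          else wallN = (G.sol(i - 1, j + 1) || G.sol(i, j + 1));
          if (j < ny - 1 && !wallN) {
            double dyn = G.yc[j + 1] - G.yc[j];
            double Dn = mu * An / dyn;
            double vv = 0.5 * (((i > 0) ? v[G.idv(i - 1, j + 1)] : v[G.idv(0, j + 1)]) +
                               ((i < nx) ? v[G.idv(i, j + 1)] : v[G.idv(nx - 1, j + 1)]));
            double Fn = rho * An * vv;
            aN = Dn + std::max(-Fn, 0.0); aP += Dn + std::max(Fn, 0.0);
            uN = u[G.idu(i, j + 1)];
          } else if (wallN) {
            double Dn = mu * An / (G.yf[j + 1] - G.yc[j]);
            aP += Dn;   // link to zero wall velocity
          }                // symmetry: zero shear, no link
        }
        // south link
        {
          bool wallS;
          double As = dxu * G.rf[j];
          if (j == 0) wallS = (G.sbc == 0);
          else wallS = (G.sol(i - 1, j - 1) || G.sol(i, j - 1));
          if (j > 0 && !wallS) {
            double dys = G.yc[j] - G.yc[j - 1];
            double Ds = mu * As / dys;
            double vv = 0.5 * (((i > 0) ? v[G.idv(i - 1, j)] : v[G.idv(0, j)]) +
                               ((i < nx) ? v[G.idv(i, j)] : v[G.idv(nx - 1, j)]));
            double Fs = rho * As * vv;
            aS = Ds + std::max(Fs, 0.0); aP += Ds + std::max(-Fs, 0.0);
            uS = u[G.idu(i, j - 1)];
          } else if (wallS) {
            double Ds = mu * As / (G.yc[j] - G.yf[j]);
            aP += Ds;
          }
        }
        aP += C2 * hindrance_f(phif) * Vol;
        if (transient) { aP += rho * Vol / opt.dt; b += rho * Vol / opt.dt * u0[k]; }
        double pW = (i > 0) ? p[G.id(i - 1, j)] : G.w_p;
        double pE = (i < nx) ? p[G.id(i, j)] : G.e_p;
        b += (pW - pE) * A;
        if (aP <= 0) aP = 1e-300;
        apu[k] = aP;
        double unew = (aE * uE + aW * uW + aN * uN + aS * uS + b) / aP;
        double duk = opt.alpha_u * (unew - u[k]);
        u[k] += duk;
        dumax = std::max(dumax, std::fabs(duk));
      }
    }
    // ---- v momentum (y direction) -------------------------------------
    for (int j = 0; j <= ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int k = G.idv(i, j);
        if (vfix[k]) { apv[k] = 1e300; continue; }
        double phiS = phi[G.id(i, j - 1)], phiN = phi[G.id(i, j)];
        double phif = 0.5 * (phiS + phiN);
        double rho = rho0 * std::max(1.0 - phif, 0.05);
        double dyv = G.yc[j] - G.yc[j - 1];
        double A = G.dx[i] * G.rf[j];
        double Vol = G.dx[i] * dyv * G.rf[j];
        double aE = 0, aW = 0, aN = 0, aS = 0, b = 0, aP = 0;
        double vE = 0, vW = 0, vN = 0, vS = 0;
        // north/south (normal)
        {
          double An = G.dx[i] * G.rc[j];
          double Dn = mu * An / G.dy[j];
          double Fn = rho * An * 0.5 * (v[k] + v[G.idv(i, j + 1)]);
          aN = Dn + std::max(-Fn, 0.0); aP += Dn + std::max(Fn, 0.0);
          vN = v[G.idv(i, j + 1)];
          double As = G.dx[i] * G.rc[j - 1];
          double Ds = mu * As / G.dy[j - 1];
          double Fs = rho * As * 0.5 * (v[G.idv(i, j - 1)] + v[k]);
          aS = Ds + std::max(Fs, 0.0); aP += Ds + std::max(-Fs, 0.0);
          vS = v[G.idv(i, j - 1)];
        }
        // east link (tangential)
        {
          bool wallE;
          double Ae = dyv * G.rf[j];
          if (i == nx - 1) wallE = (G.ebc == 0);
          else wallE = (G.sol(i + 1, j - 1) || G.sol(i + 1, j));
          if (i < nx - 1 && !wallE) {
            double dxe = G.xc[i + 1] - G.xc[i];
            double De = mu * Ae / dxe;
            double uu = 0.5 * (u[G.idu(i + 1, j - 1)] + u[G.idu(i + 1, j)]);
            double Fe = rho * Ae * uu;
            aE = De + std::max(-Fe, 0.0); aP += De + std::max(Fe, 0.0);
            vE = v[G.idv(i + 1, j)];
          } else if (wallE) {
            double De = mu * Ae / (G.xf[i + 1] - G.xc[i]);
            aP += De;
          }
        }
        // west link
        {
          bool wallW;
          double Aw = dyv * G.rf[j];
          if (i == 0) wallW = (G.wbc == 0);
          else wallW = (G.sol(i - 1, j - 1) || G.sol(i - 1, j));
          if (i > 0 && !wallW) {
            double dxw = G.xc[i] - G.xc[i - 1];
            double Dw = mu * Aw / dxw;
            double uu = 0.5 * (u[G.idu(i, j - 1)] + u[G.idu(i, j)]);
            double Fw = rho * Aw * uu;
            aW = Dw + std::max(Fw, 0.0); aP += Dw + std::max(-Fw, 0.0);
            vW = v[G.idv(i - 1, j)];
          } else if (wallW) {
            double Dw = mu * Aw / (G.xc[i] - G.xf[i]);
            aP += Dw;
          }
        }
        if (G.axisym && G.rf[j] > 0) aP += mu * Vol / (G.rf[j] * G.rf[j]);
        aP += C2 * hindrance_f(phif) * Vol;
        if (transient) { aP += rho * Vol / opt.dt; b += rho * Vol / opt.dt * v0[k]; }
        b += (p[G.id(i, j - 1)] - p[G.id(i, j)]) * A;
        if (aP <= 0) aP = 1e-300;
        apv[k] = aP;
        double vnew = (aE * vE + aW * vW + aN * vN + aS * vS + b) / aP;
        double dvk = opt.alpha_u * (vnew - v[k]);
        v[k] += dvk;
        dumax = std::max(dumax, std::fabs(dvk));
      }
    }
    }  // momentum sweeps
    // ---- pressure correction ------------------------------------------
    std::fill(pc.begin(), pc.end(), 0.0);
    // assemble diagonal and rhs once; neighbours via d-coefficients
    std::vector<double> de(nu, 0.0), dn(nv, 0.0);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int k = G.idu(i, j);
        if (!ufix[k]) de[k] = (G.dy[j] * G.rc[j]) / apu[k];
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int k = G.idv(i, j);
        if (!vfix[k]) dn[k] = (G.dx[i] * G.rf[j]) / apv[k];
      }
    double massres = 0.0;
    std::vector<double> rhs(nc, 0.0), diag(nc, 0.0);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int c = G.id(i, j);
        if (G.solid[c]) { diag[c] = 1.0; rhs[c] = 0.0; continue; }
        double Ae = G.dy[j] * G.rc[j], An_ = G.dx[i] * G.rf[j + 1],
               As_ = G.dx[i] * G.rf[j];
        double div = u[G.idu(i + 1, j)] * Ae - u[G.idu(i, j)] * Ae +
                     v[G.idv(i, j + 1)] * An_ - v[G.idv(i, j)] * As_;
        rhs[c] = -div;
        massres += std::fabs(div);
        double dsum = 0.0;
        dsum += de[G.idu(i, j)] * Ae;          // west face (incl. pressure bc)
        dsum += de[G.idu(i + 1, j)] * Ae;      // east face
        dsum += dn[G.idv(i, j)] * As_;
        dsum += dn[G.idv(i, j + 1)] * An_;
        diag[c] = std::max(dsum, 1e-300);
      }
    }
    res = massres / Qscale;
    if (res < opt.tol && dumax / Uref < opt.du_tol && it > 0) break;
    for (int sweep = 0; sweep < opt.p_sweeps; ++sweep) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int c = G.id(i, j);
          if (G.solid[c]) continue;
          double Ae = G.dy[j] * G.rc[j], An_ = G.dx[i] * G.rf[j + 1],
                 As_ = G.dx[i] * G.rf[j];
          double off = 0.0;
          if (i > 0 && !G.solid[G.id(i - 1, j)])
            off += de[G.idu(i, j)] * Ae * pc[G.id(i - 1, j)];
          if (i < nx - 1 && !G.solid[G.id(i + 1, j)])
            off += de[G.idu(i + 1, j)] * Ae * pc[G.id(i + 1, j)];
          if (j > 0 && !G.solid[G.id(i, j - 1)])
            off += dn[G.idv(i, j)] * As_ * pc[G.id(i, j - 1)];
          if (j < ny - 1 && !G.solid[G.id(i, j + 1)])
            off += dn[G.idv(i, j + 1)] * An_ * pc[G.id(i, j + 1)];
          double pnew = (rhs[c] + off) / diag[c];
          pc[c] += 1.6 * (pnew - pc[c]);      // SOR
        }
      }
    }
    // ---- correct -------------------------------------------------------
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int k = G.idu(i, j);
        if (ufix[k]) continue;
        double pcw = (i > 0) ? ((G.sol(i - 1, j)) ? 0.0 : pc[G.id(i - 1, j)]) : 0.0;
        double pce = (i < nx) ? ((G.sol(i, j)) ? 0.0 : pc[G.id(i, j)]) : 0.0;
        u[k] += de[k] * (pcw - pce);
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int k = G.idv(i, j);
        if (vfix[k]) continue;
        double pcs = (j > 0) ? pc[G.id(i, j - 1)] : 0.0;
        double pcn = (j < ny) ? pc[G.id(i, j)] : 0.0;
        v[k] += dn[k] * (pcs - pcn);
      }
    for (int c = 0; c < nc; ++c)
      if (!G.solid[c]) p[c] += opt.alpha_p * pc[c];
  }
  double Qin = 0.0;
  for (int j = 0; j < ny; ++j) Qin += u[G.idu(0, j)] * G.dy[j] * G.rc[j];
  FlowResult r; r.iters = it; r.res = res; r.converged = res < opt.tol;
  r.Qin = Qin;
  return r;
}

// ---------------------------------------------------------------------------
// Shear-rate magnitude sqrt(2 D:D) at cell centres, one-sided at walls.
// ---------------------------------------------------------------------------
static void compute_shear(const GridC& G, const std::vector<double>& u,
                          const std::vector<double>& v,
                          std::vector<double>& gam) {
  const int nx = G.nx, ny = G.ny;
  std::vector<double> ucc(nx * ny), vcc(nx * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      ucc[G.id(i, j)] = 0.5 * (u[G.idu(i, j)] + u[G.idu(i + 1, j)]);
      vcc[G.id(i, j)] = 0.5 * (v[G.idv(i, j)] + v[G.idv(i, j + 1)]);
    }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int c = G.id(i, j);
      if (G.solid[c]) { gam[c] = 0.0; continue; }
      double dudx = (u[G.idu(i + 1, j)] - u[G.idu(i, j)]) / G.dx[i];
      double dvdy = (v[G.idv(i, j + 1)] - v[G.idv(i, j)]) / G.dy[j];
      // du/dy with wall awareness
      double dudy;
      bool wallN = (j == ny - 1) ? (G.nbc == 0) : G.sol(i, j + 1);
      bool wallS = (j == 0) ? (G.sbc == 0) : G.sol(i, j - 1);
      double yN = (j < ny - 1 && !wallN) ? G.yc[j + 1] : G.yf[j + 1];
      double uN = (j < ny - 1 && !wallN) ? ucc[G.id(i, j + 1)] : (wallN ? 0.0 : ucc[c]);
      if (j == ny - 1 && G.nbc != 0) { yN = G.yc[j]; uN = ucc[c]; }
      double yS = (j > 0 && !wallS) ? G.yc[j - 1] : G.yf[j];
      double uS = (j > 0 && !wallS) ? ucc[G.id(i, j - 1)] : (wallS ? 0.0 : ucc[c]);
      if (j == 0 && (G.sbc == 4 || G.sbc == 3)) { yS = G.yc[j]; uS = ucc[c]; }
      dudy = (yN - yS > 0) ? (uN - uS) / (yN - yS) : 0.0;
      // dv/dx with wall awareness
      double dvdx;
      bool wallE = (i == nx - 1) ? (G.ebc == 0) : G.sol(i + 1, j);
      bool wallW = (i == 0) ? (G.wbc == 0) : G.sol(i - 1, j);
      double xE = (i < nx - 1 && !wallE) ? G.xc[i + 1] : G.xf[i + 1];
      double vE = (i < nx - 1 && !wallE) ? vcc[G.id(i + 1, j)] : (wallE ? 0.0 : vcc[c]);
      if (i == nx - 1 && G.ebc != 0) { xE = G.xc[i]; vE = vcc[c]; }
      double xW = (i > 0 && !wallW) ? G.xc[i - 1] : G.xf[i];
      double vW = (i > 0 && !wallW) ? vcc[G.id(i - 1, j)] : (wallW ? 0.0 : vcc[c]);
      if (i == 0 && G.wbc != 0) { xW = G.xc[i]; vW = vcc[c]; }
      dvdx = (xE - xW > 0) ? (vE - vW) / (xE - xW) : 0.0;
      double Dtt = 0.0;
      if (G.axisym && G.rc[j] > 0) Dtt = vcc[c] / G.rc[j];
      double Dxy = 0.5 * (dudy + dvdx);
      gam[c] = std::sqrt(2.0 * (dudx * dudx + dvdy * dvdy + Dtt * Dtt) +
                         4.0 * Dxy * Dxy);
    }
  }
}

// ---------------------------------------------------------------------------
// One conservative explicit transport step of a single mobile species.
// Dcell: per-cell diffusivity. cin: inlet value (west). Accumulates flux
// divergence into C (in place).
// ---------------------------------------------------------------------------
static void transport_species(const GridC& G, std::vector<double>& C,
                              const std::vector<double>& Fx,
                              const std::vector<double>& Fy,
                              const std::vector<double>& Dcell,
                              double dt, double cin) {
  const int nx = G.nx, ny = G.ny;
  static thread_local std::vector<double> dC;
  dC.assign(nx * ny, 0.0);
  // x faces
  for (int j = 0; j < ny; ++j) {
    double A = G.dy[j] * G.rc[j];
    for (int i = 0; i <= nx; ++i) {
      int kW = (i > 0) ? G.id(i - 1, j) : -1;
      int kE = (i < nx) ? G.id(i, j) : -1;
      bool solW = (i > 0) ? (G.solid[kW] != 0) : false;
      bool solE = (i < nx) ? (G.solid[kE] != 0) : false;
      double flux = 0.0;
      double F = Fx[G.idu(i, j)];
      if (i == 0) {
        if (solE || G.wbc == 0) continue;
        double cb = (F >= 0) ? cin : C[kE];
        flux = F * cb;
        if (G.w_conc_dirichlet && G.wbc != 0)
          flux += Dcell[kE] * A * (cin - C[kE]) / (0.5 * G.dx[0]);
      } else if (i == nx) {
        if (solW || G.ebc == 0) continue;
        double cb = (F >= 0) ? C[kW] : 0.0; // outflow: zero-gradient
        flux = F * cb;                      // inflow at outlet carries 0
      } else {
        if (solW || solE) continue;         // internal wall: no flux
        double cup = (F >= 0) ? C[kW] : C[kE];
        double Df = 0.5 * (Dcell[kW] + Dcell[kE]);
        flux = F * cup - Df * A * (C[kE] - C[kW]) / (G.xc[i] - G.xc[i - 1]);
      }
      if (kW >= 0 && !solW) dC[kW] -= flux;
      if (kE >= 0 && !solE) dC[kE] += flux;
    }
  }
  // y faces (south/north outer boundaries carry no species flux: wall,
  // axis or symmetry in all supported scenarios)
  for (int j = 1; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int kS = G.id(i, j - 1), kN = G.id(i, j);
      if (G.solid[kS] || G.solid[kN]) continue;
      double A = G.dx[i] * G.rf[j];
      double F = Fy[G.idv(i, j)];
      double cup = (F >= 0) ? C[kS] : C[kN];
      double Df = 0.5 * (Dcell[kS] + Dcell[kN]);
      double flux = F * cup - Df * A * (C[kN] - C[kS]) / (G.yc[j] - G.yc[j - 1]);
      dC[kS] -= flux;
      dC[kN] += flux;
    }
  }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = G.id(i, j);
      if (G.solid[c]) continue;
      double V = G.dx[i] * G.dy[j] * G.rc[j];
      C[c] += dt * dC[c] / V;
    }
}

// rate laws (shared with the R reference implementation; cross-checked in
// the test suite)
struct Kin {
  double t_ct, t_act, cap;
  double wADP, wTx, wTB, acADP, acTx, acTB;
  double k_ra, k_aa, tau_emb;
  double lambda, theta, k1ADP, k1Tx, s_pj;
  double eps, phi_at, phi_rt, k1T, H, alpha, K_AT, K_T;
  double PLT_s_max, Dia, PLT_max, f_stb, C2, mu, rho0;
  double D_plt_base, D_plt_slope, D_apr, D_aps, D_PT, D_TB, D_AT;
  double phi_prop;
};

static Kin load_kin(const List& pl) {
  Kin k;
  k.t_ct = as<double>(pl["t_ct"]); k.t_act = as<double>(pl["t_act"]);
  k.cap = std::log(100.0) / k.t_act;
  NumericVector w = pl["w"], ac = pl["a_crit"], k1 = pl["k1"], D = pl["D"];
  k.wADP = w[0]; k.wTx = w[1]; k.wTB = w[2];
  k.acADP = ac[0]; k.acTx = ac[1]; k.acTB = ac[2];
  k.k_ra = as<double>(pl["k_ra"]); k.k_aa = as<double>(pl["k_aa"]);
  k.tau_emb = as<double>(pl["tau_emb"]);
  k.lambda = as<double>(pl["lambda_j"]); k.theta = as<double>(pl["theta"]);
  k.k1ADP = k1[0]; k.k1Tx = k1[1];
  k.s_pj = as<double>(pl["s_pj"]);
  k.eps = as<double>(pl["eps"]);
  k.phi_at = as<double>(pl["phi_at"]); k.phi_rt = as<double>(pl["phi_rt"]);
  k.k1T = as<double>(pl["k1_T"]); k.H = as<double>(pl["H"]);
  k.alpha = as<double>(pl["alpha"]);
  k.K_AT = as<double>(pl["K_AT"]); k.K_T = as<double>(pl["K_T"]);
  k.PLT_s_max = as<double>(pl["PLT_s_max"]); k.Dia = as<double>(pl["Dia_PLT"]);
  k.PLT_max = as<double>(pl["PLT_max"]); k.f_stb = as<double>(pl["f_stb"]);
  k.C2 = as<double>(pl["C2"]); k.mu = as<double>(pl["mu_f"]);
  k.rho0 = as<double>(pl["rho_f0"]);
  k.D_plt_base = as<double>(pl["D_plt_base"]);
  k.D_plt_slope = as<double>(pl["D_plt_slope"]);
  k.D_apr = D[0]; k.D_aps = D[1]; k.D_PT = D[2]; k.D_TB = D[3]; k.D_AT = D[4];
  k.phi_prop = as<double>(pl["phi_prop"]);
  return k;
}

static inline double k_apa_of(double Om, const Kin& K) {
  if (Om < 1.0) return 0.0;
  double k = Om / K.t_ct;
  return (k > K.cap) ? K.cap : k;
}
static inline double k_spa_of(double tau_dyne, const Kin& K) {
  double k = std::pow(tau_dyne, 2.3) / 4.0e6;
  return (k > K.cap) ? K.cap : k;
}
static inline double f_emb_of(double tau_dyne, double tau_char, const Kin& K) {
  // erosion frequency: slip velocity at the platelet mid-height
  // (gamma * Dia/2) over one platelet diameter, times the shear excess
  // ratio and Goodman's non-adhesion fraction
  double gam = 0.1 * tau_dyne / K.mu;  // back to Pa then to shear rate
  return 0.5 * gam * (tau_dyne / tau_char) *
         (1.0 - std::exp(-0.0095 * tau_dyne));
}
static inline double gamma_inh_of(double AT, double TBU, const Kin& K) {
  double Tn = K.eps * TBU;
  double num = K.k1T * K.H * AT / (K.alpha * K.K_AT * K.K_T);
  double den = 1.0 + AT / K.K_AT + Tn / K.K_T +
               AT * Tn / (K.alpha * K.K_AT * K.K_T);
  return num / den;
}

// ---------------------------------------------------------------------------
// Exported building blocks
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_solve_flow(List gridpack, NumericMatrix phi, List params,
                    Nullable<List> init, double dt, int max_outer,
                    double tol, double du_tol, double alpha_u,
                    double alpha_p, int p_sweeps, int m_sweeps) {
  GridC G = load_grid(gridpack);
  std::vector<double> ph(phi.begin(), phi.end());
  std::vector<double> u((G.nx + 1) * G.ny, 0.0), v(G.nx * (G.ny + 1), 0.0),
      p(G.nx * G.ny, 0.0);
  if (init.isNotNull()) {
    List in(init);
    NumericMatrix iu = in["u"], iv = in["v"], ip = in["p"];
    std::copy(iu.begin(), iu.end(), u.begin());
    std::copy(iv.begin(), iv.end(), v.begin());
    std::copy(ip.begin(), ip.end(), p.begin());
  } else if (G.wbc == 2 || G.ebc == 2) {
    // initialize pressure linearly between the prescribed values
    for (int j = 0; j < G.ny; ++j)
      for (int i = 0; i < G.nx; ++i) {
        double s = (G.xc[i] - G.xf[0]) / (G.xf[G.nx] - G.xf[0]);
        p[G.id(i, j)] = G.w_p + s * (G.e_p - G.w_p);
      }
  }
  FlowOpts opt; opt.dt = dt; opt.max_outer = max_outer; opt.tol = tol;
  opt.alpha_u = alpha_u; opt.alpha_p = alpha_p; opt.p_sweeps = p_sweeps;
  opt.m_sweeps = m_sweeps; opt.du_tol = du_tol;
  double mu = as<double>(params["mu_f"]), rho0 = as<double>(params["rho_f0"]),
         C2 = as<double>(params["C2"]);
  FlowResult r = flow_solve(G, ph, C2, mu, rho0, u, v, p, opt);
  NumericMatrix uo(G.nx + 1, G.ny), vo(G.nx, G.ny + 1), po(G.nx, G.ny);
  std::copy(u.begin(), u.end(), uo.begin());
  std::copy(v.begin(), v.end(), vo.begin());
  std::copy(p.begin(), p.end(), po.begin());
  return List::create(_["u"] = uo, _["v"] = vo, _["p"] = po,
                      _["iters"] = r.iters, _["residual"] = r.res,
                      _["converged"] = r.converged, _["Q_in"] = r.Qin);
}

// [[Rcpp::export]]
NumericMatrix cpp_shear(List gridpack, NumericMatrix u, NumericMatrix v) {
  GridC G = load_grid(gridpack);
  std::vector<double> uu(u.begin(), u.end()), vv(v.begin(), v.end());
  std::vector<double> gam(G.nx * G.ny, 0.0);
  compute_shear(G, uu, vv, gam);
  NumericMatrix out(G.nx, G.ny);
  std::copy(gam.begin(), gam.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_advect_diffuse(List gridpack, NumericMatrix C,
                                 NumericMatrix u, NumericMatrix v,
                                 NumericMatrix Dcell, double dt, int nsteps,
                                 double cin) {
  GridC G = load_grid(gridpack);
  std::vector<double> cc(C.begin(), C.end());
  std::vector<double> Dc(Dcell.begin(), Dcell.end());
  std::vector<double> Fx((G.nx + 1) * G.ny), Fy(G.nx * (G.ny + 1));
  for (int j = 0; j < G.ny; ++j)
    for (int i = 0; i <= G.nx; ++i)
      Fx[G.idu(i, j)] = u(i, j) * G.dy[j] * G.rc[j];
  for (int j = 0; j <= G.ny; ++j)
    for (int i = 0; i < G.nx; ++i)
      Fy[G.idv(i, j)] = v(i, j) * G.dx[i] * G.rf[j];
  for (int s = 0; s < nsteps; ++s)
    transport_species(G, cc, Fx, Fy, Dc, dt, cin);
  NumericMatrix out(G.nx, G.ny);
  std::copy(cc.begin(), cc.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Coupled driver
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_coupled(List gridpack, List params, List config) {
  GridC G = load_grid(gridpack);
  Kin K = load_kin(params);
  const int nx = G.nx, ny = G.ny, nc = nx * ny;

  NumericVector cinv = config["cin"];           // 7 mobile inlet values
  double t0 = as<double>(config["t0"]);
  double t_end = as<double>(config["t_end"]);
  double out_dt = as<double>(config["out_dt"]);
  double field_dt = as<double>(config["field_dt"]);
  double flow_dt = as<double>(config["flow_dt"]);
  double dphi_trigger = as<double>(config["dphi_trigger"]);
  double morpho_thresh = as<double>(config["morpho_thresh"]);
  double phi_occ = as<double>(config["phi_occ"]);
  double wall_y = as<double>(config["wall_y"]);
  int wall_north = as<int>(config["wall_north"]);
  double dt_max = as<double>(config["dt_max"]);
  double cfl = as<double>(config["cfl"]);
  int stop_at_occ = as<int>(config["stop_at_occlusion"]);
  int flow_max_outer = as<int>(config["flow_max_outer"]);
  double flow_tol = as<double>(config["flow_tol"]);

  // state
  std::vector<std::vector<double>> C(NSP, std::vector<double>(nc, 0.0));
  std::vector<double> u((nx + 1) * ny, 0.0), v(nx * (ny + 1), 0.0),
      p(nc, 0.0);
  bool have_init_flow = false;
  if (config.containsElementNamed("init") && !Rf_isNull(config["init"])) {
    List in = config["init"];
    List Ci = in["C"];
    for (int s = 0; s < NSP; ++s) {
      NumericMatrix m = Ci[s];
      std::copy(m.begin(), m.end(), C[s].begin());
    }
    if (in.containsElementNamed("u") && !Rf_isNull(in["u"])) {
      NumericMatrix iu = in["u"], iv = in["v"], ip = in["p"];
      std::copy(iu.begin(), iu.end(), u.begin());
      std::copy(iv.begin(), iv.end(), v.begin());
      std::copy(ip.begin(), ip.end(), p.begin());
      have_init_flow = true;
    }
  } else {
    for (int c = 0; c < nc; ++c)
      if (!G.solid[c])
        for (int s = 0; s < 7; ++s) C[s][c] = cinv[s];
  }
  if (!have_init_flow && (G.wbc == 2 || G.ebc == 2))
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double sfrac = (G.xc[i] - G.xf[0]) / (G.xf[nx] - G.xf[0]);
        p[G.id(i, j)] = G.w_p + sfrac * (G.e_p - G.w_p);
      }

  std::vector<double> phi(nc, 0.0), phi_last(nc, 0.0), gam(nc, 0.0);
  std::vector<double> Vol(nc, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      Vol[G.id(i, j)] = G.dx[i] * G.dy[j] * G.rc[j];
  double volw = (G.axisym ? 2.0 * M_PI : 1.0);

  auto update_phi = [&]() {
    for (int c = 0; c < nc; ++c)
      phi[c] = std::min(1.0, (C[iRPD][c] + C[iAPD][c] + C[iAPSd][c]) / K.PLT_max);
  };
  update_phi();

  FlowOpts fopt; fopt.dt = -1; fopt.max_outer = flow_max_outer;
  fopt.tol = flow_tol; fopt.alpha_u = 0.7; fopt.alpha_p = 0.3;
  fopt.p_sweeps = 40; fopt.m_sweeps = 3; fopt.du_tol = 1e-6;

  std::vector<double> Fx((nx + 1) * ny, 0.0), Fy(nx * (ny + 1), 0.0);
  std::vector<double> Dplt(nc, 0.0), gam_eff(nc, 0.0);
  double dt = dt_max;
  double Q0 = 0.0, Qnow = 0.0;
  int nsolves = 0;

  // derive everything the transport/reaction stages need from the current
  // u, v (shear, face fluxes, diffusivities, stable dt) without touching
  // the flow itself; used directly when restarting from a checkpointed
  // flow so that a restart replays the uninterrupted trajectory
  auto derive_flow = [&]() {
    Qnow = 0.0;
    for (int j = 0; j < ny; ++j) Qnow += u[G.idu(0, j)] * G.dy[j] * G.rc[j];
    compute_shear(G, u, v, gam);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i)
        Fx[G.idu(i, j)] = u[G.idu(i, j)] * G.dy[j] * G.rc[j];
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i)
        Fy[G.idv(i, j)] = v[G.idv(i, j)] * G.dx[i] * G.rf[j];
    for (int c = 0; c < nc; ++c)
      Dplt[c] = K.D_plt_base + K.D_plt_slope * gam[c];
    // Interface shear for embolization: a deposit's surface is exposed to
    // the largest shear among its own cell and its fluid face neighbours,
    // so growing deposits cannot bury themselves away from erosion while
    // interior thrombus (thrombus-surrounded) remains protected.
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = G.id(i, j);
        if (G.solid[c]) { gam_eff[c] = 0; continue; }
        double g = gam[c];
        if (i > 0 && !G.sol(i - 1, j)) g = std::max(g, gam[G.id(i - 1, j)]);
        if (i < nx - 1 && !G.sol(i + 1, j)) g = std::max(g, gam[G.id(i + 1, j)]);
        if (j > 0 && !G.sol(i, j - 1)) g = std::max(g, gam[G.id(i, j - 1)]);
        if (j < ny - 1 && !G.sol(i, j + 1)) g = std::max(g, gam[G.id(i, j + 1)]);
        gam_eff[c] = g;
      }
    // stable explicit dt from advection + diffusion rates
    double rmax = 1e-12;
    double Dfix = std::max(std::max(K.D_apr, K.D_aps),
                           std::max(std::max(K.D_PT, K.D_TB), K.D_AT));
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = G.id(i, j);
        if (G.solid[c]) continue;
        double Dm = std::max(Dplt[c], Dfix);
        double rate = 0.0;
        rate += std::max(Fx[G.idu(i + 1, j)], 0.0) - std::min(Fx[G.idu(i, j)], 0.0);
        rate += std::max(Fy[G.idv(i, j + 1)], 0.0) - std::min(Fy[G.idv(i, j)], 0.0);
        double Ae = G.dy[j] * G.rc[j];
        double An = G.dx[i] * G.rf[j + 1], As = G.dx[i] * G.rf[j];
        if (i > 0) rate += Dm * Ae / (G.xc[i] - G.xc[i - 1]);
        if (i < nx - 1) rate += Dm * Ae / (G.xc[i + 1] - G.xc[i]);
        if (j > 0) rate += Dm * As / (G.yc[j] - G.yc[j - 1]);
        if (j < ny - 1) rate += Dm * An / (G.yc[j + 1] - G.yc[j]);
        rmax = std::max(rmax, rate / Vol[c]);
      }
    dt = std::min(dt_max, cfl / rmax);
    phi_last = phi;
  };
  auto resolve_flow = [&]() {
    flow_solve(G, phi, K.C2, K.mu, K.rho0, u, v, p, fopt);
    ++nsolves;
    derive_flow();
  };
  if (have_init_flow) derive_flow(); else resolve_flow();
  Q0 = std::fabs(Qnow);
  if (Q0 <= 0) Q0 = 1e-30;

  // histories
  std::vector<double> Ht, Hh, Hl, Hvol, HQ;
  std::vector<std::vector<double>> Htot(NSP);
  std::vector<double> Hft;
  std::vector<std::vector<double>> Hfields;
  double occ_geom = -1.0, occ_flow = -1.0;
  long clamps = 0;

  auto record = [&](double t) {
    double h = 0.0, l = 0.0, vol = 0.0, xmin = 1e30, xmax = -1e30;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = G.id(i, j);
        if (G.solid[c]) continue;
        vol += phi[c] * Vol[c] * volw;
        if (phi[c] >= morpho_thresh) {
          double ext = wall_north ? (wall_y - G.yf[j]) : (G.yf[j + 1] - wall_y);
          h = std::max(h, ext);
          xmin = std::min(xmin, G.xf[i]);
          xmax = std::max(xmax, G.xf[i + 1]);
        }
      }
    if (xmax > xmin) l = xmax - xmin;
    Ht.push_back(t); Hh.push_back(h); Hl.push_back(l); Hvol.push_back(vol);
    HQ.push_back(Qnow);
    for (int s = 0; s < NSP; ++s) {
      double tot = 0.0;
      for (int c = 0; c < nc; ++c) tot += C[s][c] * Vol[c] * volw;
      Htot[s].push_back(tot);
    }
  };
  auto record_field = [&](double t) {
    Hfields.push_back(phi);
    Hft.push_back(t);
  };
  auto check_occlusion = [&](double t) {
    if (occ_geom < 0) {
      for (int i = 0; i < nx; ++i) {
        bool span = true, any = false;
        for (int j = 0; j < ny; ++j) {
          int c = G.id(i, j);
          if (G.solid[c]) continue;
          any = true;
          if (phi[c] < phi_occ) { span = false; break; }
        }
        if (any && span) { occ_geom = t; break; }
      }
    }
    if (occ_flow < 0 && std::fabs(Qnow) < 0.01 * Q0) occ_flow = t;
  };

  record(t0);
  if (field_dt > 0) record_field(t0);
  double t = t0;
  double next_out = t0 + out_dt, next_field = t0 + field_dt,
         next_flow = t0 + flow_dt;

  std::vector<double> kprop(nc, 0.0);  // A_int/V near the thrombus interface
  long step_count = 0;

  while (t < t_end - 1e-12) {
    // land exactly on output/flow-update times so that a run restarted
    // from a checkpoint replays the identical step sequence
    double step = std::min(std::min(dt, t_end - t),
                           std::min(next_out - t, next_flow - t));
    if (field_dt > 0) step = std::min(step, next_field - t);
    if (step <= 0) step = dt;
    // --- propagation interface scan (uses phi at start of step)
    for (int c = 0; c < nc; ++c) kprop[c] = 0.0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = G.id(i, j);
        if (G.solid[c] || phi[c] <= K.phi_prop) continue;
        double Ae = G.dy[j] * G.rc[j];
        double An = G.dx[i] * G.rf[j + 1], As = G.dx[i] * G.rf[j];
        if (i > 0 && !G.sol(i - 1, j)) kprop[G.id(i - 1, j)] += Ae;
        if (i < nx - 1 && !G.sol(i + 1, j)) kprop[G.id(i + 1, j)] += Ae;
        if (j > 0 && !G.sol(i, j - 1)) kprop[G.id(i, j - 1)] += As;
        if (j < ny - 1 && !G.sol(i, j + 1)) kprop[G.id(i, j + 1)] += An;
      }
    for (int c = 0; c < nc; ++c) kprop[c] /= Vol[c];

    // --- transport of the 7 mobile species
    for (int s = 0; s < 7; ++s) {
      double Dconst = (s == iAPR) ? K.D_apr : (s == iAPS) ? K.D_aps :
                      (s == iPT) ? K.D_PT : (s == iTB) ? K.D_TB :
                      (s == iAT) ? K.D_AT : -1.0;
      if (Dconst < 0) {
        transport_species(G, C[s], Fx, Fy, Dplt, step, cinv[s]);
      } else {
        static thread_local std::vector<double> Dc;
        Dc.assign(nc, Dconst);
        transport_species(G, C[s], Fx, Fy, Dc, step, cinv[s]);
      }
      for (int c = 0; c < nc; ++c)
        if (C[s][c] < 0) { C[s][c] = 0; ++clamps; }
    }

    // --- reactions / deposition / embolization (donor-bounded transfers)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int c = G.id(i, j);
        if (G.solid[c]) continue;
        double RP = C[iRP][c], AP = C[iAP][c], apr = C[iAPR][c],
               aps = C[iAPS][c], PT = C[iPT][c], TB = C[iTB][c],
               AT = C[iAT][c], RPd = C[iRPD][c], APd = C[iAPD][c],
               APs = C[iAPSd][c];
        double tau_d = 10.0 * K.mu * gam[c];         // dyne/cm2
        double Om = K.wADP * apr / K.acADP + K.wTx * aps / K.acTx +
                    K.wTB * TB / K.acTB;
        double kapa = k_apa_of(Om, K);
        double kspa = k_spa_of(tau_d, K);
        double femb = f_emb_of(10.0 * K.mu * gam_eff[c], G.tau_char[c], K);
        double Gm = gamma_inh_of(AT, TB, K);
        double psi = 1.0 - (RPd + APd + APs) / K.PLT_max;
        if (psi < 0) psi = 0;
        double Scov = 1.0;
        double adh_r = 0.0, adh_a = 0.0;
        if (G.wall_area[c] > 0) {
          double Ns = (RPd + APd + APs) * Vol[c] / G.wall_area[c];
          Scov = 1.0 - Ns / K.PLT_s_max;
          if (Scov < 0) Scov = 0;
          adh_r = Scov * G.adh_rpdb[c];
          adh_a = Scov * G.adh_apdb[c];
        }
        double kact = kapa + kspa;
        double dep_b_r = psi * K.k_ra * kprop[c];
        double dep_b_a = psi * K.k_aa * kprop[c];
        // RP losses
        double Lrp = kact + dep_b_r + adh_r;
        double grp = (Lrp > 0) ? step / (1.0 + step * Lrp) : 0.0;
        double T_act = RP * kact * grp;
        double T_depR = RP * (dep_b_r + adh_r) * grp;
        // AP losses
        double Lap = dep_b_a + adh_a;
        double gap = (Lap > 0) ? step / (1.0 + step * Lap) : 0.0;
        double T_depA = AP * Lap * gap;
        // RPd losses
        double Lrpd = kact + femb;
        double grpd = (Lrpd > 0) ? step / (1.0 + step * Lrpd) : 0.0;
        double T_actD = RPd * kact * grpd;
        double T_embR = RPd * femb * grpd;
        // APd losses
        double Lapd = femb + K.f_stb;
        double gapd = (Lapd > 0) ? step / (1.0 + step * Lapd) : 0.0;
        double T_embA = APd * femb * gapd;
        double T_stb = APd * K.f_stb * gapd;
        // platelet updates (exactly conservative)
        C[iRP][c] = RP - T_act - T_depR + T_embR;
        C[iAP][c] = AP + T_act - T_depA + T_embA;
        C[iRPD][c] = RPd + (1.0 - K.theta) * T_depR - T_actD - T_embR;
        C[iAPD][c] = APd + K.theta * T_depR + T_depA + T_actD - T_embA - T_stb;
        C[iAPSd][c] = APs + T_stb;
        // ADP release from realized activation/contact events
        double rel = K.lambda * (T_act + T_actD + K.theta * T_depR);
        C[iAPR][c] = (apr + rel) / (1.0 + step * K.k1ADP);
        // TxA2 synthesis + first-order inhibition
        C[iAPS][c] = (aps + step * K.s_pj * (AP + APd)) /
                     (1.0 + step * K.k1Tx);
        // thrombin generation (prothrombin-limited) and inhibition
        // procoagulant membranes only: free+deposited activated platelets
        // and deposited resting platelets (see bulk_sources in R)
        double Lpt = K.eps * (K.phi_at * (AP + APd) + K.phi_rt * RPd);
        double gpt = (Lpt > 0) ? step / (1.0 + step * Lpt) : 0.0;
        double T_pt = PT * Lpt * gpt;           // nmol/m3 consumed
        C[iPT][c] = PT - T_pt;
        double TBgen = T_pt / K.eps;            // U/m3 generated
        double TBn = (TB + TBgen) / (1.0 + step * Gm);
        double TBinh = TB + TBgen - TBn;        // U/m3 neutralized
        C[iTB][c] = TBn;
        C[iAT][c] = AT - K.eps * TBinh;
        if (C[iAT][c] < 0) { C[iAT][c] = 0; ++clamps; }
        // ADP injection port (diffusive exchange with the pipette tip)
        if (G.port_kex[c] > 0) {
          double kex = G.port_kex[c];
          C[iAPR][c] = (C[iAPR][c] + step * kex * G.port_conc) /
                       (1.0 + step * kex);
        }
      }
    }
    update_phi();
    t += step;

    // --- scheduled flow updates and outputs
    double dphi_max = 0.0;
    for (int c = 0; c < nc; ++c)
      dphi_max = std::max(dphi_max, std::fabs(phi[c] - phi_last[c]));
    if (t + 1e-12 >= next_flow || dphi_max > dphi_trigger) {
      resolve_flow();
      while (next_flow <= t + 1e-12) next_flow += flow_dt;
    }
    check_occlusion(t);
    if (t + 1e-12 >= next_out || t >= t_end - 1e-12 ||
        (occ_geom >= 0 && stop_at_occ)) {
      record(t);
      while (next_out <= t + 1e-12) next_out += out_dt;
    }
    if (field_dt > 0 && t + 1e-12 >= next_field) {
      record_field(t);
      while (next_field <= t + 1e-12) next_field += field_dt;
    }
    if (occ_geom >= 0 && stop_at_occ) break;
    if ((++step_count & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // pack outputs
  List fields(NSP);
  for (int s = 0; s < NSP; ++s) {
    NumericMatrix m(nx, ny);
    std::copy(C[s].begin(), C[s].end(), m.begin());
    fields[s] = m;
  }
  NumericMatrix um(nx + 1, ny), vm(nx, ny + 1), pm(nx, ny), gm(nx, ny),
      phm(nx, ny);
  std::copy(u.begin(), u.end(), um.begin());
  std::copy(v.begin(), v.end(), vm.begin());
  std::copy(p.begin(), p.end(), pm.begin());
  std::copy(gam.begin(), gam.end(), gm.begin());
  std::copy(phi.begin(), phi.end(), phm.begin());
  List totals(NSP);
  for (int s = 0; s < NSP; ++s) totals[s] = wrap(Htot[s]);
  List fieldhist(Hfields.size());
  for (size_t s = 0; s < Hfields.size(); ++s) {
    NumericMatrix m(nx, ny);
    std::copy(Hfields[s].begin(), Hfields[s].end(), m.begin());
    fieldhist[s] = m;
  }
  return List::create(
      _["time"] = wrap(Ht), _["height"] = wrap(Hh), _["length"] = wrap(Hl),
      _["volume"] = wrap(Hvol), _["Q"] = wrap(HQ), _["totals"] = totals,
      _["occlusion_time_geometric"] = occ_geom,
      _["occlusion_time_flow"] = occ_flow,
      _["C"] = fields, _["u"] = um, _["v"] = vm, _["p"] = pm,
      _["gamma"] = gm, _["phi"] = phm,
      _["phi_times"] = wrap(Hft), _["phi_history"] = fieldhist,
      _["clamp_events"] = (double)clamps, _["flow_solves"] = nsolves,
      _["t_final"] = t, _["Q0"] = Q0, _["dt_last"] = dt);
}
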