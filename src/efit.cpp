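#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 2D velocity-stress staggered-grid (Virieux) elastodynamic update.
//
// Layout (uniform spacing dx, x = row index i lateral, y = column index j
// depth, transducer face at j = 0):
//   sxx, syy  at cell centers        (i, j)
//   sxy       at (i+1/2, j+1/2)
//   vx        at (i+1/2, j)
//   vy        at (i, j+1/2)
// Material (rho, lambda, mu) is cell-centered; buoyancy at velocity nodes is
// the inverse of the arithmetic neighbour mean with void cells counted as
// rho = 0 (vacuum formalism: void cells carry zero moduli, so their stresses
// stay identically zero and staircased boundaries are traction-free).
// Shear stiffness at sxy nodes is the harmonic mean of the four neighbours,
// zero if any neighbour is fluid or void.
//
// Boundaries: velocity nodes on the outer edges are never updated (rigid),
// which models the transducer face as a rigid baffle at j = 0; a Cerjan
// sponge (precomputed per-cell factor `damp`) absorbs left/right/bottom.

static inline double idx2(const std::vector<double>& a, int nx, int i, int j) {
  return a[(size_t)j * nx + i];
}

// [[Rcpp::export(name = ".efit_core")]]
List efit_core(NumericMatrix lam, NumericMatrix mu, NumericMatrix rho,
               IntegerMatrix voidm, NumericMatrix damp,
               double dt, double dx, int nt,
               NumericVector src, IntegerMatrix src_cells,
               List rec_cells, IntegerVector rec_kind,
               IntegerVector snap_steps, int snap_component,
               int energy_every, bool return_state, int check_every) {
  const int nx = lam.nrow(), ny = lam.ncol();
  const double cfl_fac = dt / dx;

  std::vector<double> sxx(nx * ny, 0.0), syy(nx * ny, 0.0), sxy(nx * ny, 0.0),
      vx(nx * ny, 0.0), vy(nx * ny, 0.0);

  // Precomputed coefficients. Damping factors are sampled at each field's
  // own staggered position (geometric mean of the neighbouring cell
  // factors) so the sponge is exactly mirror-symmetric.
  std::vector<double> c11(nx * ny), c13(nx * ny), cxy(nx * ny),
      bx(nx * ny, 0.0), by(nx * ny, 0.0), dmp(nx * ny),
      dmp_x(nx * ny), dmp_y(nx * ny), dmp_xy(nx * ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      size_t k = (size_t)j * nx + i;
      double l = voidm(i, j) ? 0.0 : lam(i, j);
      double m = voidm(i, j) ? 0.0 : mu(i, j);
      c11[k] = cfl_fac * (l + 2.0 * m);
      c13[k] = cfl_fac * l;
      dmp[k] = damp(i, j);
      double d10 = (i + 1 < nx) ? damp(i + 1, j) : damp(i, j);
      double d01 = (j + 1 < ny) ? damp(i, j + 1) : damp(i, j);
      double d11 = (i + 1 < nx && j + 1 < ny) ? damp(i + 1, j + 1)
                                              : damp(i, j);
      dmp_x[k] = std::sqrt(damp(i, j) * d10);
      dmp_y[k] = std::sqrt(damp(i, j) * d01);
      dmp_xy[k] = std::sqrt(std::sqrt(damp(i, j) * d10) *
                            std::sqrt(d01 * d11));
      // mu at (i+1/2, j+1/2): harmonic mean of 4 neighbours, 0 if any is 0
      double m00 = m;
      double m10 = (i + 1 < nx && !voidm(i + 1, j)) ? mu(i + 1, j) : 0.0;
      double m01 = (j + 1 < ny && !voidm(i, j + 1)) ? mu(i, j + 1) : 0.0;
      double m11 = (i + 1 < nx && j + 1 < ny && !voidm(i + 1, j + 1))
                       ? mu(i + 1, j + 1) : 0.0;
      if (m00 > 0 && m10 > 0 && m01 > 0 && m11 > 0)
        cxy[k] = cfl_fac * 4.0 / (1.0 / m00 + 1.0 / m10 + 1.0 / m01 + 1.0 / m11);
      else
        cxy[k] = 0.0;
      // buoyancy at vx node (i+1/2, j) and vy node (i, j+1/2)
      double r0 = voidm(i, j) ? 0.0 : rho(i, j);
      if (i + 1 < nx) {
        double r1 = voidm(i + 1, j) ? 0.0 : rho(i + 1, j);
        double rb = 0.5 * (r0 + r1);
        bx[k] = (rb > 0.0) ? cfl_fac / rb : 0.0;
      }
      if (j + 1 < ny) {
        double r1 = voidm(i, j + 1) ? 0.0 : rho(i, j + 1);
        double rb = 0.5 * (r0 + r1);
        by[k] = (rb > 0.0) ? cfl_fac / rb : 0.0;
      }
    }
  }

  const int nsrc = src_cells.nrow();
  const int nrec = rec_cells.size();
  NumericMatrix traces(nt, nrec);
  std::vector<std::vector<std::pair<int, int> > > recs(nrec);
  for (int r = 0; r < nrec; ++r) {
    IntegerMatrix cm = rec_cells[r];
    for (int q = 0; q < cm.nrow(); ++q)
      recs[r].push_back(std::make_pair(cm(q, 0) - 1, cm(q, 1) - 1));
  }

  std::vector<int> snaps(snap_steps.begin(), snap_steps.end());
  List snap_out(snaps.size());
  int snap_next = 0;

  int n_energy = (energy_every > 0) ? nt / energy_every + 1 : 0;
  NumericVector energy(n_energy);
  int e_at = 0;
  // staggered-time kinetic energy needs v at the previous half step
  std::vector<double> vx_prev, vy_prev;
  if (energy_every > 0) {
    vx_prev.resize((size_t)nx * ny, 0.0);
    vy_prev.resize((size_t)nx * ny, 0.0);
  }

  for (int it = 0; it < nt; ++it) {
    bool energy_step = energy_every > 0 && (it % energy_every) == 0;
    if (energy_step) {
      vx_prev = vx;
      vy_prev = vy;
    }
    // --- velocity update ---
    // vx nodes sit on vertical cell faces: indices 0..nx-2 are interior
    // (the outermost faces are rigid), which keeps the rigid side walls
    // mirror-symmetric. vy nodes sit on cell centers laterally; sxy outside
    // the face strip is identically zero.
    for (int j = 1; j < ny - 1; ++j) {
      const size_t off = (size_t)j * nx;
      for (int i = 0; i < nx - 1; ++i) {
        size_t k = off + i;
        vx[k] += bx[k] * (sxx[k + 1] - sxx[k] + sxy[k] - sxy[k - nx]);
      }
      for (int i = 0; i < nx; ++i) {
        size_t k = off + i;
        double sl = (i > 0) ? sxy[k - 1] : 0.0;
        vy[k] += by[k] * (sxy[k] - sl + syy[k + nx] - syy[k]);
      }
    }
    // j = 0 row: vx along the face (tangential, allowed); vy uses sxy[j-1]=0
    {
      for (int i = 0; i < nx - 1; ++i) {
        size_t k = i;
        vx[k] += bx[k] * (sxx[k + 1] - sxx[k] + sxy[k]);
      }
      for (int i = 0; i < nx; ++i) {
        size_t k = i;
        double sl = (i > 0) ? sxy[k - 1] : 0.0;
        vy[k] += by[k] * (sxy[k] - sl + syy[k + nx] - syy[k]);
      }
    }

    // --- discrete energy (kinetic + strain) ---
    // The leapfrog-conserved quadratic form pairs velocities at successive
    // half steps, KE = rho/2 * v(t-1/2) v(t+1/2), with the strain energy of
    // the stresses the velocity update consumed.
    if (energy_step) {
      double E = 0.0;
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (voidm(i, j)) continue;
          size_t k = (size_t)j * nx + i;
          double r = rho(i, j), l = lam(i, j), m = mu(i, j);
          E += 0.5 * r * (vx[k] * vx_prev[k] + vy[k] * vy_prev[k]);
          double tr = sxx[k] + syy[k];
          E += tr * tr / (8.0 * (l + m));
          if (m > 0) {
            double dev = 0.5 * (sxx[k] - syy[k]);
            E += (dev * dev + sxy[k] * sxy[k]) / (2.0 * m);
          }
        }
      energy[e_at++] = E * dx * dx;
    }

    // --- stress update (vx on the outermost faces is rigid, i.e. zero) ---
    for (int j = 1; j < ny; ++j) {
      const size_t off = (size_t)j * nx;
      for (int i = 0; i < nx; ++i) {
        size_t k = off + i;
        double vl = (i > 0) ? vx[k - 1] : 0.0;
        double vr = (i < nx - 1) ? vx[k] : 0.0;
        double dvx = vr - vl;
        double dvy = vy[k] - vy[k - nx];
        sxx[k] += c11[k] * dvx + c13[k] * dvy;
        syy[k] += c13[k] * dvx + c11[k] * dvy;
      }
    }
    { // j = 0 row: vy below face minus 0 (rigid baffle: vy = 0 on the face)
      for (int i = 0; i < nx; ++i) {
        size_t k = i;
        double vl = (i > 0) ? vx[k - 1] : 0.0;
        double vr = (i < nx - 1) ? vx[k] : 0.0;
        double dvx = vr - vl;
        double dvy = vy[k];
        sxx[k] += c11[k] * dvx + c13[k] * dvy;
        syy[k] += c13[k] * dvx + c11[k] * dvy;
      }
    }
    for (int j = 0; j < ny - 1; ++j) {
      const size_t off = (size_t)j * nx;
      for (int i = 0; i < nx - 1; ++i) {
        size_t k = off + i;
        if (cxy[k] != 0.0)
          sxy[k] += cxy[k] * (vx[k + nx] - vx[k] + vy[k + 1] - vy[k]);
      }
    }

    // --- source: surface force density added to syy over the element cells.
    // The dt/dx factor makes the one-cell-thick surface layer a consistent
    // discretisation of a stress source concentrated on the face, so the
    // radiated amplitude converges under grid refinement.
    double sv = src[it] * cfl_fac;
    if (sv != 0.0) {
      for (int s = 0; s < nsrc; ++s) {
        int i = src_cells(s, 0) - 1, j = src_cells(s, 1) - 1;
        syy[(size_t)j * nx + i] += sv;
      }
    }

    // --- sponge damping (per staggered position) ---
    for (size_t k = 0; k < (size_t)nx * ny; ++k) {
      if (dmp[k] != 1.0 || dmp_xy[k] != 1.0) {
        sxx[k] *= dmp[k]; syy[k] *= dmp[k];
        sxy[k] *= dmp_xy[k];
        vx[k] *= dmp_x[k]; vy[k] *= dmp_y[k];
      }
    }

    // --- record ---
    for (int r = 0; r < nrec; ++r) {
      double acc = 0.0;
      if (rec_kind[r] == 0) {          // element: mean normal stress syy
        for (size_t q = 0; q < recs[r].size(); ++q)
          acc += syy[(size_t)recs[r][q].second * nx + recs[r][q].first];
      } else {                          // probe point: pressure-like
        for (size_t q = 0; q < recs[r].size(); ++q) {
          size_t k = (size_t)recs[r][q].second * nx + recs[r][q].first;
          acc += -0.5 * (sxx[k] + syy[k]);
        }
      }
      traces(it, r) = acc / (double)recs[r].size();
    }

    // --- snapshots ---
    if (snap_next < (int)snaps.size() && it == snaps[snap_next]) {
      NumericMatrix sm(nx, ny);
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t k = (size_t)j * nx + i;
          if (snap_component == 0)      sm(i, j) = -0.5 * (sxx[k] + syy[k]);
          else if (snap_component == 1) sm(i, j) = sxy[k];
          else if (snap_component == 2) sm(i, j) = vx[k];
          else                          sm(i, j) = vy[k];
        }
      snap_out[snap_next++] = sm;
    }

    // --- stability check ---
    if (check_every > 0 && (it % check_every) == 0) {
      size_t mid = (size_t)(ny / 2) * nx + nx / 2;
      if (!R_finite(syy[mid]) || !R_finite(vx[mid]))
        stop("numerical instability (non-finite field) at step %d", it + 1);
    }
  }

  // final full-field finiteness check
  for (size_t k = 0; k < (size_t)nx * ny; ++k)
    if (!R_finite(syy[k]) || !R_finite(vx[k]) || !R_finite(vy[k]))
      stop("numerical instability (non-finite field) at final step");

  List out = List::create(_["traces"] = traces, _["snapshots"] = snap_out,
                          _["energy"] = energy);
  if (return_state) {
    NumericMatrix msxx(nx, ny), msyy(nx, ny), msxy(nx, ny), mvx(nx, ny),
        mvy(nx, ny);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t k = (size_t)j * nx + i;
        msxx(i, j) = sxx[k]; msyy(i, j) = syy[k]; msxy(i, j) = sxy[k];
        mvx(i, j) = vx[k]; mvy(i, j) = vy[k];
      }
    out["state"] = List::create(_["sxx"] = msxx, _["syy"] = msyy,
                                _["sxy"] = msxy, _["vx"] = mvx, _["vy"] = mvy);
  }
  return out;
}
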