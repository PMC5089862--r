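// Compiled core: pair potentials, neighbor search, Brownian-dynamics
// propagation, windowed MSD, nearest-surface distances and voxel counting.
// Units package-wide: lengths in Angstrom, times in ps, energies in kBT,
// diffusion constants in A^2/ps, forces in kBT/A.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// minimum-image convention for one displacement component (cubic box)
static inline double mimg(double d, double L) {
  if (L <= 0.0) return d;
  return d - L * std::nearbyint(d / L);
}

static inline double wrap0L(double x, double L) {
  double y = x - L * std::floor(x / L);
  // guard against y == L from rounding
  if (y >= L) y = 0.0;
  return y;
}

struct Pot {
  int form;       // 0 = half_harmonic, 1 = lennard_jones, 2 = lj_coulomb
  double k;       // kBT/A^2
  double delta;   // A
  double eps;     // kBT
  double lB;      // Bjerrum length, A (Coulomb prefactor in kBT units)
  double ljcut;   // LJ cutoff in units of sigma_ij
};

static Pot pot_from_list(List p) {
  Pot q;
  q.form  = as<int>(p["form_id"]);
  q.k     = as<double>(p["k"]);
  q.delta = as<double>(p["delta"]);
  q.eps   = as<double>(p["epsilon"]);
  q.lB    = as<double>(p["bjerrum"]);
  q.ljcut = as<double>(p["lj_cutoff"]);
  return q;
}

// pair energy; *fmag receives -dV/dr (positive = repulsive)
static inline double pair_ev(double r, double ai, double aj, double qi,
                             double qj, const Pot& p, double L, double* fmag) {
  double e = 0.0, f = 0.0;
  if (p.form == 0) {
    double rc = ai + aj + p.delta;
    if (r < rc) {
      double x = r - ai - aj - p.delta; // negative inside the buffer
      e = 0.5 * p.k * x * x;
      f = -p.k * x;
    }
  } else {
    double sig = ai + aj;
    double cut = p.ljcut * sig;
    if (L > 0.0 && cut > 0.5 * L) cut = 0.5 * L;
    if (r < cut) {
      double sr2 = (sig / r) * (sig / r);
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      double sc2 = (sig / cut) * (sig / cut);
      double sc6 = sc2 * sc2 * sc2;
      // truncated-and-shifted so the energy is continuous at the cutoff
      e = 4.0 * p.eps * (sr12 - sr6) - 4.0 * p.eps * (sc6 * sc6 - sc6);
      f = 24.0 * p.eps * (2.0 * sr12 - sr6) / r;
    }
    if (p.form == 2 && qi != 0.0 && qj != 0.0) {
      double ccut = (L > 0.0) ? 0.5 * L : R_PosInf;
      if (r < ccut) {
        e += p.lB * qi * qj / r;
        f += p.lB * qi * qj / (r * r);
      }
    }
  }
  *fmag = f;
  return e;
}

// Cell-list assisted energy/force evaluation for polydisperse systems.
// Particles much larger than the rest ("big": radius > 0.6 max radius, at
// most n/8 of the system) interact through a plain all-pairs sweep; the
// remaining particles use a linked-cell grid sized by their own maximum
// interaction range.  Falls back to all-pairs when fewer than 3 cells fit
// per box edge or the box is aperiodic.  Exactness relative to the
// all-pairs path is a tested invariant.
static double forces_impl(const std::vector<double>& x,
                          const std::vector<double>& radii,
                          const std::vector<double>& charges, double L,
                          const Pot& p, std::vector<double>& F,
                          bool use_cells) {
  const int n = (int)radii.size();
  std::fill(F.begin(), F.end(), 0.0);
  double etot = 0.0;
  const double halfL = 0.5 * L;
  // wrapped copy: single-fold minimum image is then exact
  std::vector<double> w(3 * n);
  if (L > 0.0)
    for (int k = 0; k < 3 * n; ++k) w[k] = wrap0L(x[k], L);
  else
    w = x;
  bool any_q = false;
  if (p.form == 2)
    for (double q : charges) if (q != 0.0) { any_q = true; break; }

  auto prange = [&](double ai, double aj) -> double {
    if (p.form == 0) return ai + aj + p.delta;
    double c = p.ljcut * (ai + aj);
    if (p.form == 2 && any_q) c = (L > 0.0) ? halfL : R_PosInf;
    if (L > 0.0 && c > halfL) c = halfL;
    return c;
  };
  auto accum = [&](int i, int j) {
    double dx = w[3 * i] - w[3 * j];
    double dy = w[3 * i + 1] - w[3 * j + 1];
    double dz = w[3 * i + 2] - w[3 * j + 2];
    if (L > 0.0) {
      if (dx > halfL) dx -= L; else if (dx < -halfL) dx += L;
      if (dy > halfL) dy -= L; else if (dy < -halfL) dy += L;
      if (dz > halfL) dz -= L; else if (dz < -halfL) dz += L;
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    double pc = prange(radii[i], radii[j]);
    if (r2 > pc * pc) return;
    double r = std::sqrt(r2);
    if (r < 1e-12)
      stop("singular configuration: particles %d and %d coincide", i + 1,
           j + 1);
    double fmag;
    etot += pair_ev(r, radii[i], radii[j], charges[i], charges[j], p, L,
                    &fmag);
    if (fmag != 0.0) {
      double s = fmag / r;
      F[3 * i] += s * dx;     F[3 * j] -= s * dx;
      F[3 * i + 1] += s * dy; F[3 * j + 1] -= s * dy;
      F[3 * i + 2] += s * dz; F[3 * j + 2] -= s * dz;
    }
  };
  auto all_pairs = [&]() {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) accum(i, j);
  };
  if (!use_cells || L <= 0.0) { all_pairs(); return etot; }

  double amax = 0.0;
  for (double a : radii) if (a > amax) amax = a;
  std::vector<char> isbig(n, 0);
  double thr = 0.6 * amax;
  int nbig = 0;
  for (int i = 0; i < n; ++i)
    if (radii[i] > thr) { isbig[i] = 1; ++nbig; }
  if (nbig > n / 8) {           // near-monodisperse: no useful split
    std::fill(isbig.begin(), isbig.end(), 0);
    nbig = 0;
  }
  double asmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (!isbig[i] && radii[i] > asmax) asmax = radii[i];
  double cut_ss = prange(asmax, asmax);
  int nc = (cut_ss > 0.0) ? (int)std::floor(L / cut_ss) : 0;
  if (nc < 3) { all_pairs(); return etot; }
  // no finer than ~one particle per cell: binning cost stays O(n)
  int ncap = (int)std::floor(std::cbrt(4.0 * n));
  if (ncap < 3) ncap = 3;
  if (nc > ncap) nc = ncap;
  if (nc > 64) nc = 64;

  // big particles: all-pairs against everything (big-big counted once)
  if (nbig) {
    for (int i = 0; i < n; ++i) {
      if (!isbig[i]) continue;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (isbig[j] && j < i) continue;
        if (!isbig[j] || j > i) accum(i, j);
      }
    }
  }

  // small particles: linked cells
  double cl = L / nc;
  std::vector<int> head(nc * nc * nc, -1), nxt(n, -1);
  std::vector<int> cix(n), ciy(n), ciz(n);
  for (int i = 0; i < n; ++i) {
    if (isbig[i]) continue;
    int cx = (int)(w[3 * i] / cl); if (cx >= nc) cx = nc - 1;
    int cy = (int)(w[3 * i + 1] / cl); if (cy >= nc) cy = nc - 1;
    int cz = (int)(w[3 * i + 2] / cl); if (cz >= nc) cz = nc - 1;
    cix[i] = cx; ciy[i] = cy; ciz[i] = cz;
    int c = (cx * nc + cy) * nc + cz;
    nxt[i] = head[c];
    head[c] = i;
  }
  for (int i = 0; i < n; ++i) {
    if (isbig[i]) continue;
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          int cx = (cix[i] + ox + nc) % nc;
          int cy = (ciy[i] + oy + nc) % nc;
          int cz = (ciz[i] + oz + nc) % nc;
          int c = (cx * nc + cy) * nc + cz;
          for (int j = head[c]; j >= 0; j = nxt[j])
            if (j > i) accum(i, j);
        }
  }
  return etot;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix coords, NumericVector radii,
                NumericVector charges, double L, List pot,
                bool use_cells = true) {
  const int n = coords.nrow();
  Pot p = pot_from_list(pot);
  std::vector<double> x(3 * n), rr(radii.begin(), radii.end()),
      qq(charges.begin(), charges.end()), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  double e = forces_impl(x, rr, qq, L, p, F, use_cells);
  NumericMatrix Fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
  return List::create(_["energy"] = e, _["forces"] = Fm);
}

static inline void cap_forces(std::vector<double>& F, int n, double cap) {
  if (!R_finite(cap)) return;
  for (int i = 0; i < n; ++i) {
    double fx = F[3 * i], fy = F[3 * i + 1], fz = F[3 * i + 2];
    double f = std::sqrt(fx * fx + fy * fy + fz * fz);
    if (f > cap) {
      double s = cap / f;
      F[3 * i] *= s; F[3 * i + 1] *= s; F[3 * i + 2] *= s;
    }
  }
}

// Brownian-dynamics propagation.
// scheme 0: Ermak-McCammon first order
// scheme 1: Iniesta-de la Torre predictor-corrector (same noise realization
//           in predictor and corrector half-updates)
// Noise comes from R's RNG stream so runs are reproducible via set.seed().
// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix coords0, NumericVector radii,
                NumericVector charges, double L, List pot, NumericVector D,
                double dt, int steps, int stride, int scheme,
                double force_cap, bool with_noise = true) {
  const int n = coords0.nrow();
  if (steps < 0) stop("steps must be >= 0");
  if (stride < 1) stop("output_stride must be >= 1");
  Pot p = pot_from_list(pot);
  std::vector<double> x(3 * n), rr(radii.begin(), radii.end()),
      qq(charges.begin(), charges.end());
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords0(i, d);
  std::vector<double> F(3 * n), F2(3 * n), xs(3 * n), xi(3 * n);

  const int nrec = steps / stride + 1;
  NumericVector frames(Dimension(nrec, n, 3));
  NumericVector energies(nrec), times(nrec);
  double e0 = forces_impl(x, rr, qq, L, p, F, true);
  int rec = 0;
  auto record = [&](int step, double e) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[rec + nrec * (i + (R_xlen_t)n * d)] = x[3 * i + d];
    energies[rec] = e;
    times[rec] = step * dt;
    ++rec;
  };
  record(0, e0);

  const double maxdisp = (L > 0.0) ? 0.25 * L : R_PosInf;
  for (int s = 1; s <= steps; ++s) {
    if (s % 1024 == 0) Rcpp::checkUserInterrupt();
    // forces at current configuration (reuse F from previous corrector)
    forces_impl(x, rr, qq, L, p, F, true);
    cap_forces(F, n, force_cap);
    for (int i = 0; i < n; ++i) {
      double sd = with_noise ? std::sqrt(2.0 * D[i] * dt) : 0.0;
      for (int d = 0; d < 3; ++d)
        xi[3 * i + d] = sd * (with_noise ? norm_rand() : 0.0);
    }
    if (scheme == 0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          double dx = D[i] * F[3 * i + d] * dt + xi[3 * i + d];
          if (std::fabs(dx) > maxdisp)
            stop("instability: particle %d moved %.1f A in one step at step "
                 "%d", i + 1, std::fabs(dx), s);
          x[3 * i + d] += dx;
        }
    } else {
      // predictor
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          xs[3 * i + d] =
              x[3 * i + d] + D[i] * F[3 * i + d] * dt + xi[3 * i + d];
      forces_impl(xs, rr, qq, L, p, F2, true);
      cap_forces(F2, n, force_cap);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          double dx = 0.5 * D[i] * (F[3 * i + d] + F2[3 * i + d]) * dt +
                      xi[3 * i + d];
          if (std::fabs(dx) > maxdisp)
            stop("instability: particle %d moved %.1f A in one step at step "
                 "%d", i + 1, std::fabs(dx), s);
          x[3 * i + d] += dx;
        }
    }
    if (s % stride == 0) {
      double e = forces_impl(x, rr, qq, L, p, F, true);
      record(s, e);
    }
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["energies"] = energies);
}

// All pairs with minimum-image distance below cutoff (brute force; serves as
// the oracle against the cell-list path and as the counting backend for
// small systems).
// [[Rcpp::export]]
List cpp_pairs_within(NumericMatrix coords, double L, double cutoff) {
  const int n = coords.nrow();
  std::vector<int> pi, pj;
  std::vector<double> pd;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = mimg(coords(i, 0) - coords(j, 0), L);
      double dy = mimg(coords(i, 1) - coords(j, 1), L);
      double dz = mimg(coords(i, 2) - coords(j, 2), L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= c2) {
        pi.push_back(i + 1);
        pj.push_back(j + 1);
        pd.push_back(std::sqrt(r2));
      }
    }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["d"] = wrap(pd));
}

// For each query point: distance to the nearest atom surface
// (min over atoms of |p - a| - radius_a) and the index of that atom.
// With zero radii this is the nearest atom-center distance.
// [[Rcpp::export]]
List cpp_nearest_surface(NumericMatrix points, NumericMatrix atoms,
                         NumericVector radii, double L) {
  const int m = points.nrow(), n = atoms.nrow();
  NumericVector dmin(m);
  IntegerVector imin(m);
  for (int q = 0; q < m; ++q) {
    double best = R_PosInf;
    int bi = NA_INTEGER;
    for (int j = 0; j < n; ++j) {
      double dx = mimg(points(q, 0) - atoms(j, 0), L);
      double dy = mimg(points(q, 1) - atoms(j, 1), L);
      double dz = mimg(points(q, 2) - atoms(j, 2), L);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[j];
      if (d < best) { best = d; bi = j + 1; }
    }
    dmin[q] = best;
    imin[q] = bi;
  }
  return List::create(_["dist"] = dmin, _["index"] = imin);
}

// Count of cross-selection pairs within cutoff (minimum image).
// [[Rcpp::export]]
int cpp_cross_pairs(NumericMatrix A, NumericMatrix B, double L,
                    double cutoff) {
  int cnt = 0;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = mimg(A(i, 0) - B(j, 0), L);
      double dy = mimg(A(i, 1) - B(j, 1), L);
      double dz = mimg(A(i, 2) - B(j, 2), L);
      if (dx * dx + dy * dy + dz * dz <= c2) ++cnt;
    }
  return cnt;
}

// Windowed mean-square displacement per particle.
// coords: nrec x n x 3 array (unwrapped), taus/origin stride in frame units;
// origins run from frame 0 to max_origin (inclusive) every ostride frames,
// the same origin set for every tau.
// [[Rcpp::export]]
NumericMatrix cpp_msd(NumericVector coords, IntegerVector taus, int ostride,
                      int max_origin) {
  IntegerVector dim = coords.attr("dim");
  const int F = dim[0], n = dim[1];
  const int nt = taus.size();
  NumericMatrix out(nt, n);
  if (ostride < 1) stop("origin stride must be >= 1");
  int norig = max_origin / ostride + 1;
  auto at = [&](int f, int i, int d) -> double {
    return coords[f + (R_xlen_t)F * (i + (R_xlen_t)n * d)];
  };
  for (int t = 0; t < nt; ++t) {
    int tau = taus[t];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int o = 0; o <= max_origin; o += ostride) {
        if (o + tau >= F) stop("tau exceeds trajectory length");
        double dx = at(o + tau, i, 0) - at(o, i, 0);
        double dy = at(o + tau, i, 1) - at(o, i, 1);
        double dz = at(o + tau, i, 2) - at(o, i, 2);
        acc += dx * dx + dy * dy + dz * dz;
      }
      out(t, i) = acc / norig;
    }
  }
  return out;
}

// Voxel-based accessible volume: assign every voxel center of the periodic
// box to a shell of its nearest-surface distance (min over atoms of center
// distance minus the atom's van der Waals radius).  Voxels inside any atom
// (negative distance) are "excluded"; shells beyond r_max are pooled in
// "beyond".  Counts are in voxels (voxel^3 A^3 each).
// [[Rcpp::export]]
List cpp_voxel_profile(NumericMatrix atoms, NumericVector radii, double L,
                       double voxel, double r_max, double bin) {
  const int n = atoms.nrow();
  if (n < 1) stop("no macromolecule atoms");
  const int ng = (int)std::floor(L / voxel + 0.5);
  const int nbin = (int)std::ceil(r_max / bin);
  std::vector<double> V(nbin, 0.0);
  double excluded = 0.0, beyond = 0.0;
  for (int ix = 0; ix < ng; ++ix) {
    Rcpp::checkUserInterrupt();
    double cx = (ix + 0.5) * voxel;
    for (int iy = 0; iy < ng; ++iy) {
      double cy = (iy + 0.5) * voxel;
      for (int iz = 0; iz < ng; ++iz) {
        double cz = (iz + 0.5) * voxel;
        double best = R_PosInf;
        for (int j = 0; j < n; ++j) {
          double dx = mimg(cx - atoms(j, 0), L);
          double dy = mimg(cy - atoms(j, 1), L);
          double dz = mimg(cz - atoms(j, 2), L);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[j];
          if (d < best) best = d;
        }
        if (best < 0.0)
          excluded += 1.0;
        else {
          int b = (int)(best / bin);
          if (b >= nbin) beyond += 1.0; else V[b] += 1.0;
        }
      }
    }
  }
  return List::create(_["V_voxels"] = wrap(V), _["excluded"] = excluded,
                      _["beyond"] = beyond, _["n_grid"] = ng);
}
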