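// Numerical core: grid field construction, trilinear scoring, internal
// strain, and batch RMSD.  Kept free of molecular bookkeeping -- callers pass
// plain coordinate matrices and index vectors.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// V-shaped hydrogen-bond distance well: minimum -2 at the ideal 2.9 A
// donor-acceptor separation, with a shallow capture tail out to 4.3 A so
// gradient descent is pulled toward the designed geometry from afar.  The
// depth is deliberately large relative to the dispersion terms: specific
// designed contacts must out-pull nonspecific wall packing.
static inline double hb_well(double r) {
  if (r <= 2.3 || r >= 4.3) return 0.0;
  if (r < 2.9) return -2.0 * (r - 2.3) / 0.6;
  if (r <= 3.5) return -2.0 * (1.0 - 0.85 * (r - 2.9) / 0.6);
  return -0.3 * (4.3 - r) / 0.8;
}

// Soft-core Lennard-Jones with floored distance and per-pair cap.
static inline double soft_lj(double r, double sigma, double eps, double cap) {
  if (r < 2.2) r = 2.2;
  double s6 = std::pow(sigma / r, 6.0);
  double e = 4.0 * eps * (s6 * s6 - s6);
  return e > cap ? cap : e;
}

// [[Rcpp::export]]
List cpp_build_fields(NumericMatrix rec_xyz, NumericVector rec_sigma,
                      NumericVector rec_eps, NumericVector rec_charge,
                      LogicalVector rec_donor, LogicalVector rec_acceptor,
                      NumericVector origin, double spacing,
                      IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t npt = (R_xlen_t)nx * ny * nz;
  const int na = rec_xyz.nrow();
  NumericVector steric(npt), donor(npt), acceptor(npt), elec(npt), burial(npt);
  const double cutoff2 = sq(8.0);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double gx = origin[0] + i * spacing;
        double gy = origin[1] + j * spacing;
        double gz = origin[2] + k * spacing;
        double s = 0, d = 0, a = 0, e = 0, b = 0;
        for (int t = 0; t < na; ++t) {
          double r2 = sq(gx - rec_xyz(t, 0)) + sq(gy - rec_xyz(t, 1)) +
                      sq(gz - rec_xyz(t, 2));
          if (r2 < sq(6.0)) b += 1.0;
          if (r2 > cutoff2) continue;
          double r = std::sqrt(r2);
          s += soft_lj(r, rec_sigma[t], rec_eps[t], 10.0);
          if (rec_acceptor[t]) d += hb_well(r);
          if (rec_donor[t]) a += hb_well(r);
          double rf = r < 2.0 ? 2.0 : r;
          e += 33.2 * rec_charge[t] / (rf * rf);
        }
        R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        steric[idx] = s; donor[idx] = d; acceptor[idx] = a;
        elec[idx] = e; burial[idx] = b > 20 ? 20 : b;
      }
    }
  }
  return List::create(_["steric"] = steric, _["donor"] = donor,
                      _["acceptor"] = acceptor, _["elec"] = elec,
                      _["burial"] = burial);
}

struct GridView {
  const double *steric, *donor, *acceptor, *elec, *burial;
  double ox, oy, oz, sp;
  int nx, ny, nz;
};

static GridView make_view(const List &fields, const NumericVector &origin,
                          double spacing, const IntegerVector &dims) {
  GridView g;
  g.steric = REAL(((SEXP)fields["steric"]));
  g.donor = REAL(((SEXP)fields["donor"]));
  g.acceptor = REAL(((SEXP)fields["acceptor"]));
  g.elec = REAL(((SEXP)fields["elec"]));
  g.burial = REAL(((SEXP)fields["burial"]));
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.sp = spacing; g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  return g;
}

// Trilinear interpolation of one field; caller guarantees in-box.
static inline double tri(const double *f, const GridView &g, double fx,
                         double fy, double fz, int i0, int j0, int k0) {
  const R_xlen_t NX = g.nx, NXY = (R_xlen_t)g.nx * g.ny;
  R_xlen_t b = i0 + NX * j0 + NXY * k0;
  double c000 = f[b],             c100 = f[b + 1];
  double c010 = f[b + NX],        c110 = f[b + NX + 1];
  double c001 = f[b + NXY],       c101 = f[b + NXY + 1];
  double c011 = f[b + NX + NXY],  c111 = f[b + NX + NXY + 1];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Per-pose raw field sums.  donors/acceptors are 0-based atom indices.
// Returns (steric, hb_donor, hb_acceptor, elec, burial, n_outside).
static void grid_sums(const GridView &g, const double *x, const double *y,
                      const double *z, int n, const int *don, int ndon,
                      const int *acc, int nacc, const double *q, double *out) {
  double s = 0, e = 0, b = 0, hd = 0, ha = 0;
  int nout = 0;
  std::vector<double> sd(n), sa(n);
  for (int t = 0; t < n; ++t) {
    sd[t] = 0; sa[t] = 0;
    double u = (x[t] - g.ox) / g.sp, v = (y[t] - g.oy) / g.sp,
           w = (z[t] - g.oz) / g.sp;
    if (u < 0 || v < 0 || w < 0 || u > g.nx - 1 || v > g.ny - 1 ||
        w > g.nz - 1) {
      ++nout;
      continue;
    }
    int i0 = (int)u, j0 = (int)v, k0 = (int)w;
    if (i0 >= g.nx - 1) i0 = g.nx - 2;
    if (j0 >= g.ny - 1) j0 = g.ny - 2;
    if (k0 >= g.nz - 1) k0 = g.nz - 2;
    double fx = u - i0, fy = v - j0, fz = w - k0;
    s += tri(g.steric, g, fx, fy, fz, i0, j0, k0);
    e += q[t] * tri(g.elec, g, fx, fy, fz, i0, j0, k0);
    b += tri(g.burial, g, fx, fy, fz, i0, j0, k0);
    sd[t] = tri(g.donor, g, fx, fy, fz, i0, j0, k0);
    sa[t] = tri(g.acceptor, g, fx, fy, fz, i0, j0, k0);
  }
  for (int t = 0; t < ndon; ++t) hd += sd[don[t]];
  for (int t = 0; t < nacc; ++t) ha += sa[acc[t]];
  out[0] = s; out[1] = hd; out[2] = ha; out[3] = e; out[4] = b;
  out[5] = nout;
}

// [[Rcpp::export]]
NumericVector cpp_grid_sums(List fields, NumericVector origin, double spacing,
                            IntegerVector dims, NumericMatrix xyz,
                            IntegerVector donors, IntegerVector acceptors,
                            NumericVector charges) {
  GridView g = make_view(fields, origin, spacing, dims);
  int n = xyz.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int t = 0; t < n; ++t) {
    x[t] = xyz(t, 0); y[t] = xyz(t, 1); z[t] = xyz(t, 2);
  }
  NumericVector out(6);
  grid_sums(g, x.data(), y.data(), z.data(), n,
            donors.size() ? INTEGER(donors) : nullptr, donors.size(),
            acceptors.size() ? INTEGER(acceptors) : nullptr, acceptors.size(),
            REAL(charges), REAL(out));
  return out;
}

// Weighted interaction score (no strain) for one conformer over many
// translations.  weights = (w_vdw, w_hb, w_el, w_bur, out_penalty).
// [[Rcpp::export]]
NumericVector cpp_score_translations(List fields, NumericVector origin,
                                     double spacing, IntegerVector dims,
                                     NumericMatrix xyz, NumericMatrix trans,
                                     IntegerVector donors,
                                     IntegerVector acceptors,
                                     NumericVector charges,
                                     NumericVector weights) {
  GridView g = make_view(fields, origin, spacing, dims);
  const int n = xyz.nrow(), nt = trans.nrow();
  NumericVector out(nt);
  std::vector<double> x(n), y(n), z(n);
  double sums[6];
  for (int p = 0; p < nt; ++p) {
    for (int t = 0; t < n; ++t) {
      x[t] = xyz(t, 0) + trans(p, 0);
      y[t] = xyz(t, 1) + trans(p, 1);
      z[t] = xyz(t, 2) + trans(p, 2);
    }
    grid_sums(g, x.data(), y.data(), z.data(), n,
              donors.size() ? INTEGER(donors) : nullptr, donors.size(),
              acceptors.size() ? INTEGER(acceptors) : nullptr,
              acceptors.size(), REAL(charges), sums);
    out[p] = weights[0] * sums[0] + weights[1] * (sums[1] + sums[2]) +
             weights[2] * sums[3] - weights[3] * sums[4] +
             weights[4] * sums[5];
  }
  return out;
}

// Internal strain: harmonic bond restraints plus capped LJ over listed
// nonbonded pairs (graph distance >= 3).  bonds: (i, j, r0) 1-based rows.
// [[Rcpp::export]]
double cpp_internal_strain(NumericMatrix xyz, NumericMatrix bonds,
                           IntegerMatrix pairs) {
  double e = 0;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    double r = std::sqrt(sq(xyz(i, 0) - xyz(j, 0)) +
                         sq(xyz(i, 1) - xyz(j, 1)) +
                         sq(xyz(i, 2) - xyz(j, 2)));
    e += 10.0 * sq(r - bonds(b, 2));
  }
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double r = std::sqrt(sq(xyz(i, 0) - xyz(j, 0)) +
                         sq(xyz(i, 1) - xyz(j, 1)) +
                         sq(xyz(i, 2) - xyz(j, 2)));
    e += soft_lj(r, 3.0, 0.1, 10.0);
  }
  return e;
}

// Plain (no-superposition) RMSD matrix over a list of equally-shaped
// coordinate matrices.
// [[Rcpp::export]]
NumericMatrix cpp_rmsd_matrix(List coord_list) {
  int m = coord_list.size();
  std::vector<NumericMatrix> cs(m);
  for (int i = 0; i < m; ++i) cs[i] = as<NumericMatrix>(coord_list[i]);
  NumericMatrix out(m, m);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double ss = 0;
      int n = cs[i].nrow();
      for (int t = 0; t < n; ++t)
        ss += sq(cs[i](t, 0) - cs[j](t, 0)) + sq(cs[i](t, 1) - cs[j](t, 1)) +
              sq(cs[i](t, 2) - cs[j](t, 2));
      double r = std::sqrt(ss / n);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}

// Minimum pairwise distance between two coordinate sets.
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix a, NumericMatrix b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      double d2 = sq(a(i, 0) - b(j, 0)) + sq(a(i, 1) - b(j, 1)) +
                  sq(a(i, 2) - b(j, 2));
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// Minimum distance over listed index pairs (1-based) within one coord set.
// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix xyz, IntegerMatrix pairs) {
  double best = R_PosInf;
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double d2 = sq(xyz(i, 0) - xyz(j, 0)) + sq(xyz(i, 1) - xyz(j, 1)) +
                sq(xyz(i, 2) - xyz(j, 2));
    if (d2 < best) best = d2;
  }
  return std::sqrt(best);
}

// Greedy deduplication: coord sets are visited in the given (score-sorted)
// order; one is kept when its plain RMSD to every kept set is >= radius.
// Returns 1-based indices of kept sets, at most max_n.
// [[Rcpp::export]]
IntegerVector cpp_greedy_dedup(List coord_list, double radius, int max_n) {
  int m = coord_list.size();
  std::vector<NumericMatrix> kept;
  std::vector<int> kept_idx;
  for (int i = 0; i < m && (int)kept.size() < max_n; ++i) {
    NumericMatrix ci = as<NumericMatrix>(coord_list[i]);
    bool ok = true;
    int n = ci.nrow();
    for (size_t k = 0; k < kept.size(); ++k) {
      double ss = 0;
      for (int t = 0; t < n; ++t)
        ss += sq(ci(t, 0) - kept[k](t, 0)) + sq(ci(t, 1) - kept[k](t, 1)) +
              sq(ci(t, 2) - kept[k](t, 2));
      if (std::sqrt(ss / n) < radius) { ok = false; break; }
    }
    if (ok) { kept.push_back(ci); kept_idx.push_back(i + 1); }
  }
  return wrap(kept_idx);
}

// Pairwise intermolecular energy between two atom sets (e.g. incoming
// fragment vs anchored partial peptide): returns (steric, hbond, elec).
// [[Rcpp::export]]
NumericVector cpp_inter_energy(NumericMatrix xa, NumericVector sig_a,
                               NumericVector qa, LogicalVector don_a,
                               LogicalVector acc_a, NumericMatrix xb,
                               NumericVector sig_b, NumericVector qb,
                               LogicalVector don_b, LogicalVector acc_b) {
  double s = 0, h = 0, e = 0;
  for (int i = 0; i < xa.nrow(); ++i) {
    for (int j = 0; j < xb.nrow(); ++j) {
      double r = std::sqrt(sq(xa(i, 0) - xb(j, 0)) + sq(xa(i, 1) - xb(j, 1)) +
                           sq(xa(i, 2) - xb(j, 2)));
      if (r > 8.0) continue;
      s += soft_lj(r, 0.5 * (sig_a[i] + sig_b[j]), 0.2, 10.0);
      if ((don_a[i] && acc_b[j]) || (acc_a[i] && don_b[j])) h += hb_well(r);
      double rf = r < 2.0 ? 2.0 : r;
      e += 33.2 * qa[i] * qb[j] / (rf * rf);
    }
  }
  return NumericVector::create(s, h, e);
}
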