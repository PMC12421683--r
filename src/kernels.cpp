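#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// shared helpers
// ---------------------------------------------------------------------------

// minimum-image displacement (orthorhombic box); returns squared distance
static inline double mi_d2(const double *a, const double *b, const double *box,
                           double *dv = nullptr) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    d -= box[k] * std::round(d / box[k]);
    if (dv) dv[k] = d;
    s += d * d;
  }
  return s;
}

struct AtomParams {
  const double *x, *y, *z;   // column pointers of an n x 3 matrix
  const double *q, *sig, *eps;
  int n;
  inline void get(int i, double *p) const { p[0] = x[i]; p[1] = y[i]; p[2] = z[i]; }
};

static inline AtomParams make_params(const NumericMatrix &X, const NumericVector &q,
                                     const NumericVector &sig, const NumericVector &eps) {
  AtomParams a;
  a.n = X.nrow();
  a.x = &X(0, 0); a.y = &X(0, 1); a.z = &X(0, 2);
  a.q = q.begin(); a.sig = sig.begin(); a.eps = eps.begin();
  return a;
}

// single atom-pair energy given squared distance; no cutoff applied here.
// strict: error on near-zero separation of interacting atoms (analysis path);
// non-strict returns a huge value so MC proposals are simply rejected.
static inline double atom_pair_e(const AtomParams &A, int i, const AtomParams &B, int j,
                                 double d2, double kcoul, bool strict) {
  double qq = A.q[i] * B.q[j];
  double ee = A.eps[i] * B.eps[j];
  if (d2 < 1e-12) {
    if (strict && (qq != 0.0 || ee > 0.0))
      stop("overlapping atoms (separation < 1e-6 A) between interacting atoms");
    return 1e30;
  }
  double r = std::sqrt(d2);
  double e = kcoul * qq / r;
  if (ee > 0.0) {
    double s = 0.5 * (A.sig[i] + B.sig[j]);
    double sr2 = (s * s) / d2;
    double sr6 = sr2 * sr2 * sr2;
    e += 4.0 * std::sqrt(ee) * (sr6 * sr6 - sr6);
  }
  return e;
}

// energy between two atom groups, per-atom-pair cutoff (solute-water rule)
static double group_pair_e(const AtomParams &A, const int *ia, int na,
                           const AtomParams &B, const int *ib, int nb,
                           const double *box, double cutoff, double kcoul, bool strict) {
  double cut2 = cutoff * cutoff, e = 0.0, pa[3], pb[3];
  for (int u = 0; u < na; ++u) {
    A.get(ia[u], pa);
    for (int v = 0; v < nb; ++v) {
      B.get(ib[v], pb);
      double d2 = mi_d2(pa, pb, box);
      if (d2 <= cut2) e += atom_pair_e(A, ia[u], B, ib[v], d2, kcoul, strict);
    }
  }
  return e;
}

// solute-water energy of one water molecule: each solute atom is included
// against the whole water molecule when its distance to the water OXYGEN is
// within the cutoff. Water molecules are never split at the cutoff sphere
// (splitting a neutral molecule leaves a monopole artifact the sampler
// would exploit).
static double solute_water_e(const AtomParams &A, const int *wrows, int k, int o_row,
                             const int *srows, int ns, const double *box,
                             double cutoff, double kcoul, bool strict) {
  double cut2 = cutoff * cutoff, e = 0.0, po[3], ps[3], pw[3];
  A.get(o_row, po);
  for (int s = 0; s < ns; ++s) {
    A.get(srows[s], ps);
    if (mi_d2(po, ps, box) > cut2) continue;
    for (int u = 0; u < k; ++u) {
      A.get(wrows[u], pw);
      double d2 = mi_d2(pw, ps, box);
      e += atom_pair_e(A, wrows[u], A, srows[s], d2, kcoul, strict);
    }
  }
  return e;
}

// full molecular pair energy (no inner cutoff) between two water molecules
static double water_pair_e(const AtomParams &A, const int *wa, const int *wb, int k,
                           const double *box, double kcoul, bool strict) {
  double e = 0.0, pa[3], pb[3];
  for (int u = 0; u < k; ++u) {
    A.get(wa[u], pa);
    for (int v = 0; v < k; ++v) {
      A.get(wb[v], pb);
      double d2 = mi_d2(pa, pb, box);
      e += atom_pair_e(A, wa[u], A, wb[v], d2, kcoul, strict);
    }
  }
  return e;
}

// ---------------------------------------------------------------------------
// exported kernels
// ---------------------------------------------------------------------------

// generic group-group energy with per-atom-pair cutoff (pair_energy surface)
// [[Rcpp::export]]
double cpp_pair_energy(NumericMatrix Xa, NumericVector qa, NumericVector sa, NumericVector ea,
                       NumericMatrix Xb, NumericVector qb, NumericVector sb, NumericVector eb,
                       NumericVector box, double cutoff, double kcoul, bool strict = true) {
  AtomParams A = make_params(Xa, qa, sa, ea);
  AtomParams B = make_params(Xb, qb, sb, eb);
  std::vector<int> ia(A.n), ib(B.n);
  for (int i = 0; i < A.n; ++i) ia[i] = i;
  for (int i = 0; i < B.n; ++i) ib[i] = i;
  return group_pair_e(A, ia.data(), A.n, B, ib.data(), B.n, box.begin(), cutoff, kcoul, strict);
}

// per-water solute-water and water-water energies for one frame.
// watoms: M x k matrix of 1-based atom rows per water (includes virtual sites);
// o_rows: 1-based oxygen row per water; solute_rows: 1-based solute atom rows.
// Water-water uses a molecule-based cutoff on the O-O minimum-image distance;
// solute-water uses a per-atom-pair cutoff. e_ww has ww_split applied.
// [[Rcpp::export]]
List cpp_frame_water_energies(NumericMatrix X, NumericVector q, NumericVector sig, NumericVector eps,
                              IntegerMatrix watoms, IntegerVector o_rows, IntegerVector solute_rows,
                              NumericVector box, double cutoff, double kcoul, double ww_split,
                              bool strict = true) {
  AtomParams A = make_params(X, q, sig, eps);
  int M = watoms.nrow(), k = watoms.ncol(), ns = solute_rows.size();
  NumericVector e_sw(M), e_ww(M);
  std::vector<int> srows(ns);
  for (int i = 0; i < ns; ++i) srows[i] = solute_rows[i] - 1;
  std::vector< std::vector<int> > wrows(M, std::vector<int>(k));
  for (int w = 0; w < M; ++w)
    for (int j = 0; j < k; ++j) wrows[w][j] = watoms(w, j) - 1;

  if (ns > 0)
    for (int w = 0; w < M; ++w)
      e_sw[w] = solute_water_e(A, wrows[w].data(), k, o_rows[w] - 1,
                               srows.data(), ns, box.begin(), cutoff, kcoul,
                               strict);

  double cut2 = cutoff * cutoff, pa[3], pb[3];
  for (int w = 0; w < M; ++w) {
    A.get(o_rows[w] - 1, pa);
    for (int v = w + 1; v < M; ++v) {
      A.get(o_rows[v] - 1, pb);
      if (mi_d2(pa, pb, box.begin()) <= cut2) {
        double e = water_pair_e(A, wrows[w].data(), wrows[v].data(), k,
                                box.begin(), kcoul, strict);
        e_ww[w] += ww_split * e;
        e_ww[v] += ww_split * e;
      }
    }
  }
  return List::create(_["e_sw"] = e_sw, _["e_ww"] = e_ww);
}

// total nonbonded energy of one frame under the analysis convention
// (unique water pairs, molecule-based cutoff + solute-water, atom-pair cutoff)
// [[Rcpp::export]]
double cpp_frame_total_energy(NumericMatrix X, NumericVector q, NumericVector sig, NumericVector eps,
                              IntegerMatrix watoms, IntegerVector o_rows, IntegerVector solute_rows,
                              NumericVector box, double cutoff, double kcoul, bool strict = true) {
  List pe = cpp_frame_water_energies(X, q, sig, eps, watoms, o_rows, solute_rows,
                                     box, cutoff, kcoul, 0.5, strict);
  NumericVector e_sw = pe["e_sw"], e_ww = pe["e_ww"];
  return sum(e_sw) + sum(e_ww);
}

// geometric hydrogen-bond detection for one frame.
// donor_heavy/donor_h: parallel 1-based rows for every covalent D-H pair;
// acceptors: 1-based rows of acceptor heavy atoms; molid: per-atom molecule id
// (intramolecular pairs are skipped). Returns triples (donor, hydrogen, acceptor).
// convention 0: angle at the donor heavy atom between D->A and D->H  < angle_max
// convention 1: deviation from D-H...A linearity (180 - angle at H) < angle_max
// [[Rcpp::export]]
IntegerMatrix cpp_frame_hbonds(NumericMatrix X, IntegerVector donor_heavy, IntegerVector donor_h,
                               IntegerVector acceptors, IntegerVector molid,
                               NumericVector box, double dist_max, double angle_max_deg,
                               int convention) {
  int nd = donor_heavy.size(), na = acceptors.size();
  double d2max = dist_max * dist_max;
  double cos_min = std::cos(angle_max_deg * M_PI / 180.0); // cos decreasing: angle < max <=> cos > cos_min
  std::vector<int> out;
  const double *bx = box.begin();
  double pd[3], ph[3], pa[3], v_dh[3], v_da[3], v_hd[3], v_ha[3];
  for (int i = 0; i < nd; ++i) {
    int d = donor_heavy[i] - 1, h = donor_h[i] - 1;
    pd[0] = X(d, 0); pd[1] = X(d, 1); pd[2] = X(d, 2);
    ph[0] = X(h, 0); ph[1] = X(h, 1); ph[2] = X(h, 2);
    mi_d2(ph, pd, bx, v_dh);  // D -> H (minimum image)
    for (int j = 0; j < na; ++j) {
      int a = acceptors[j] - 1;
      if (a == d) continue;
      if (molid[a] == molid[d]) continue;
      pa[0] = X(a, 0); pa[1] = X(a, 1); pa[2] = X(a, 2);
      double d2 = mi_d2(pa, pd, bx, v_da);  // D -> A
      if (d2 >= d2max) continue;            // strict: "less than"
      double cosang;
      if (convention == 0) {
        double num = v_dh[0] * v_da[0] + v_dh[1] * v_da[1] + v_dh[2] * v_da[2];
        double nn = std::sqrt((v_dh[0]*v_dh[0]+v_dh[1]*v_dh[1]+v_dh[2]*v_dh[2]) * d2);
        cosang = num / nn;
      } else {
        // angle at H between H->D and H->A; linear bond has angle 180,
        // deviation = 180 - angle; deviation < max <=> cos(angle) < -cos_min... use
        // cos(deviation) = -cos(angle at H)
        mi_d2(pd, ph, bx, v_hd);
        mi_d2(pa, ph, bx, v_ha);
        double num = v_hd[0] * v_ha[0] + v_hd[1] * v_ha[1] + v_hd[2] * v_ha[2];
        double n1 = std::sqrt(v_hd[0]*v_hd[0]+v_hd[1]*v_hd[1]+v_hd[2]*v_hd[2]);
        double n2 = std::sqrt(v_ha[0]*v_ha[0]+v_ha[1]*v_ha[1]+v_ha[2]*v_ha[2]);
        cosang = -num / (n1 * n2);
      }
      if (cosang > cos_min) {
        out.push_back(d + 1); out.push_back(h + 1); out.push_back(a + 1);
      }
    }
  }
  int nb = (int)out.size() / 3;
  IntegerMatrix res(nb, 3);
  for (int i = 0; i < nb; ++i) {
    res(i, 0) = out[3 * i]; res(i, 1) = out[3 * i + 1]; res(i, 2) = out[3 * i + 2];
  }
  return res;
}

// number of water oxygens within `cutoff` (inclusive) of any group atom
// [[Rcpp::export]]
int cpp_frame_neighbors(NumericMatrix X, IntegerVector group_rows, IntegerVector o_rows,
                        NumericVector box, double cutoff) {
  double cut2 = cutoff * cutoff, pg[3], po[3];
  int count = 0;
  for (int w = 0; w < o_rows.size(); ++w) {
    int o = o_rows[w] - 1;
    po[0] = X(o, 0); po[1] = X(o, 1); po[2] = X(o, 2);
    for (int g = 0; g < group_rows.size(); ++g) {
      int gi = group_rows[g] - 1;
      pg[0] = X(gi, 0); pg[1] = X(gi, 1); pg[2] = X(gi, 2);
      if (mi_d2(po, pg, box.begin()) <= cut2) { ++count; break; }
    }
  }
  return count;
}

// per-water count of other water oxygens within cutoff (inclusive)
// [[Rcpp::export]]
IntegerVector cpp_frame_ww_neighbors(NumericMatrix X, IntegerVector o_rows,
                                     NumericVector box, double cutoff) {
  int M = o_rows.size();
  double cut2 = cutoff * cutoff, pa[3], pb[3];
  IntegerVector n(M);
  for (int w = 0; w < M; ++w) {
    int o = o_rows[w] - 1;
    pa[0] = X(o, 0); pa[1] = X(o, 1); pa[2] = X(o, 2);
    for (int v = w + 1; v < M; ++v) {
      int o2 = o_rows[v] - 1;
      pb[0] = X(o2, 0); pb[1] = X(o2, 1); pb[2] = X(o2, 2);
      if (mi_d2(pa, pb, box.begin()) <= cut2) { n[w]++; n[v]++; }
    }
  }
  return n;
}

// ---------------------------------------------------------------------------
// greedy hydration-site clustering
// obs: N x 3 observed oxygen positions (all frames pooled); returns site centers,
// their observation counts, and per-observation site assignment (0 = none).
// A site's sphere has `radius`; accepted centers stay >= min_sep apart; stop when
// the best remaining sphere holds fewer than min_count observations.
// Ties broken by lowest observation index.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_greedy_sites(NumericMatrix obs, NumericVector box, double radius,
                      double min_sep, double min_count) {
  int N = obs.nrow();
  double r2 = radius * radius, sep2 = min_sep * min_sep;
  std::vector<int> count(N, 0);
  std::vector<bool> removed(N, false), eligible(N, true);
  std::vector<int> assign(N, 0);
  double pa[3], pb[3];
  const double *bx = box.begin();

  // initial in-sphere counts (self included)
  for (int i = 0; i < N; ++i) {
    pa[0] = obs(i, 0); pa[1] = obs(i, 1); pa[2] = obs(i, 2);
    count[i] = 1;
    for (int j = i + 1; j < N; ++j) {
      pb[0] = obs(j, 0); pb[1] = obs(j, 1); pb[2] = obs(j, 2);
      if (mi_d2(pa, pb, bx) <= r2) { count[i]++; count[j]++; }
    }
  }

  std::vector<double> cx, cy, cz;
  std::vector<int> ccount;
  for (;;) {
    int best = -1, bestc = -1;
    for (int i = 0; i < N; ++i)
      if (!removed[i] && eligible[i] && count[i] > bestc) { bestc = count[i]; best = i; }
    if (best < 0 || (double)bestc < min_count) break;
    int site_id = (int)cx.size() + 1;
    pa[0] = obs(best, 0); pa[1] = obs(best, 1); pa[2] = obs(best, 2);
    cx.push_back(pa[0]); cy.push_back(pa[1]); cz.push_back(pa[2]);
    // remove members; update counts of remaining candidates
    std::vector<int> members;
    for (int j = 0; j < N; ++j) {
      if (removed[j]) continue;
      pb[0] = obs(j, 0); pb[1] = obs(j, 1); pb[2] = obs(j, 2);
      double d2 = mi_d2(pa, pb, bx);
      if (d2 <= r2) { members.push_back(j); }
      if (d2 <= sep2) eligible[j] = false;  // too close to an accepted center
    }
    ccount.push_back((int)members.size());
    for (size_t m = 0; m < members.size(); ++m) {
      int j = members[m];
      removed[j] = true;
      assign[j] = site_id;
      pb[0] = obs(j, 0); pb[1] = obs(j, 1); pb[2] = obs(j, 2);
      for (int i = 0; i < N; ++i) {
        if (removed[i]) continue;
        pa[0] = obs(i, 0); pa[1] = obs(i, 1); pa[2] = obs(i, 2);
        if (mi_d2(pa, pb, bx) <= r2) count[i]--;
      }
    }
  }
  int S = (int)cx.size();
  NumericMatrix centers(S, 3);
  IntegerVector counts(S);
  for (int s = 0; s < S; ++s) {
    centers(s, 0) = cx[s]; centers(s, 1) = cy[s]; centers(s, 2) = cz[s];
    counts[s] = ccount[s];
  }
  return List::create(_["centers"] = centers, _["counts"] = counts,
                      _["assignment"] = IntegerVector(assign.begin(), assign.end()));
}

// ---------------------------------------------------------------------------
// marching tetrahedra: area of the iso-surface of a scalar field sampled at
// voxel centers on a regular grid with uniform spacing.
// ---------------------------------------------------------------------------
static inline double tri_area(const double *a, const double *b, const double *c) {
  double u[3], v[3];
  for (int k = 0; k < 3; ++k) { u[k] = b[k] - a[k]; v[k] = c[k] - a[k]; }
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static inline void edge_point(const double *pa, double fa, const double *pb, double fb,
                              double iso, double *out) {
  double t = (iso - fa) / (fb - fa);
  for (int k = 0; k < 3; ++k) out[k] = pa[k] + t * (pb[k] - pa[k]);
}

// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dims, double iso,
                           double spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *F = field.begin();
  // cube corner offsets (x, y, z)
  static const int corner[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                                   {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0;
  double P[8][3], fv[8];
  for (int i = 0; i + 1 < nx; ++i)
    for (int j = 0; j + 1 < ny; ++j)
      for (int k = 0; k + 1 < nz; ++k) {
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner[c][0], jj = j + corner[c][1], kk = k + corner[c][2];
          fv[c] = F[ii + nx * (jj + (size_t)ny * kk)];
          P[c][0] = ii * spacing; P[c][1] = jj * spacing; P[c][2] = kk * spacing;
        }
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int below[4], above[4], nb = 0, na = 0;
          for (int v = 0; v < 4; ++v) {
            if (fv[tv[v]] < iso) below[nb++] = tv[v]; else above[na++] = tv[v];
          }
          if (nb == 0 || nb == 4) continue;
          double q[4][3];
          if (nb == 1 || nb == 3) {
            int solo = (nb == 1) ? below[0] : above[0];
            const int *rest = (nb == 1) ? above : below;
            for (int v = 0; v < 3; ++v)
              edge_point(P[solo], fv[solo], P[rest[v]], fv[rest[v]], iso, q[v]);
            area += tri_area(q[0], q[1], q[2]);
          } else {
            // 2-2 split: quad b0a0, b0a1, b1a1, b1a0
            edge_point(P[below[0]], fv[below[0]], P[above[0]], fv[above[0]], iso, q[0]);
            edge_point(P[below[0]], fv[below[0]], P[above[1]], fv[above[1]], iso, q[1]);
            edge_point(P[below[1]], fv[below[1]], P[above[1]], fv[above[1]], iso, q[2]);
            edge_point(P[below[1]], fv[below[1]], P[above[0]], fv[above[0]], iso, q[3]);
            area += tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Metropolis Monte Carlo over rigid-water translations/rotations, with an
// optional two-state solute group swap move. Uses R's RNG (seed via set.seed).
// The move energies use the exact analysis convention (molecule-based water-
// water cutoff, per-atom-pair solute-water cutoff), so saved-frame energies
// re-evaluated by the analysis kernels agree exactly.
// ---------------------------------------------------------------------------

struct MCSystem {
  NumericMatrix X;                 // working coordinates (atoms x 3)
  std::vector<double> q, sig, eps;
  std::vector< std::vector<int> > wrows;  // per water: 0-based atom rows
  std::vector<int> o_rows;         // 0-based oxygen row per water
  std::vector<int> srows;          // 0-based solute rows
  double box[3], cutoff, kcoul;
  AtomParams A;

  void refresh() { A = make_params(X, wrap_q, wrap_s, wrap_e); }
  NumericVector wrap_q, wrap_s, wrap_e;
};

static double mc_water_env_energy(MCSystem &S, int w) {
  // energy of water w with all other waters + solute (non-strict)
  int k = (int)S.wrows[w].size();
  double e = 0.0, pa[3], pb[3];
  double cut2 = S.cutoff * S.cutoff;
  S.A.get(S.o_rows[w], pa);
  for (size_t v = 0; v < S.wrows.size(); ++v) {
    if ((int)v == w) continue;
    S.A.get(S.o_rows[v], pb);
    if (mi_d2(pa, pb, S.box) <= cut2)
      e += water_pair_e(S.A, S.wrows[w].data(), S.wrows[v].data(), k, S.box, S.kcoul, false);
  }
  if (!S.srows.empty())
    e += solute_water_e(S.A, S.wrows[w].data(), k, S.o_rows[w],
                        S.srows.data(), (int)S.srows.size(),
                        S.box, S.cutoff, S.kcoul, false);
  return e;
}

static double mc_group_env_energy(MCSystem &S, const std::vector<int> &grows) {
  // energy of a solute subgroup with all waters and the rest of the solute
  // (atom-pair cutoff everywhere; within-group pairs excluded)
  std::vector<bool> ing(S.X.nrow(), false);
  for (size_t i = 0; i < grows.size(); ++i) ing[grows[i]] = true;
  double e = 0.0;
  for (size_t v = 0; v < S.wrows.size(); ++v)
    e += solute_water_e(S.A, S.wrows[v].data(), (int)S.wrows[v].size(),
                        S.o_rows[v], grows.data(), (int)grows.size(),
                        S.box, S.cutoff, S.kcoul, false);
  std::vector<int> other;
  for (size_t i = 0; i < S.srows.size(); ++i)
    if (!ing[S.srows[i]]) other.push_back(S.srows[i]);
  if (!other.empty())
    e += group_pair_e(S.A, grows.data(), (int)grows.size(),
                      S.A, other.data(), (int)other.size(),
                      S.box, S.cutoff, S.kcoul, false);
  return e;
}

static void random_rotation(double ang_max, double R[3][3]) {
  // uniform random axis (Marsaglia), angle uniform in [-ang_max, ang_max]
  double x1, x2, s;
  do { x1 = 2.0 * unif_rand() - 1.0; x2 = 2.0 * unif_rand() - 1.0; s = x1 * x1 + x2 * x2; }
  while (s >= 1.0);
  double ux = 2.0 * x1 * std::sqrt(1.0 - s);
  double uy = 2.0 * x2 * std::sqrt(1.0 - s);
  double uz = 1.0 - 2.0 * s;
  double th = ang_max * (2.0 * unif_rand() - 1.0);
  double c = std::cos(th), si = std::sin(th), C = 1.0 - c;
  R[0][0] = c + ux * ux * C;      R[0][1] = ux * uy * C - uz * si; R[0][2] = ux * uz * C + uy * si;
  R[1][0] = uy * ux * C + uz * si; R[1][1] = c + uy * uy * C;      R[1][2] = uy * uz * C - ux * si;
  R[2][0] = uz * ux * C - uy * si; R[2][1] = uz * uy * C + ux * si; R[2][2] = c + uz * uz * C;
}

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix X0, NumericVector q, NumericVector sig, NumericVector eps,
                IntegerMatrix watoms, IntegerVector o_rows, IntegerVector solute_rows,
                NumericVector box, double cutoff, double kcoul,
                double temperature, int n_burnin, int n_frames, int sweeps_per_frame,
                double trans_step, double rot_step_deg,
                IntegerVector flex_rows, NumericMatrix flex_alt,
                double swap_attempts_per_sweep) {
  MCSystem S;
  S.X = clone(X0);
  S.wrap_q = q; S.wrap_s = sig; S.wrap_e = eps;
  S.refresh();
  int M = watoms.nrow(), k = watoms.ncol();
  S.wrows.assign(M, std::vector<int>(k));
  for (int w = 0; w < M; ++w)
    for (int j = 0; j < k; ++j) S.wrows[w][j] = watoms(w, j) - 1;
  S.o_rows.resize(M);
  for (int w = 0; w < M; ++w) S.o_rows[w] = o_rows[w] - 1;
  S.srows.resize(solute_rows.size());
  for (int i = 0; i < solute_rows.size(); ++i) S.srows[i] = solute_rows[i] - 1;
  for (int kk = 0; kk < 3; ++kk) S.box[kk] = box[kk];
  S.cutoff = cutoff; S.kcoul = kcoul;

  double beta = R_finite(temperature) ? 1.0 / (0.0019872041 * temperature) : 0.0;
  double rot_max = rot_step_deg * M_PI / 180.0;

  bool two_state = flex_rows.size() > 0;
  std::vector<int> grows(flex_rows.size());
  for (int i = 0; i < flex_rows.size(); ++i) grows[i] = flex_rows[i] - 1;
  // cognate coordinates of the flexible group (state 0); flex_alt is state 1
  NumericMatrix cognate(flex_rows.size(), 3);
  for (int i = 0; i < flex_rows.size(); ++i)
    for (int kk = 0; kk < 3; ++kk) cognate(i, kk) = S.X(grows[i], kk);
  int state = 0;

  int total_sweeps = n_burnin + n_frames * sweeps_per_frame;
  long n_try = 0, n_acc = 0, n_swap_try = 0, n_swap_acc = 0;
  NumericVector out((R_xlen_t)X0.nrow() * 3 * n_frames);
  IntegerVector out_state(n_frames);
  NumericVector out_energy(n_frames);
  int natoms = X0.nrow();
  int saved = 0;

  double oldpos_buf[16 * 3];  // waters have few atoms
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int mv = 0; mv < M; ++mv) {
      int w = (int)(unif_rand() * M); if (w >= M) w = M - 1;
      double e_old = mc_water_env_energy(S, w);
      // save coords
      for (int j = 0; j < k; ++j)
        for (int kk = 0; kk < 3; ++kk) oldpos_buf[3 * j + kk] = S.X(S.wrows[w][j], kk);
      // translate + rotate about oxygen
      double dx[3];
      for (int kk = 0; kk < 3; ++kk) dx[kk] = trans_step * (2.0 * unif_rand() - 1.0);
      double R[3][3];
      random_rotation(rot_max, R);
      double oc[3] = {S.X(S.o_rows[w], 0), S.X(S.o_rows[w], 1), S.X(S.o_rows[w], 2)};
      for (int j = 0; j < k; ++j) {
        int row = S.wrows[w][j];
        double rel[3], rot[3];
        for (int kk = 0; kk < 3; ++kk) rel[kk] = S.X(row, kk) - oc[kk];
        for (int kk = 0; kk < 3; ++kk)
          rot[kk] = R[kk][0] * rel[0] + R[kk][1] * rel[1] + R[kk][2] * rel[2];
        for (int kk = 0; kk < 3; ++kk) S.X(row, kk) = oc[kk] + rot[kk] + dx[kk];
      }
      // wrap oxygen into the box, shifting the whole molecule
      for (int kk = 0; kk < 3; ++kk) {
        double o = S.X(S.o_rows[w], kk);
        double shift = std::floor(o / S.box[kk]) * S.box[kk];
        if (shift != 0.0)
          for (int j = 0; j < k; ++j) S.X(S.wrows[w][j], kk) -= shift;
      }
      double e_new = mc_water_env_energy(S, w);
      double dE = e_new - e_old;
      ++n_try;
      bool accept = (beta == 0.0) || (dE <= 0.0) || (unif_rand() < std::exp(-beta * dE));
      if (accept) { ++n_acc; }
      else {
        for (int j = 0; j < k; ++j)
          for (int kk = 0; kk < 3; ++kk) S.X(S.wrows[w][j], kk) = oldpos_buf[3 * j + kk];
      }
    }
    if (two_state) {
      double attempts = swap_attempts_per_sweep;
      while (attempts > 0) {
        if (attempts < 1.0 && unif_rand() >= attempts) break;
        attempts -= 1.0;
        double e_old = mc_group_env_energy(S, grows);
        const NumericMatrix &target = (state == 0) ? flex_alt : cognate;
        std::vector<double> saveg(grows.size() * 3);
        for (size_t i = 0; i < grows.size(); ++i)
          for (int kk = 0; kk < 3; ++kk) {
            saveg[3 * i + kk] = S.X(grows[i], kk);
            S.X(grows[i], kk) = target(i, kk);
          }
        double e_new = mc_group_env_energy(S, grows);
        double dE = e_new - e_old;
        ++n_swap_try;
        bool accept = (beta == 0.0) || (dE <= 0.0) || (unif_rand() < std::exp(-beta * dE));
        if (accept) { state = 1 - state; ++n_swap_acc; }
        else {
          for (size_t i = 0; i < grows.size(); ++i)
            for (int kk = 0; kk < 3; ++kk) S.X(grows[i], kk) = saveg[3 * i + kk];
        }
      }
    }
    if (sweep >= n_burnin && ((sweep - n_burnin + 1) % sweeps_per_frame == 0)) {
      for (int i = 0; i < natoms; ++i)
        for (int kk = 0; kk < 3; ++kk)
          out[i + (R_xlen_t)natoms * (kk + 3 * (R_xlen_t)saved)] = S.X(i, kk);
      out_state[saved] = state;
      // full-system energy under the analysis convention
      double etot = 0.0;
      for (int w = 0; w < M; ++w) etot += 0.5 * mc_water_env_energy(S, w);
      if (!S.srows.empty()) {
        // the 0.5 halves solute-water too; add the other half back
        double esw = 0.0;
        for (int w = 0; w < M; ++w)
          esw += solute_water_e(S.A, S.wrows[w].data(), k, S.o_rows[w],
                                S.srows.data(), (int)S.srows.size(),
                                S.box, S.cutoff, S.kcoul, false);
        etot += 0.5 * esw;
      }
      out_energy[saved] = etot;
      ++saved;
    }
  }
  out.attr("dim") = IntegerVector::create(natoms, 3, n_frames);
  return List::create(_["coords"] = out, _["state"] = out_state, _["energy"] = out_energy,
                      _["acceptance"] = (n_try > 0) ? (double)n_acc / n_try : NA_REAL,
                      _["swap_acceptance"] = (n_swap_try > 0) ? (double)n_swap_acc / n_swap_try : NA_REAL);
}
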