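// Built-in docking engine internals: empirical contact score and
// derivative-free local refinement (cyclic coordinate descent over rigid-body
// and active-torsion coordinates with step halving).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Contact score: for every receptor/ligand heavy-atom pair within 8 A,
// with s = d - (r_i + r_j), add -0.05 * exp(-(s/0.5)^2) plus a quadratic
// wall 0.8 * s^2 when s < 0. Ligand-internal nonbonded pairs (graph distance
// >= 3) are penalised by 0.8 * s^2 when s < -0.5. Lower is better.
// Flat (column) copy of the receptor coordinates plus radii, so the inner
// scoring loops run on contiguous arrays.
struct RecView {
  std::vector<double> x, y, z, r;
  int nr;
  RecView(const NumericMatrix& rec, const NumericVector& rec_rad)
      : x(rec.nrow()), y(rec.nrow()), z(rec.nrow()),
        r(rec_rad.begin(), rec_rad.end()), nr(rec.nrow()) {
    for (int j = 0; j < nr; ++j) {
      x[j] = rec(j, 0); y[j] = rec(j, 1); z[j] = rec(j, 2);
    }
  }
};

// Receptor-contact contribution of one ligand heavy atom.
static double atom_rec_score(double xi, double yi, double zi, double ri,
                             const RecView& rv) {
  double total = 0.0;
  for (int j = 0; j < rv.nr; ++j) {
    const double dx = xi - rv.x[j];
    const double dy = yi - rv.y[j];
    const double dz = zi - rv.z[j];
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > 64.0) continue;
    // beyond s = 3 the well term is < 2e-16 of its depth: skip it
    const double cut = ri + rv.r[j] + 3.0;
    if (d2 > cut * cut) continue;
    const double d = std::sqrt(d2);
    const double s = d - (ri + rv.r[j]);
    const double u = s / 0.5;
    total += -0.05 * std::exp(-u * u);
    if (s < 0.0) total += 0.8 * s * s;
  }
  return total;
}

// Internal-pair contribution (graph distance >= 3 heavy pairs).
static double pair_int_score(const double* xyz, int n_atoms, int i, int j,
                             double rsum) {
  const double dx = xyz[i] - xyz[j];
  const double dy = xyz[i + n_atoms] - xyz[j + n_atoms];
  const double dz = xyz[i + 2 * n_atoms] - xyz[j + 2 * n_atoms];
  const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  const double s = d - rsum;
  return s < -0.5 ? 0.8 * s * s : 0.0;
}

static double contact_score(const double* xyz, int n_atoms,
                            const std::vector<int>& heavy,
                            const std::vector<double>& lig_rad,
                            const RecView& rv,
                            const std::vector<int>& pi,
                            const std::vector<int>& pj,
                            const std::vector<double>& prsum) {
  const int nh = (int)heavy.size();
  double total = 0.0;
  for (int a = 0; a < nh; ++a) {
    const int i = heavy[a];
    total += atom_rec_score(xyz[i], xyz[i + n_atoms], xyz[i + 2 * n_atoms],
                            lig_rad[a], rv);
  }
  const int np = (int)pi.size();
  for (int p = 0; p < np; ++p)
    total += pair_int_score(xyz, n_atoms, pi[p], pj[p], prsum[p]);
  return total;
}

static std::vector<int> to0(const IntegerVector& v) {
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;
  return out;
}

// [[Rcpp::export]]
double cpp_score(NumericMatrix xyz, IntegerVector heavy_idx,
                 NumericVector lig_rad, NumericMatrix rec_xyz,
                 NumericVector rec_rad, IntegerVector pair_i,
                 IntegerVector pair_j, NumericVector pair_rsum) {
  std::vector<int> heavy = to0(heavy_idx);
  std::vector<double> lr(lig_rad.begin(), lig_rad.end());
  std::vector<int> pi = to0(pair_i), pj = to0(pair_j);
  std::vector<double> pr(pair_rsum.begin(), pair_rsum.end());
  RecView rv(rec_xyz, rec_rad);
  return contact_score(REAL(xyz), xyz.nrow(), heavy, lr, rv, pi, pj, pr);
}

// Smallest s = d - (r_i + r_j) over all receptor/ligand heavy pairs; used for
// the clash-rejection step of conformation randomization.
// [[Rcpp::export]]
double cpp_min_s(NumericMatrix xyz, IntegerVector heavy_idx,
                 NumericVector lig_rad, NumericMatrix rec_xyz,
                 NumericVector rec_rad) {
  std::vector<int> heavy = to0(heavy_idx);
  const int n = xyz.nrow(), nr = rec_xyz.nrow();
  const double* p = REAL(xyz);
  double best = R_PosInf;
  for (size_t a = 0; a < heavy.size(); ++a) {
    const int i = heavy[a];
    for (int j = 0; j < nr; ++j) {
      const double dx = p[i] - rec_xyz(j, 0);
      const double dy = p[i + n] - rec_xyz(j, 1);
      const double dz = p[i + 2 * n] - rec_xyz(j, 2);
      const double s = std::sqrt(dx * dx + dy * dy + dz * dz) -
                       (lig_rad[a] + rec_rad[j]);
      if (s < best) best = s;
    }
  }
  return best;
}

static void rotate_subset(const std::vector<double>& src, std::vector<double>& dst,
                          int n, const std::vector<int>& rows,
                          const double* origin, const double* axis, double theta);

// True when any receptor/ligand heavy pair has gap s < threshold; early
// exit on the first violation, squared distances (no sqrt needed).
static bool any_gap_below(const std::vector<double>& xyz, int n,
                          const std::vector<int>& heavy,
                          const std::vector<double>& lig_rad,
                          const RecView& rv, double threshold) {
  for (size_t a = 0; a < heavy.size(); ++a) {
    const int i = heavy[a];
    const double xi = xyz[i], yi = xyz[i + n], zi = xyz[i + 2 * n];
    for (int j = 0; j < rv.nr; ++j) {
      const double lim = lig_rad[a] + rv.r[j] + threshold;
      if (lim <= 0.0) continue;
      const double dx = xi - rv.x[j];
      const double dy = yi - rv.y[j];
      const double dz = zi - rv.z[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) return true;
    }
  }
  return false;
}

// Random conformation draw: uniform active torsions, uniform rigid-body
// orientation (Gaussian quaternion), translation uniform over in-box
// placements, rejecting placements with any pair gap below -1 A. Returns a
// 0 x 3 matrix when no placement is found within max_tries. Consumes the
// R RNG stream.
// [[Rcpp::export]]
NumericMatrix cpp_randomize(NumericMatrix xyz0, IntegerVector heavy_idx,
                            NumericVector lig_rad, NumericMatrix rec_xyz,
                            NumericVector rec_rad, List torsions,
                            NumericVector box_lo, NumericVector box_hi,
                            int max_tries = 100) {
  RNGScope scope;
  const int n = xyz0.nrow();
  std::vector<int> heavy = to0(heavy_idx);
  std::vector<double> lr(lig_rad.begin(), lig_rad.end());
  RecView rv(rec_xyz, rec_rad);
  const int nt = torsions.size();
  std::vector<int> tor_a(nt), tor_b(nt);
  std::vector<std::vector<int> > tor_rows(nt);
  for (int t = 0; t < nt; ++t) {
    List tt = torsions[t];
    tor_a[t] = as<int>(tt["anchor"]) - 1;
    tor_b[t] = as<int>(tt["pivot"]) - 1;
    tor_rows[t] = to0(as<IntegerVector>(tt["move"]));
  }
  std::vector<double> base(REAL(xyz0), REAL(xyz0) + 3 * n), cur(3 * n),
      tmp(3 * n);
  for (int trial = 0; trial < max_tries; ++trial) {
    cur = base;
    for (int t = 0; t < nt; ++t) {
      const double theta = R::runif(-M_PI, M_PI);
      double org[3] = {cur[tor_a[t]], cur[tor_a[t] + n], cur[tor_a[t] + 2 * n]};
      double axis[3] = {cur[tor_b[t]] - org[0], cur[tor_b[t] + n] - org[1],
                        cur[tor_b[t] + 2 * n] - org[2]};
      const double nrm = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                                   axis[2] * axis[2]);
      if (nrm < 1e-9) continue;
      axis[0] /= nrm; axis[1] /= nrm; axis[2] /= nrm;
      rotate_subset(cur, tmp, n, tor_rows[t], org, axis, theta);
      cur.swap(tmp);
    }
    double q[4];
    for (int k = 0; k < 4; ++k) q[k] = norm_rand();
    const double qn = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] +
                                q[3] * q[3]);
    const double w = q[0] / qn, x = q[1] / qn, y = q[2] / qn, z = q[3] / qn;
    double R9[9] = {1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
                    2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
                    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)};
    double ctr[3] = {0, 0, 0};
    for (size_t a = 0; a < heavy.size(); ++a) {
      ctr[0] += cur[heavy[a]];
      ctr[1] += cur[heavy[a] + n];
      ctr[2] += cur[heavy[a] + 2 * n];
    }
    const double nh = (double)heavy.size();
    ctr[0] /= nh; ctr[1] /= nh; ctr[2] /= nh;
    for (int i = 0; i < n; ++i) {
      const double px = cur[i] - ctr[0];
      const double py = cur[i + n] - ctr[1];
      const double pz = cur[i + 2 * n] - ctr[2];
      tmp[i]         = R9[0] * px + R9[1] * py + R9[2] * pz + ctr[0];
      tmp[i + n]     = R9[3] * px + R9[4] * py + R9[5] * pz + ctr[1];
      tmp[i + 2 * n] = R9[6] * px + R9[7] * py + R9[8] * pz + ctr[2];
    }
    cur.swap(tmp);
    for (int ax = 0; ax < 3; ++ax) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int i = 0; i < n; ++i) {
        const double v = cur[i + ax * n];
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      const double t_lo = box_lo[ax] - mn, t_hi = box_hi[ax] - mx;
      const double u = unif_rand();
      const double shift = t_lo <= t_hi
          ? t_lo + u * (t_hi - t_lo)
          : (box_lo[ax] + box_hi[ax]) / 2.0 - (mn + mx) / 2.0;
      for (int i = 0; i < n; ++i) cur[i + ax * n] += shift;
    }
    if (!any_gap_below(cur, n, heavy, lr, rv, -1.0)) {
      NumericMatrix out(n, 3);
      std::copy(cur.begin(), cur.end(), REAL(out));
      return out;
    }
  }
  return NumericMatrix(0, 3);
}

struct MoveBuffer {
  std::vector<double> cur, trial;
  int n;
  MoveBuffer(const NumericMatrix& xyz) : cur(REAL(xyz), REAL(xyz) + 3 * xyz.nrow()),
                                         trial(3 * xyz.nrow()), n(xyz.nrow()) {}
};

static void translate(const std::vector<double>& src, std::vector<double>& dst,
                      int n, int axis, double step) {
  dst = src;
  double* d = dst.data() + axis * n;
  for (int i = 0; i < n; ++i) d[i] += step;
}

static void rotmat(const double* u, double theta, double R[9]) {
  const double ct = std::cos(theta), st = std::sin(theta), vt = 1 - ct;
  const double x = u[0], y = u[1], z = u[2];
  R[0] = ct + x * x * vt; R[1] = x * y * vt - z * st; R[2] = x * z * vt + y * st;
  R[3] = y * x * vt + z * st; R[4] = ct + y * y * vt; R[5] = y * z * vt - x * st;
  R[6] = z * x * vt - y * st; R[7] = z * y * vt + x * st; R[8] = ct + z * z * vt;
}

static void rotate_subset(const std::vector<double>& src, std::vector<double>& dst,
                          int n, const std::vector<int>& rows,
                          const double* origin, const double* axis, double theta) {
  dst = src;
  double R[9];
  rotmat(axis, theta, R);
  for (size_t k = 0; k < rows.size(); ++k) {
    const int i = rows[k];
    const double px = src[i] - origin[0];
    const double py = src[i + n] - origin[1];
    const double pz = src[i + 2 * n] - origin[2];
    dst[i]         = R[0] * px + R[1] * py + R[2] * pz + origin[0];
    dst[i + n]     = R[3] * px + R[4] * py + R[5] * pz + origin[1];
    dst[i + 2 * n] = R[6] * px + R[7] * py + R[8] * pz + origin[2];
  }
}

// [[Rcpp::export]]
List cpp_refine(NumericMatrix xyz, IntegerVector heavy_idx, NumericVector lig_rad,
                NumericMatrix rec_xyz, NumericVector rec_rad,
                IntegerVector pair_i, IntegerVector pair_j, NumericVector pair_rsum,
                List torsions, NumericVector box_lo, NumericVector box_hi,
                double trans_step0 = 2.0, double rot_step0_deg = 30.0,
                double trans_min = 0.01, double rot_min_deg = 0.25,
                double conv = 1e-4, int max_passes = 12) {
  const int n = xyz.nrow();
  std::vector<int> heavy = to0(heavy_idx);
  std::vector<double> lr(lig_rad.begin(), lig_rad.end());
  std::vector<int> pi = to0(pair_i), pj = to0(pair_j);
  std::vector<double> pr(pair_rsum.begin(), pair_rsum.end());

  const int nt = torsions.size();
  std::vector<int> tor_a(nt), tor_b(nt);
  std::vector<std::vector<int> > tor_rows(nt);
  for (int t = 0; t < nt; ++t) {
    List tt = torsions[t];
    tor_a[t] = as<int>(tt["anchor"]) - 1;
    tor_b[t] = as<int>(tt["pivot"]) - 1;
    tor_rows[t] = to0(as<IntegerVector>(tt["move"]));
  }

  MoveBuffer buf(xyz);
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;

  RecView rv(rec_xyz, rec_rad);
  const int nh = (int)heavy.size();
  const int np = (int)pi.size();
  // Per-torsion move bookkeeping for partial rescoring: the heavy atoms
  // that move, and the internal pairs whose distance can change (exactly
  // one endpoint in the moved set; a rigid rotation leaves same-side pairs
  // unchanged). Rigid-body moves change no internal distance at all.
  std::vector<std::vector<int> > tor_heavy(nt), tor_pairs(nt);
  for (int t = 0; t < nt; ++t) {
    std::vector<char> in_move(n, 0);
    for (size_t k = 0; k < tor_rows[t].size(); ++k) in_move[tor_rows[t][k]] = 1;
    for (int a = 0; a < nh; ++a)
      if (in_move[heavy[a]]) tor_heavy[t].push_back(a);
    for (int p = 0; p < np; ++p)
      if (in_move[pi[p]] != in_move[pj[p]]) tor_pairs[t].push_back(p);
  }
  std::vector<int> all_heavy(nh);
  for (int a = 0; a < nh; ++a) all_heavy[a] = a;

  // cached score decomposition for the current conformation
  std::vector<double> rec_part(nh), int_part(np);
  double score = 0.0;
  for (int a = 0; a < nh; ++a) {
    const int i = heavy[a];
    rec_part[a] = atom_rec_score(buf.cur[i], buf.cur[i + n],
                                 buf.cur[i + 2 * n], lr[a], rv);
    score += rec_part[a];
  }
  for (int p = 0; p < np; ++p) {
    int_part[p] = pair_int_score(buf.cur.data(), n, pi[p], pj[p], pr[p]);
    score += int_part[p];
  }
  std::vector<double> new_rec(nh), new_int(np);
  long n_eval = 1;
  double trans_step = trans_step0;
  double rot_step = rot_step0_deg * M_PI / 180.0;
  const double rot_min = rot_min_deg * M_PI / 180.0;
  const int n_coord = 6 + nt;

  bool has_box = box_lo.size() == 3;
  // lambda-free trial application
  for (;;) {
    bool level_improved = false;
    for (int pass = 0; pass < max_passes; ++pass) {
      double pass_start = score;
      for (int c = 0; c < n_coord; ++c) {
        for (int dir = 0; dir < 2; ++dir) {
          const double sgn = dir == 0 ? 1.0 : -1.0;
          for (;;) {  // keep stepping while improving
            if (c < 3) {
              translate(buf.cur, buf.trial, n, c, sgn * trans_step);
              if (has_box) {
                // keep the heavy-atom centroid inside the docking box
                double cx = 0, cy = 0, cz = 0;
                for (size_t a = 0; a < heavy.size(); ++a) {
                  cx += buf.trial[heavy[a]];
                  cy += buf.trial[heavy[a] + n];
                  cz += buf.trial[heavy[a] + 2 * n];
                }
                const double nh = (double)heavy.size();
                cx /= nh; cy /= nh; cz /= nh;
                if (cx < box_lo[0] || cx > box_hi[0] || cy < box_lo[1] ||
                    cy > box_hi[1] || cz < box_lo[2] || cz > box_hi[2]) break;
              }
            } else if (c < 6) {
              double org[3] = {0, 0, 0};
              for (size_t a = 0; a < heavy.size(); ++a) {
                org[0] += buf.cur[heavy[a]];
                org[1] += buf.cur[heavy[a] + n];
                org[2] += buf.cur[heavy[a] + 2 * n];
              }
              const double nh = (double)heavy.size();
              org[0] /= nh; org[1] /= nh; org[2] /= nh;
              double axis[3] = {0, 0, 0};
              axis[c - 3] = 1.0;
              rotate_subset(buf.cur, buf.trial, n, all_rows, org, axis,
                            sgn * rot_step);
            } else {
              const int t = c - 6;
              double org[3] = {buf.cur[tor_a[t]], buf.cur[tor_a[t] + n],
                               buf.cur[tor_a[t] + 2 * n]};
              double axis[3] = {buf.cur[tor_b[t]] - org[0],
                                buf.cur[tor_b[t] + n] - org[1],
                                buf.cur[tor_b[t] + 2 * n] - org[2]};
              const double nrm = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                                           axis[2] * axis[2]);
              if (nrm < 1e-9) break;
              axis[0] /= nrm; axis[1] /= nrm; axis[2] /= nrm;
              rotate_subset(buf.cur, buf.trial, n, tor_rows[t], org, axis,
                            sgn * rot_step);
            }
            // partial rescoring: only moved atoms / crossing pairs change
            const std::vector<int>& mh = c < 6 ? all_heavy : tor_heavy[c - 6];
            const std::vector<int>* mp = c < 6 ? 0 : &tor_pairs[c - 6];
            double trial_score = score;
            for (size_t k = 0; k < mh.size(); ++k) {
              const int a = mh[k];
              const int i = heavy[a];
              new_rec[k] = atom_rec_score(buf.trial[i], buf.trial[i + n],
                                          buf.trial[i + 2 * n], lr[a], rv);
              trial_score += new_rec[k] - rec_part[a];
            }
            if (mp) {
              for (size_t k = 0; k < mp->size(); ++k) {
                const int p = (*mp)[k];
                new_int[k] = pair_int_score(buf.trial.data(), n,
                                            pi[p], pj[p], pr[p]);
                trial_score += new_int[k] - int_part[p];
              }
            }
            ++n_eval;
            if (trial_score < score - 1e-12) {
              for (size_t k = 0; k < mh.size(); ++k) rec_part[mh[k]] = new_rec[k];
              if (mp)
                for (size_t k = 0; k < mp->size(); ++k)
                  int_part[(*mp)[k]] = new_int[k];
              buf.cur.swap(buf.trial);
              score = trial_score;
            } else break;
          }
        }
      }
      if (pass_start - score > conv) level_improved = true;
      if (pass_start - score <= conv) break;
    }
    if (trans_step <= trans_min && rot_step <= rot_min) {
      if (!level_improved) break;
      // converged at the finest step: one more sweep already done, stop
      break;
    }
    trans_step = std::max(trans_step / 2.0, trans_min);
    rot_step = std::max(rot_step / 2.0, rot_min);
  }

  NumericMatrix out(n, 3);
  std::copy(buf.cur.begin(), buf.cur.end(), REAL(out));
  return List::create(_["coords"] = out, _["score"] = score,
                      _["n_eval"] = (double)n_eval);
}
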