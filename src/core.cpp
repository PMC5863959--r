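#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Boundary codes per axis: 0 = open, 1 = wall (clamp at the 0-plane), 2 = periodic.

static inline double min_image(double d, double L, int bdry) {
  if (bdry == 2) d -= L * std::nearbyint(d / L);
  return d;
}

static inline long long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

// Separation vector from agent j to agent i under minimum image, and its norm.
static inline double sep_vec(const NumericMatrix &pos, int i, int j,
                             const NumericVector &L, const IntegerVector &bdry,
                             double out[3]) {
  double d2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    double d = min_image(pos(i, a) - pos(j, a), L[a], bdry[a]);
    out[a] = d;
    d2 += d * d;
  }
  return std::sqrt(d2);
}

// Cell-list candidate pairs within cutoff (superset-free: exact distance filter).
// Returns a 2-column 1-based index matrix, rows sorted lexicographically.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double cutoff,
                                 NumericVector L, IntegerVector bdry) {
  const int n = pos.nrow();
  std::vector<std::pair<int, int> > pairs;
  if (n >= 2) {
    // Bin extents: periodic axes use [0, L); others use the data range.
    double lo[3], span[3];
    int nc[3];
    for (int a = 0; a < 3; ++a) {
      if (bdry[a] == 2) {
        lo[a] = 0.0;
        span[a] = L[a];
      } else {
        double mn = pos(0, a), mx = pos(0, a);
        for (int i = 1; i < n; ++i) {
          mn = std::min(mn, pos(i, a));
          mx = std::max(mx, pos(i, a));
        }
        lo[a] = mn;
        span[a] = std::max(mx - mn, 1e-9);
      }
      nc[a] = std::max(1, (int)std::floor(span[a] / cutoff));
    }
    const int ncy = nc[1], ncz = nc[2];
    const int ncells = nc[0] * ncy * ncz;
    std::vector<std::vector<int> > cells(ncells);
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      int idx[3];
      for (int a = 0; a < 3; ++a) {
        double x = pos(i, a);
        if (bdry[a] == 2) {
          x -= L[a] * std::floor(x / L[a]);
        }
        int c = (int)std::floor((x - lo[a]) / span[a] * nc[a]);
        idx[a] = std::min(std::max(c, 0), nc[a] - 1);
      }
      ci[i] = idx[0]; cj[i] = idx[1]; ck[i] = idx[2];
      cells[(idx[0] * ncy + idx[1]) * ncz + idx[2]].push_back(i);
    }
    const double cut2 = cutoff * cutoff;
    int nbr[27];
    for (int i = 0; i < n; ++i) {
      // Collect the (deduplicated) neighbour cells of agent i's cell.
      int nn = 0;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int cx = ci[i] + dx, cy = cj[i] + dy, cz = ck[i] + dz;
            if (bdry[0] == 2) cx = (cx + nc[0]) % nc[0];
            if (bdry[1] == 2) cy = (cy + ncy) % ncy;
            if (bdry[2] == 2) cz = (cz + ncz) % ncz;
            if (cx < 0 || cx >= nc[0] || cy < 0 || cy >= ncy ||
                cz < 0 || cz >= ncz)
              continue;
            int cc = (cx * ncy + cy) * ncz + cz;
            bool seen = false;
            for (int t = 0; t < nn; ++t)
              if (nbr[t] == cc) { seen = true; break; }
            if (!seen) nbr[nn++] = cc;
          }
      for (int t = 0; t < nn; ++t)
        for (size_t u = 0; u < cells[nbr[t]].size(); ++u) {
          int j = cells[nbr[t]][u];
          if (j <= i) continue;
          double d2 = 0.0;
          for (int a = 0; a < 3; ++a) {
            double d = min_image(pos(i, a) - pos(j, a), L[a], bdry[a]);
            d2 += d * d;
          }
          if (d2 <= cut2) pairs.push_back(std::make_pair(i, j));
        }
    }
    std::sort(pairs.begin(), pairs.end());
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first + 1;
    out(r, 1) = pairs[r].second + 1;
  }
  return out;
}

static std::vector<std::pair<int, int> > update_bonds_impl(
    const NumericMatrix &pos, const IntegerMatrix &bonds,
    double delta_c, double delta_d,
    const NumericVector &L, const IntegerVector &bdry) {
  const int n = pos.nrow();
  std::unordered_set<long long> have;
  std::vector<std::pair<int, int> > out;
  double v[3];
  // Keep existing bonds not stretched past delta_d (hysteresis band).
  for (int r = 0; r < bonds.nrow(); ++r) {
    int i = bonds(r, 0) - 1, j = bonds(r, 1) - 1;
    double d = sep_vec(pos, i, j, L, bdry, v);
    if (d <= delta_d) {
      out.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
      have.insert(pair_key(i, j, n));
    }
  }
  // Create bonds for unbonded pairs closer than delta_c.
  IntegerMatrix cand = cpp_neighbor_pairs(const_cast<NumericMatrix &>(pos),
                                          delta_c, const_cast<NumericVector &>(L),
                                          const_cast<IntegerVector &>(bdry));
  for (int r = 0; r < cand.nrow(); ++r) {
    int i = cand(r, 0) - 1, j = cand(r, 1) - 1;
    double d = sep_vec(pos, i, j, L, bdry, v);
    if (d < delta_c && have.find(pair_key(i, j, n)) == have.end()) {
      out.push_back(std::make_pair(i, j));
      have.insert(pair_key(i, j, n));
    }
  }
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_update_bonds(NumericMatrix pos, IntegerMatrix bonds,
                               double delta_c, double delta_d,
                               NumericVector L, IntegerVector bdry) {
  std::vector<std::pair<int, int> > b =
      update_bonds_impl(pos, bonds, delta_c, delta_d, L, bdry);
  IntegerMatrix out(b.size(), 2);
  for (size_t r = 0; r < b.size(); ++r) {
    out(r, 0) = b[r].first + 1;
    out(r, 1) = b[r].second + 1;
  }
  return out;
}

static void net_forces_impl(const NumericMatrix &pos, const NumericVector &aR,
                            const std::vector<std::pair<int, int> > &bonds,
                            double K, double s_b, double s_ba, double delta_ca,
                            bool cc_adh, bool ca_adh, bool agar,
                            const NumericVector &L, const IntegerVector &bdry,
                            std::vector<double> &f) {
  const int n = pos.nrow();
  std::fill(f.begin(), f.end(), 0.0);
  double v[3];
  for (size_t r = 0; r < bonds.size(); ++r) {
    int i = bonds[r].first, j = bonds[r].second;
    double d = sep_vec(pos, i, j, L, bdry, v);
    if (d == 0.0)
      stop("coincident agent centers (pair %d,%d): force direction undefined",
           i + 1, j + 1);
    double x = aR[i] + aR[j] - d;
    double mag = 0.0;
    if (x >= 0.0 || cc_adh) mag = K * x * std::tanh(s_b * std::fabs(x));
    for (int a = 0; a < 3; ++a) {
      double fa = mag * v[a] / d;
      f[3 * i + a] += fa;
      f[3 * j + a] -= fa;
    }
  }
  if (agar) {
    for (int i = 0; i < n; ++i) {
      double d = pos(i, 0);
      double x = aR[i] - d;
      if (x > 0.0) {
        f[3 * i] += K * x * std::tanh(s_ba * x);
      } else if (x < 0.0 && ca_adh && d < delta_ca) {
        f[3 * i] += K * x * std::tanh(s_ba * std::fabs(x));
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_net_forces(NumericMatrix pos, NumericVector aR,
                             IntegerMatrix bonds, double K, double s_b,
                             double s_ba, double delta_ca, bool cc_adh,
                             bool ca_adh, bool agar, NumericVector L,
                             IntegerVector bdry) {
  const int n = pos.nrow();
  std::vector<std::pair<int, int> > b;
  for (int r = 0; r < bonds.nrow(); ++r)
    b.push_back(std::make_pair(bonds(r, 0) - 1, bonds(r, 1) - 1));
  std::vector<double> f(3 * n);
  net_forces_impl(pos, aR, b, K, s_b, s_ba, delta_ca, cc_adh, ca_adh, agar,
                  L, bdry, f);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = f[3 * i + a];
  return out;
}

// Advance the system: per step (1) bond update, (2) forces, (3) Euler-Maruyama
// move, (4) boundaries. If v_thresh > 0, stops (before moving) once the maximum
// deterministic agent speed max|f|/zeta drops below it.
// frozen_y: agents whose y coordinate is held fixed (compression border cells).
//
// Performance structure: candidate pairs within delta_d + skin are kept in a
// Verlet list (rebuilt via a cell sweep once any agent has moved further than
// skin/2 since the last build); the hysteretic bond state is a CSR adjacency
// rebuilt each step. Pair separations use per-pair wrap shifts against an
// internally unwrapped coordinate copy, so the inner loop is branch-light.
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericVector aR, IntegerMatrix bonds,
             double K, double s_b, double s_ba, double delta_c, double delta_d,
             double delta_ca, bool cc_adh, bool ca_adh, double zeta, double Dc,
             double dt, NumericVector L, IntegerVector bdry,
             LogicalVector frozen_y, int n_steps, double force_scale,
             double v_thresh) {
  const int n = pos.nrow();
  NumericMatrix pout = clone(pos);
  double *p[3] = {&pout(0, 0), &pout(0, 1), &pout(0, 2)};
  std::vector<double> pu(3 * n);   // unwrapped coordinates
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) pu[3 * i + a] = p[a][i];

  // hysteretic bond state as CSR adjacency
  std::vector<std::pair<int, int> > curpairs, newpairs;
  curpairs.reserve(bonds.nrow() + 64);
  for (int r = 0; r < bonds.nrow(); ++r)
    curpairs.push_back(std::make_pair(bonds(r, 0) - 1, bonds(r, 1) - 1));
  std::vector<int> adj_off(n + 1), adj;
  auto build_csr = [&](const std::vector<std::pair<int, int> > &pr) {
    std::fill(adj_off.begin(), adj_off.end(), 0);
    for (size_t r = 0; r < pr.size(); ++r) {
      ++adj_off[pr[r].first + 1];
      ++adj_off[pr[r].second + 1];
    }
    for (int i = 0; i < n; ++i) adj_off[i + 1] += adj_off[i];
    adj.assign(2 * pr.size(), 0);
    std::vector<int> cursor(adj_off.begin(), adj_off.end() - 1);
    for (size_t r = 0; r < pr.size(); ++r) {
      adj[cursor[pr[r].first]++] = pr[r].second;
      adj[cursor[pr[r].second]++] = pr[r].first;
    }
  };
  build_csr(curpairs);
  auto is_bonded_now = [&](int i, int j) {
    for (int t = adj_off[i]; t < adj_off[i + 1]; ++t)
      if (adj[t] == j) return true;
    return false;
  };

  const bool agar = (bdry[0] == 1);
  const double noise_sd = std::sqrt(2.0 * Dc * dt);
  const double skin = 0.3 * delta_d;
  const double cutoff = delta_d + skin;
  const double cut2 = delta_d * delta_d, dc2 = delta_c * delta_c;

  // Verlet pair list with per-pair wrap shifts (relative to pu)
  std::vector<int> vi, vj;
  std::vector<double> vs0, vs1, vs2;
  std::vector<double> ref(3 * n);
  std::vector<int> head, nxt(n);

  auto rebuild_pairs = [&]() {
    vi.clear(); vj.clear(); vs0.clear(); vs1.clear(); vs2.clear();
    double lo[3], span[3];
    int nc[3];
    for (int a = 0; a < 3; ++a) {
      if (bdry[a] == 2) {
        lo[a] = 0.0;
        span[a] = L[a];
      } else {
        double mn = p[a][0], mx = p[a][0];
        for (int i = 1; i < n; ++i) {
          mn = std::min(mn, p[a][i]);
          mx = std::max(mx, p[a][i]);
        }
        lo[a] = mn;
        span[a] = std::max(mx - mn, 1e-9);
      }
      nc[a] = std::max(1, (int)std::floor(span[a] / cutoff));
    }
    const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
    head.assign(ncx * ncy * ncz, -1);
    std::vector<int> ci(n), cj(n), ck(n);
    for (int i = 0; i < n; ++i) {
      int idx[3];
      for (int a = 0; a < 3; ++a) {
        double x = p[a][i];
        if (bdry[a] == 2) x -= L[a] * std::floor(x / L[a]);
        int c = (int)std::floor((x - lo[a]) / span[a] * nc[a]);
        idx[a] = std::min(std::max(c, 0), nc[a] - 1);
      }
      ci[i] = idx[0]; cj[i] = idx[1]; ck[i] = idx[2];
      int cc = (idx[0] * ncy + idx[1]) * ncz + idx[2];
      nxt[i] = head[cc];
      head[cc] = i;
    }
    const double c2 = cutoff * cutoff;
    const bool half_ok = (bdry[0] != 2 || ncx >= 3) &&
                         (bdry[1] != 2 || ncy >= 3) &&
                         (bdry[2] != 2 || ncz >= 3);
    auto add_pair = [&](int i, int j) {
      // exact minimum image at build time, recorded as a shift on pu
      double v[3];
      for (int a = 0; a < 3; ++a)
        v[a] = min_image(p[a][i] - p[a][j], L[a], bdry[a]);
      double d2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
      if (d2 > c2) return;
      vi.push_back(i); vj.push_back(j);
      vs0.push_back(v[0] - (pu[3 * i] - pu[3 * j]));
      vs1.push_back(v[1] - (pu[3 * i + 1] - pu[3 * j + 1]));
      vs2.push_back(v[2] - (pu[3 * i + 2] - pu[3 * j + 2]));
    };
    int nbr[27];
    for (int ix = 0; ix < ncx; ++ix)
      for (int iy = 0; iy < ncy; ++iy)
        for (int iz = 0; iz < ncz; ++iz) {
          int c0 = (ix * ncy + iy) * ncz + iz;
          if (head[c0] < 0) continue;
          int nn = 0;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (half_ok &&
                    (dz < 0 || (dz == 0 && dy < 0) ||
                     (dz == 0 && dy == 0 && dx < 0)))
                  continue;
                int cx = ix + dx, cy = iy + dy, cz = iz + dz;
                if (bdry[0] == 2) cx = (cx + ncx) % ncx;
                if (bdry[1] == 2) cy = (cy + ncy) % ncy;
                if (bdry[2] == 2) cz = (cz + ncz) % ncz;
                if (cx < 0 || cx >= ncx || cy < 0 || cy >= ncy ||
                    cz < 0 || cz >= ncz)
                  continue;
                int cc = (cx * ncy + cy) * ncz + cz;
                if (cc == c0) continue;
                bool seen = false;
                for (int t = 0; t < nn; ++t)
                  if (nbr[t] == cc) { seen = true; break; }
                if (!seen) nbr[nn++] = cc;
              }
          for (int i = head[c0]; i >= 0; i = nxt[i]) {
            for (int j = head[c0]; j >= 0; j = nxt[j])
              if (j > i) add_pair(i, j);
            for (int t = 0; t < nn; ++t)
              for (int j = head[nbr[t]]; j >= 0; j = nxt[j]) {
                if (!half_ok && j <= i) continue;
                add_pair(i, j);
              }
          }
        }
    std::copy(pu.begin(), pu.end(), ref.begin());
  };

  std::vector<double> f(3 * n);
  double vmax = NA_REAL;
  int steps_done = 0;
  bool converged = false;
  bool need_rebuild = true;
  const double half_skin2 = (skin / 2) * (skin / 2);

  for (int s = 0; s < n_steps; ++s) {
    if (need_rebuild) {
      rebuild_pairs();
      need_rebuild = false;
    }
    // fused bond update + forces over the Verlet pairs
    std::fill(f.begin(), f.end(), 0.0);
    newpairs.clear();
    newpairs.reserve(curpairs.size() + 64);
    const size_t m = vi.size();
    for (size_t r = 0; r < m; ++r) {
      const int i = vi[r], j = vj[r];
      const double v0 = pu[3 * i] - pu[3 * j] + vs0[r];
      const double v1 = pu[3 * i + 1] - pu[3 * j + 1] + vs1[r];
      const double v2 = pu[3 * i + 2] - pu[3 * j + 2] + vs2[r];
      const double d2 = v0 * v0 + v1 * v1 + v2 * v2;
      if (d2 > cut2) continue;
      bool bonded_pair;
      if (d2 < dc2) bonded_pair = true;       // below delta_c: bonded either way
      else bonded_pair = is_bonded_now(i, j); // hysteresis band
      if (!bonded_pair) continue;
      newpairs.push_back(std::make_pair(i, j));
      const double d = std::sqrt(d2);
      if (d == 0.0)
        stop("coincident agent centers: force direction undefined");
      const double x = aR[i] + aR[j] - d;
      double mag = 0.0;
      if (x >= 0.0 || cc_adh) mag = K * x * std::tanh(s_b * std::fabs(x));
      mag /= d;
      f[3 * i] += mag * v0; f[3 * j] -= mag * v0;
      f[3 * i + 1] += mag * v1; f[3 * j + 1] -= mag * v1;
      f[3 * i + 2] += mag * v2; f[3 * j + 2] -= mag * v2;
    }
    curpairs.swap(newpairs);
    build_csr(curpairs);
    if (agar) {
      for (int i = 0; i < n; ++i) {
        double d = p[0][i];
        double x = aR[i] - d;
        if (x > 0.0)
          f[3 * i] += K * x * std::tanh(s_ba * x);
        else if (x < 0.0 && ca_adh && d < delta_ca)
          f[3 * i] += K * x * std::tanh(s_ba * std::fabs(x));
      }
    }
    if (force_scale != 1.0)
      for (int i = 0; i < 3 * n; ++i) f[i] *= force_scale;
    vmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double fx = f[3 * i], fy = frozen_y[i] ? 0.0 : f[3 * i + 1],
             fz = f[3 * i + 2];
      double q = fx * fx + fy * fy + fz * fz;
      if (q > vmax) vmax = q;
    }
    vmax = std::sqrt(vmax) / zeta;
    if (v_thresh > 0.0 && vmax < v_thresh) {
      converged = true;
      break;
    }
    double maxdisp2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double disp2 = 0.0;
      for (int a = 0; a < 3; ++a) {
        if (a == 1 && frozen_y[i]) continue;
        double step_a = dt * f[3 * i + a] / zeta;
        if (Dc > 0.0) step_a += noise_sd * norm_rand();
        double xw = p[a][i] + step_a;
        double xu = pu[3 * i + a] + step_a;
        if (bdry[a] == 2) {
          xw -= L[a] * std::floor(xw / L[a]);
        } else if (bdry[a] == 1 && xw < 0.0) {
          xw = 0.0;
          xu = 0.0;  // wall axes carry no unwrapped offset
        }
        if (!std::isfinite(xw))
          stop("non-finite position at step %d: integration unstable, reduce dt",
               s + 1);
        p[a][i] = xw;
        pu[3 * i + a] = xu;
        double dref = pu[3 * i + a] - ref[3 * i + a];
        disp2 += dref * dref;
      }
      if (disp2 > maxdisp2) maxdisp2 = disp2;
    }
    if (maxdisp2 > half_skin2) need_rebuild = true;
    ++steps_done;
  }
  std::sort(curpairs.begin(), curpairs.end());
  IntegerMatrix bout((int)curpairs.size(), 2);
  for (size_t r = 0; r < curpairs.size(); ++r) {
    bout(r, 0) = curpairs[r].first + 1;
    bout(r, 1) = curpairs[r].second + 1;
  }
  return List::create(_["positions"] = pout, _["bonds"] = bout,
                      _["steps"] = steps_done, _["v_max"] = vmax,
                      _["converged"] = converged);
}
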