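#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact SSA for the one-reaction lattice contact process: a mutant site with a
// wild-type von Neumann neighbour is replaced by wild-type at rate d per contact.
// Contacts are kept incrementally in a Fenwick tree indexed by slot = site*4 + dir
// (site row-major, dir N,E,S,W), so the k-th active contact in enumeration order
// can be selected in O(log M); results are identical to full re-enumeration.

namespace {

struct Fenwick {
  int n;
  std::vector<int> t;
  Fenwick(int n_) : n(n_), t(n_ + 1, 0) {}
  void add(int i, int v) {            // 0-based index
    for (++i; i <= n; i += i & -i) t[i] += v;
  }
  // index of the (k+1)-th active slot, k 0-based; assumes k < total
  int select(int k) const {
    int pos = 0, rem = k + 1;
    int logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << logn; pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] < rem) {
        pos += pw;
        rem -= t[pos];
      }
    }
    return pos;  // 0-based slot
  }
};

// boundary_mode: 0 = wildtype_frame (off-grid counts as wild-type),
//                1 = periodic_x (columns wrap, rows closed),
//                2 = periodic_xy (both wrap)
// Returns neighbour linear index, or -1 for off-grid wild-type, -2 for no neighbour.
inline int neighbour_of(int i, int j, int dir, int nr, int nc, int mode) {
  int ni = i, nj = j;
  switch (dir) {
    case 0: ni = i - 1; break;  // N
    case 1: nj = j + 1; break;  // E
    case 2: ni = i + 1; break;  // S
    case 3: nj = j - 1; break;  // W
  }
  if (mode == 2) {
    ni = (ni + nr) % nr;
    nj = (nj + nc) % nc;
  } else if (mode == 1) {
    nj = (nj + nc) % nc;
    if (ni < 0 || ni >= nr) return -2;
  } else {
    if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) return -1;
  }
  return ni * nc + nj;
}

}  // namespace

// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(IntegerMatrix occ0, double d, double t_final,
             NumericVector snapshot_times, int boundary_mode,
             bool record_events) {
  const int nr = occ0.nrow(), nc = occ0.ncol(), N = nr * nc;
  std::vector<int> occ(N);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) occ[i * nc + j] = occ0(i, j);

  Fenwick fen(4 * N);
  std::vector<int> site_contacts(N, 0);
  int n_active = 0, boundary_cells = 0, mutant_count = 0;

  auto wt_neighbour = [&](int s, int dir) -> bool {
    int i = s / nc, j = s % nc;
    int nb = neighbour_of(i, j, dir, nr, nc, boundary_mode);
    if (nb == -1) return true;   // off-grid wild-type frame
    if (nb == -2) return false;  // closed edge: no neighbour
    return occ[nb] == 0;
  };

  for (int s = 0; s < N; ++s) {
    if (occ[s] != 1) continue;
    ++mutant_count;
    for (int dir = 0; dir < 4; ++dir) {
      if (wt_neighbour(s, dir)) {
        fen.add(s * 4 + dir, 1);
        ++site_contacts[s];
        ++n_active;
      }
    }
    if (site_contacts[s] > 0) ++boundary_cells;
  }

  const int K = snapshot_times.size();
  List snap_occ(K);
  NumericVector snap_time(K);
  IntegerVector snap_mut(K), snap_bcells(K), snap_bedges(K);
  std::vector<double> ev_time;
  std::vector<int> ev_i, ev_j, ev_dir;

  int k = 0, n_events = 0;
  double t = 0.0;
  auto record_upto = [&](double horizon) {
    // record all snapshots with time strictly below `horizon` as the current state
    while (k < K && snapshot_times[k] < horizon) {
      IntegerMatrix m(nr, nc);
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j) m(i, j) = occ[i * nc + j];
      snap_occ[k] = m;
      snap_time[k] = snapshot_times[k];
      snap_mut[k] = mutant_count;
      snap_bcells[k] = boundary_cells;
      snap_bedges[k] = n_active;
      ++k;
    }
  };

  GetRNGstate();
  while (true) {
    if (n_active == 0 || d <= 0.0) break;
    double r1 = unif_rand();
    while (r1 <= 0.0) r1 = unif_rand();  // guard: log(1/r1) must be finite
    double a0 = d * n_active;
    double tau = std::log(1.0 / r1) / a0;
    double t_new = t + tau;
    record_upto(t_new);          // snapshots strictly before this event
    if (t_new > t_final) break;  // would jump past the horizon: do not fire
    double r2 = unif_rand();
    int rank = (int)std::floor(r2 * n_active);
    if (rank >= n_active) rank = n_active - 1;
    int slot = fen.select(rank);
    int s = slot / 4, fired_dir = slot % 4;
    int fi = s / nc, fj = s % nc;

    // fire: mutant site becomes wild-type
    occ[s] = 0;
    --mutant_count;
    // remove s's own contacts (each active slot of s pointed at a WT neighbour)
    {
      int removed = 0;
      for (int dir = 0; dir < 4 && removed < site_contacts[s]; ++dir) {
        if (wt_neighbour(s, dir)) {
          fen.add(s * 4 + dir, -1);
          --n_active;
          ++removed;
        }
      }
      if (site_contacts[s] > 0) --boundary_cells;
      site_contacts[s] = 0;
    }
    // mutant neighbours of s gain a contact pointing at s
    for (int dir = 0; dir < 4; ++dir) {
      int nb = neighbour_of(fi, fj, dir, nr, nc, boundary_mode);
      if (nb < 0) continue;
      if (occ[nb] == 1) {
        int opp = (dir + 2) % 4;
        fen.add(nb * 4 + opp, 1);
        ++n_active;
        if (site_contacts[nb] == 0) ++boundary_cells;
        ++site_contacts[nb];
      }
    }

    t = t_new;
    ++n_events;
    if (record_events) {
      ev_time.push_back(t);
      ev_i.push_back(fi + 1);
      ev_j.push_back(fj + 1);
      ev_dir.push_back(fired_dir + 1);
    }
    if (t >= t_final) break;
  }
  PutRNGstate();
  record_upto(R_PosInf);  // remaining snapshots see the final state

  List events = List::create(
      _["time_days"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["i"] = IntegerVector(ev_i.begin(), ev_i.end()),
      _["j"] = IntegerVector(ev_j.begin(), ev_j.end()),
      _["dir"] = IntegerVector(ev_dir.begin(), ev_dir.end()));

  return List::create(
      _["snap_occ"] = snap_occ, _["snap_time"] = snap_time,
      _["mutant_count"] = snap_mut, _["boundary_cells"] = snap_bcells,
      _["boundary_edges"] = snap_bedges, _["final_time"] = t,
      _["n_events"] = n_events, _["events"] = events);
}

// Connected-component labelling of an integer/logical array (non-zero = foreground).
// dims of length 2 (connectivity 4 or 8) or 3 (connectivity 6 or 26). Labels are
// assigned in raster-scan order of each component's first-encountered element.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector x, IntegerVector dim,
                               int connectivity) {
  const int ndim = dim.size();
  const int nr = dim[0], nc = dim[1], nz = (ndim == 3) ? dim[2] : 1;
  const R_xlen_t N = (R_xlen_t)nr * nc * nz;
  if (x.size() != N) stop("array size does not match dims");
  IntegerVector lab(N, 0);

  std::vector<std::array<int, 3>> offs;
  if (ndim == 2) {
    if (connectivity != 4 && connectivity != 8)
      stop("2D connectivity must be 4 or 8");
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        if (di == 0 && dj == 0) continue;
        if (connectivity == 4 && std::abs(di) + std::abs(dj) != 1) continue;
        offs.push_back({di, dj, 0});
      }
  } else {
    if (connectivity != 6 && connectivity != 26)
      stop("3D connectivity must be 6 or 26");
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          if (connectivity == 6 &&
              std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
            continue;
          offs.push_back({di, dj, dk});
        }
  }

  // R arrays are column-major: index = i + nr*(j + nc*k)
  auto idx_of = [&](int i, int j, int kk) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)nr * ((R_xlen_t)j + (R_xlen_t)nc * kk);
  };

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (int kk = 0; kk < nz; ++kk)
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        R_xlen_t p = idx_of(i, j, kk);
        if (x[p] == 0 || lab[p] != 0) continue;
        ++next_label;
        lab[p] = next_label;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t q = stack.back();
          stack.pop_back();
          int qi = (int)(q % nr);
          int rest = (int)(q / nr);
          int qj = rest % nc, qk = rest / nc;
          for (auto &o : offs) {
            int ni = qi + o[0], nj = qj + o[1], nk = qk + o[2];
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc || nk < 0 || nk >= nz)
              continue;
            R_xlen_t np = idx_of(ni, nj, nk);
            if (x[np] != 0 && lab[np] == 0) {
              lab[np] = next_label;
              stack.push_back(np);
            }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}
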