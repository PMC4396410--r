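#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Internal state for the fixed-margin MCMC: taxa indices per cell (row) plus
// a dense membership table so checkerboard-swap feasibility is O(1).
struct MatState {
  int n_row, n_col;
  std::vector< std::vector<int> > rows;  // 0-based taxon ids per cell
  std::vector<char> member;              // n_row * n_col occupancy flags

  void init(const IntegerMatrix& pres) {
    n_row = pres.nrow();
    n_col = pres.ncol();
    rows.assign(n_row, std::vector<int>());
    member.assign((size_t)n_row * n_col, 0);
    for (int i = 0; i < n_row; ++i) {
      for (int j = 0; j < n_col; ++j) {
        if (pres(i, j) != 0) {
          rows[i].push_back(j);
          member[(size_t)i * n_col + j] = 1;
        }
      }
    }
  }

  inline bool has(int i, int j) const {
    return member[(size_t)i * n_col + j] != 0;
  }
  inline void set(int i, int j, char v) {
    member[(size_t)i * n_col + j] = v;
  }

  IntegerMatrix to_matrix() const {
    IntegerMatrix out(n_row, n_col);
    for (int i = 0; i < n_row; ++i)
      for (size_t k = 0; k < rows[i].size(); ++k)
        out(i, rows[i][k]) = 1;
    return out;
  }
};

static inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// One curveball trade between two random rows: the taxa unique to either row
// are pooled and redealt at random, keeping each row's size (and therefore
// all row and column sums) fixed.
static void curveball_trade(MatState& st) {
  if (st.n_row < 2) return;
  int i = runif_int(st.n_row);
  int j = runif_int(st.n_row - 1);
  if (j >= i) ++j;

  std::vector<int>& ri = st.rows[i];
  std::vector<int>& rj = st.rows[j];

  std::vector<int> only_i, only_j;
  only_i.reserve(ri.size());
  only_j.reserve(rj.size());
  for (size_t k = 0; k < ri.size(); ++k)
    if (!st.has(j, ri[k])) only_i.push_back(ri[k]);
  for (size_t k = 0; k < rj.size(); ++k)
    if (!st.has(i, rj[k])) only_j.push_back(rj[k]);

  int ni = (int)only_i.size(), nj = (int)only_j.size();
  if (ni == 0 || nj == 0) return;

  std::vector<int> pool(only_i);
  pool.insert(pool.end(), only_j.begin(), only_j.end());
  // Fisher-Yates on the pooled exchangeable taxa
  for (int k = (int)pool.size() - 1; k > 0; --k) {
    int m = runif_int(k + 1);
    std::swap(pool[k], pool[m]);
  }

  // remove old exchangeable taxa from both rows
  for (int k = 0; k < ni; ++k) st.set(i, only_i[k], 0);
  for (int k = 0; k < nj; ++k) st.set(j, only_j[k], 0);
  std::vector<int> new_i, new_j;
  new_i.reserve(ri.size());
  new_j.reserve(rj.size());
  for (size_t k = 0; k < ri.size(); ++k)
    if (st.has(i, ri[k])) new_i.push_back(ri[k]);
  for (size_t k = 0; k < rj.size(); ++k)
    if (st.has(j, rj[k])) new_j.push_back(rj[k]);

  for (int k = 0; k < ni; ++k) {
    new_i.push_back(pool[k]);
    st.set(i, pool[k], 1);
  }
  for (int k = ni; k < ni + nj; ++k) {
    new_j.push_back(pool[k]);
    st.set(j, pool[k], 1);
  }
  ri.swap(new_i);
  rj.swap(new_j);
}

// One attempted checkerboard swap: move taxon a (in row i only) to row j and
// taxon b (in row j only) to row i. Rejected attempts leave the state as-is,
// which is the correct Metropolis behaviour for uniform sampling.
static void checkerboard_swap(MatState& st) {
  if (st.n_row < 2) return;
  int i = runif_int(st.n_row);
  int j = runif_int(st.n_row - 1);
  if (j >= i) ++j;
  std::vector<int>& ri = st.rows[i];
  std::vector<int>& rj = st.rows[j];
  if (ri.empty() || rj.empty()) return;
  int ka = runif_int((int)ri.size());
  int kb = runif_int((int)rj.size());
  int a = ri[ka], b = rj[kb];
  if (a == b || st.has(j, a) || st.has(i, b)) return;
  ri[ka] = b;
  rj[kb] = a;
  st.set(i, a, 0); st.set(i, b, 1);
  st.set(j, b, 0); st.set(j, a, 1);
}

static void run_steps(MatState& st, double steps, int backend) {
  for (double s = 0; s < steps; ++s) {
    if (backend == 0) curveball_trade(st);
    else checkerboard_swap(st);
  }
}

// Per-cell raw PD: sum of branch lengths on the union of root-to-tip paths.
// tip_edges holds, per taxon (matrix column), the 0-based edge indices on its
// path to the root; `stamp` avoids clearing the visited flags per cell.
struct PDEngine {
  std::vector< std::vector<int> > paths;
  std::vector<double> len;
  std::vector<int> stamp;
  int cur;

  void init(const List& tip_edges, const NumericVector& edge_len) {
    int p = tip_edges.size();
    paths.resize(p);
    for (int t = 0; t < p; ++t) {
      IntegerVector v = tip_edges[t];
      paths[t].assign(v.begin(), v.end());
    }
    len.assign(edge_len.begin(), edge_len.end());
    stamp.assign(len.size(), -1);
    cur = -1;
  }

  double cell_pd(const std::vector<int>& taxa) {
    ++cur;
    double s = 0.0;
    for (size_t k = 0; k < taxa.size(); ++k) {
      const std::vector<int>& pe = paths[taxa[k]];
      for (size_t e = 0; e < pe.size(); ++e) {
        int ei = pe[e];
        if (stamp[ei] != cur) {
          stamp[ei] = cur;
          s += len[ei];
        }
      }
    }
    return s;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_shuffle(IntegerMatrix pres, double steps, int backend) {
  MatState st;
  st.init(pres);
  run_steps(st, steps, backend);
  return st.to_matrix();
}

// [[Rcpp::export]]
NumericVector cpp_pd_cells(IntegerMatrix pres, List tip_edges,
                           NumericVector edge_len) {
  MatState st;
  st.init(pres);
  PDEngine pd;
  pd.init(tip_edges, edge_len);
  NumericVector out(st.n_row);
  for (int i = 0; i < st.n_row; ++i) out[i] = pd.cell_pd(st.rows[i]);
  return out;
}

// Full randomization test loop: burn in, then n_rand (thin + PD) sweeps,
// accumulating per-cell counts of null statistic >= / <= the observed one.
// The statistic is raw PD divided by cell_scale (1 for PD itself, cell
// richness for relative PD). Ties (within eps, in scaled units) count
// toward both tails.
// [[Rcpp::export]]
List cpp_randomization(IntegerMatrix pres, List tip_edges,
                       NumericVector edge_len, int n_rand,
                       double burn_steps, double thin_steps,
                       int backend, double eps, NumericVector cell_scale) {
  MatState st;
  st.init(pres);
  PDEngine pd;
  pd.init(tip_edges, edge_len);

  int n = st.n_row;
  NumericVector obs_raw(n), obs(n);
  for (int i = 0; i < n; ++i) {
    obs_raw[i] = pd.cell_pd(st.rows[i]);
    obs[i] = obs_raw[i] / cell_scale[i];
  }

  IntegerVector count_ge(n, 0), count_le(n, 0);
  run_steps(st, burn_steps, backend);
  for (int r = 0; r < n_rand; ++r) {
    run_steps(st, thin_steps, backend);
    for (int i = 0; i < n; ++i) {
      double v = pd.cell_pd(st.rows[i]) / cell_scale[i];
      double e = eps / cell_scale[i];
      if (v >= obs[i] - e) ++count_ge[i];
      if (v <= obs[i] + e) ++count_le[i];
    }
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["observed"] = obs_raw, _["count_ge"] = count_ge,
                      _["count_le"] = count_le);
}
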