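#include <Rcpp.h>
#include <vector>
#include <map>
#include <functional>
#include <cmath>
#include <climits>
#include <cstdint>
using namespace Rcpp;

// Gate-level encoding shared by all entry points.
//   gate_target[g]          : 0-based target node of gate g
//   gate_ptr[g] .. ptr[g+1] : slice of gate_src/gate_sign holding the signed sources
// Clamp codes per (condition, node): -1 free, 0 clamped low, 1 clamped high.
// Node values during simulation are 0/1; -1 marks an unresolved (oscillating) node.

struct Net {
  int N, E;
  std::vector<int> gate_target, gate_ptr, gate_src, gate_sign, gate_nsrc;
  std::vector<std::vector<int>> gates_of; // node -> gate ids (ascending)
};

static Net build_net(int N, const IntegerVector& gate_target,
                     const IntegerVector& gate_ptr, const IntegerVector& gate_src,
                     const IntegerVector& gate_sign) {
  Net net;
  net.N = N;
  net.E = gate_target.size();
  net.gate_target.assign(gate_target.begin(), gate_target.end());
  net.gate_ptr.assign(gate_ptr.begin(), gate_ptr.end());
  net.gate_src.assign(gate_src.begin(), gate_src.end());
  net.gate_sign.assign(gate_sign.begin(), gate_sign.end());
  net.gate_nsrc.resize(net.E);
  net.gates_of.assign(N, std::vector<int>());
  for (int g = 0; g < net.E; ++g) {
    net.gate_nsrc[g] = net.gate_ptr[g + 1] - net.gate_ptr[g];
    net.gates_of[net.gate_target[g]].push_back(g);
  }
  return net;
}

// One synchronous step; cur values are 0/1. Returns true if anything changed.
static bool sync_step(const Net& net, const std::vector<char>& sel,
                      const int* clamp, const std::vector<int>& cur,
                      std::vector<int>& nxt) {
  bool changed = false;
  for (int v = 0; v < net.N; ++v) {
    int val;
    if (clamp[v] >= 0) {
      val = clamp[v];
    } else {
      val = 0;
      for (int g : net.gates_of[v]) {
        if (!sel[g]) continue;
        bool andv = true;
        for (int k = net.gate_ptr[g]; k < net.gate_ptr[g + 1]; ++k) {
          int need = net.gate_sign[k] > 0 ? 1 : 0;
          if (cur[net.gate_src[k]] != need) { andv = false; break; }
        }
        if (andv) { val = 1; break; }
      }
    }
    nxt[v] = val;
    if (val != cur[v]) changed = true;
  }
  return changed;
}

// Synchronous fixpoint from the all-zero (plus clamps) state. On
// non-convergence within max_steps, nodes still changing over a further
// N-step probe are reported as -1 (unresolved).
static void simulate_condition(const Net& net, const std::vector<char>& sel,
                               const int* clamp, std::vector<int>& out,
                               int max_steps) {
  std::vector<int> cur(net.N), nxt(net.N);
  for (int v = 0; v < net.N; ++v) cur[v] = clamp[v] >= 0 ? clamp[v] : 0;
  bool converged = false;
  for (int step = 0; step < max_steps; ++step) {
    bool changed = sync_step(net, sel, clamp, cur, nxt);
    std::swap(cur, nxt);
    if (!changed) { converged = true; break; }
  }
  out = cur;
  if (!converged) {
    std::vector<char> unstable(net.N, 0);
    for (int step = 0; step < net.N + 1; ++step) {
      sync_step(net, sel, clamp, cur, nxt);
      for (int v = 0; v < net.N; ++v)
        if (nxt[v] != cur[v]) unstable[v] = 1;
      std::swap(cur, nxt);
    }
    for (int v = 0; v < net.N; ++v) if (unstable[v]) out[v] = -1;
  }
}

// [[Rcpp::export]]
IntegerMatrix simulate_cpp(int N, IntegerVector gate_target, IntegerVector gate_ptr,
                           IntegerVector gate_src, IntegerVector gate_sign,
                           IntegerVector selected, IntegerMatrix clamps,
                           int max_steps) {
  Net net = build_net(N, gate_target, gate_ptr, gate_src, gate_sign);
  std::vector<char> sel(net.E, 0);
  for (int g = 0; g < net.E; ++g) sel[g] = selected[g] != 0;
  int nc = clamps.nrow();
  IntegerMatrix out(nc, N);
  std::vector<int> clamp(N), state;
  for (int i = 0; i < nc; ++i) {
    for (int v = 0; v < N; ++v) clamp[v] = clamps(i, v);
    simulate_condition(net, sel, clamp.data(), state, max_steps);
    for (int v = 0; v < N; ++v)
      out(i, v) = state[v] < 0 ? NA_INTEGER : state[v];
  }
  return out;
}

// Squared residual on the scaled integer grid; -1 prediction = worst case.
static inline double residual2(int pred, int obs_scaled, double pscale) {
  if (pred < 0) return pscale * pscale;
  double d = pred * pscale - obs_scaled;
  return d * d;
}

// [[Rcpp::export]]
List score_models_cpp(int N, IntegerVector gate_target, IntegerVector gate_ptr,
                      IntegerVector gate_src, IntegerVector gate_sign,
                      IntegerMatrix models, IntegerMatrix clamps,
                      IntegerMatrix obs, IntegerVector readout_idx,
                      double pscale, int max_steps) {
  Net net = build_net(N, gate_target, gate_ptr, gate_src, gate_sign);
  int M = models.nrow(), nc = clamps.nrow(), m = readout_idx.size();
  if (models.ncol() != net.E) stop("model matrix has wrong number of columns");
  long n_compared = 0;
  for (int i = 0; i < nc; ++i)
    for (int j = 0; j < m; ++j)
      if (obs(i, j) != NA_INTEGER) ++n_compared;
  NumericVector sse(M);
  IntegerVector size(M);
  std::vector<char> sel(net.E);
  std::vector<int> clamp(N), state;
  for (int r = 0; r < M; ++r) {
    long sz = 0;
    for (int g = 0; g < net.E; ++g) {
      sel[g] = models(r, g) != 0;
      if (sel[g]) sz += net.gate_nsrc[g];
    }
    double s = 0.0;
    for (int i = 0; i < nc; ++i) {
      for (int v = 0; v < N; ++v) clamp[v] = clamps(i, v);
      simulate_condition(net, sel, clamp.data(), state, max_steps);
      for (int j = 0; j < m; ++j) {
        int ob = obs(i, j);
        if (ob == NA_INTEGER) continue;
        s += residual2(state[readout_idx[j]], ob, pscale);
      }
    }
    sse[r] = s;
    size[r] = (int)sz;
  }
  return List::create(_["sse"] = sse, _["size"] = size,
                      _["n_compared"] = (double)n_compared);
}

// ---------------------------------------------------------------------------
// Complete search (optimize / enumerate) over gate subsets.
// ---------------------------------------------------------------------------

struct Search {
  const Net* net;
  int nc, m;
  std::vector<int> clamps;      // nc x N, row-major
  std::vector<int> obs;         // nc x m, row-major, INT_MIN = missing
  std::vector<int> readout_col; // node -> obs column or -1
  double pscale;
  int max_steps;
  bool enumerate_mode;
  double sse_bound;             // enumerate: inclusive bound (guarded)
  long size_bound;
  double cap;
  // optimize incumbent
  double best_sse;
  long best_size;
  std::vector<char> best_sel;
  bool have_best;
  // enumerate results
  std::vector<char> out_sel;    // flattened rows of length E
  std::vector<double> out_sse;
  std::vector<long> out_size;
  long n_found;

  inline int clamp_at(int i, int v) const { return clamps[(size_t)i * net->N + v]; }
  inline int obs_at(int i, int j) const { return obs[(size_t)i * m + j]; }

  bool sse_ok(double s) const {
    return s <= sse_bound * (1.0 + 1e-12) + 1e-9;
  }

  void record(const std::vector<char>& sel, double sse, long size) {
    if (enumerate_mode) {
      if (!sse_ok(sse) || size > size_bound) return;
      if (++n_found > cap)
        stop("model family exceeds the safety cap (%g); tighten the tolerance", cap);
      out_sel.insert(out_sel.end(), sel.begin(), sel.end());
      out_sse.push_back(sse);
      out_size.push_back(size);
    } else {
      if (!have_best || sse < best_sse ||
          (sse == best_sse && size < best_size)) {
        best_sse = sse; best_size = size; best_sel = sel; have_best = true;
      }
    }
  }

  // Pruning test given an admissible SSE lower bound and the current
  // (monotone) size of the partial selection.
  bool prune(double sse_lb, long cur_size) const {
    if (cur_size > size_bound) return true;
    if (enumerate_mode) return !sse_ok(sse_lb);
    if (!have_best) return false;
    if (sse_lb > best_sse) return true;
    if (sse_lb == best_sse && cur_size >= best_size) return true;
    return false;
  }
};

// ---- structured DFS over acyclic hypergraphs ------------------------------

struct DagCtx {
  Search* S;
  std::vector<int> targets;            // target nodes in topological order
  std::vector<double> min_res;         // per target: min achievable residual sum
  std::vector<double> suffix_min;      // suffix sums over targets
  std::vector<std::vector<int>> value; // node -> per-condition value
  std::vector<char> sel;
  double base_sse;                     // from readouts that are not targets
};

static void dag_dfs(DagCtx& C, int depth, double cur_sse, long cur_size);

// Score one resolved (mask, value-vector) choice for the current target and
// recurse into the next depth.
static void dag_descend(DagCtx& C, int depth, double cur_sse, long cur_size,
                        long long mask, long add_size,
                        const std::vector<int>& val) {
  Search& S = *C.S;
  const Net& net = *S.net;
  int t = C.targets[depth];
  const std::vector<int>& gates = net.gates_of[t];
  int rc = S.readout_col[t];
  double add_sse = 0.0;
  if (rc >= 0)
    for (int i = 0; i < S.nc; ++i) {
      int ob = S.obs_at(i, rc);
      if (ob != INT_MIN) add_sse += residual2(val[i], ob, S.pscale);
    }
  double lb = cur_sse + add_sse + C.suffix_min[depth + 1];
  if (S.prune(lb, cur_size + add_size)) return;
  C.value[t] = val;
  for (size_t b = 0; b < gates.size(); ++b)
    C.sel[gates[b]] = (mask >> b) & 1;
  dag_dfs(C, depth + 1, cur_sse + add_sse, cur_size + add_size);
  for (size_t b = 0; b < gates.size(); ++b) C.sel[gates[b]] = 0;
}

static void dag_dfs(DagCtx& C, int depth, double cur_sse, long cur_size) {
  Search& S = *C.S;
  const Net& net = *S.net;
  if (depth == (int)C.targets.size()) {
    S.record(C.sel, cur_sse, cur_size);
    return;
  }
  int t = C.targets[depth];
  const std::vector<int>& gates = net.gates_of[t];
  int g = (int)gates.size();
  long limit = S.size_bound - cur_size;
  // per-gate AND vectors under the (already decided) upstream values;
  // clamped conditions are fixed regardless of the gate choice
  std::vector<int> base(S.nc, 0);
  std::vector<char> fixed(S.nc, 0);
  for (int i = 0; i < S.nc; ++i) {
    int cl = S.clamp_at(i, t);
    if (cl >= 0) { base[i] = cl; fixed[i] = 1; }
  }
  std::vector<std::vector<int>> gv(g, std::vector<int>(S.nc, 0));
  for (int b = 0; b < g; ++b) {
    int gg = gates[b];
    for (int i = 0; i < S.nc; ++i) {
      if (fixed[i]) continue;
      bool andv = true;
      for (int k = net.gate_ptr[gg]; k < net.gate_ptr[gg + 1]; ++k) {
        int need = net.gate_sign[k] > 0 ? 1 : 0;
        if (C.value[net.gate_src[k]][i] != need) { andv = false; break; }
      }
      gv[b][i] = andv ? 1 : 0;
    }
  }
  if (S.enumerate_mode) {
    // every feasible mask is a distinct model: enumerate them with
    // size-bounded recursion over gate inclusion
    std::vector<int> orvec = base;
    std::function<void(int, long long, long)> gen =
      [&](int b, long long mask, long add_size) {
      if (b == g) {
        dag_descend(C, depth, cur_sse, cur_size, mask, add_size, orvec);
        return;
      }
      gen(b + 1, mask, add_size);                 // exclude gate b
      long ns = net.gate_nsrc[gates[b]];
      if (add_size + ns <= limit) {               // include gate b
        std::vector<int> prev = orvec;
        for (int i = 0; i < S.nc; ++i)
          if (!fixed[i] && gv[b][i]) orvec[i] = 1;
        gen(b + 1, mask | (1LL << b), add_size + ns);
        orvec = prev;
      }
    };
    gen(0, 0LL, 0);
  } else {
    // lexicographic optimum: only the cheapest mask per distinct prediction
    // vector can matter, so run a DP over gates keeping, per value vector,
    // the minimum added size (first mask on ties, for determinism)
    std::map<std::vector<int>, std::pair<long, long long>> states;
    states[base] = std::make_pair(0L, 0LL);
    for (int b = 0; b < g; ++b) {
      long ns = net.gate_nsrc[gates[b]];
      std::map<std::vector<int>, std::pair<long, long long>> next = states;
      for (std::map<std::vector<int>,
                    std::pair<long, long long>>::const_iterator it =
             states.begin(); it != states.end(); ++it) {
        if (it->second.first + ns > limit) continue;
        std::vector<int> v = it->first;
        for (int i = 0; i < S.nc; ++i)
          if (!fixed[i] && gv[b][i]) v[i] = 1;
        long sz = it->second.first + ns;
        long long mk = it->second.second | (1LL << b);
        std::map<std::vector<int>, std::pair<long, long long>>::iterator f =
          next.find(v);
        if (f == next.end() || sz < f->second.first)
          next[v] = std::make_pair(sz, mk);
      }
      states.swap(next);
    }
    for (std::map<std::vector<int>,
                  std::pair<long, long long>>::const_iterator it =
           states.begin(); it != states.end(); ++it)
      dag_descend(C, depth, cur_sse, cur_size, it->second.second,
                  it->second.first, it->first);
  }
}

// ---- flat DFS with leaf simulation (cyclic fallback) ----------------------

struct FlatCtx {
  Search* S;
  std::vector<char> sel;
  double min_total; // model-independent lower bound on total SSE
};

static void flat_dfs(FlatCtx& C, const std::vector<int>& readout_nodes,
                     int g, long cur_size) {
  Search& S = *C.S;
  const Net& net = *S.net;
  if (cur_size > S.size_bound) return;
  if (!S.enumerate_mode && S.have_best) {
    if (C.min_total > S.best_sse ||
        (C.min_total == S.best_sse && cur_size >= S.best_size)) return;
  }
  if (S.enumerate_mode && !S.sse_ok(C.min_total)) return;
  if (g == net.E) {
    std::vector<int> clamp(net.N), state;
    double s = 0.0;
    for (int i = 0; i < S.nc; ++i) {
      for (int v = 0; v < net.N; ++v) clamp[v] = S.clamp_at(i, v);
      simulate_condition(net, C.sel, clamp.data(), state, S.max_steps);
      for (int j = 0; j < S.m; ++j) {
        int ob = S.obs_at(i, j);
        if (ob == INT_MIN) continue;
        s += residual2(state[readout_nodes[j]], ob, S.pscale);
      }
    }
    S.record(C.sel, s, cur_size);
    return;
  }
  C.sel[g] = 0;
  flat_dfs(C, readout_nodes, g + 1, cur_size);
  C.sel[g] = 1;
  flat_dfs(C, readout_nodes, g + 1, cur_size + net.gate_nsrc[g]);
  C.sel[g] = 0;
}

// Kahn topological order of nodes under gate-source dependencies.
// Returns empty vector when cyclic.
static std::vector<int> topo_order(const Net& net) {
  std::vector<std::vector<int>> adj(net.N);
  std::vector<int> indeg(net.N, 0);
  for (int g = 0; g < net.E; ++g) {
    int t = net.gate_target[g];
    for (int k = net.gate_ptr[g]; k < net.gate_ptr[g + 1]; ++k) {
      adj[net.gate_src[k]].push_back(t);
      ++indeg[t];
    }
  }
  std::vector<int> q, ord;
  for (int v = 0; v < net.N; ++v) if (indeg[v] == 0) q.push_back(v);
  for (size_t h = 0; h < q.size(); ++h) {
    int v = q[h];
    ord.push_back(v);
    for (int w : adj[v]) if (--indeg[w] == 0) q.push_back(w);
  }
  if ((int)ord.size() != net.N) ord.clear();
  return ord;
}

// [[Rcpp::export]]
List search_cpp(int N, IntegerVector gate_target, IntegerVector gate_ptr,
                IntegerVector gate_src, IntegerVector gate_sign,
                IntegerMatrix clamps, IntegerMatrix obs,
                IntegerVector readout_idx, double pscale, int max_steps,
                std::string mode, double sse_bound, double size_bound,
                double cap) {
  Net net = build_net(N, gate_target, gate_ptr, gate_src, gate_sign);
  Search S;
  S.net = &net;
  S.nc = clamps.nrow();
  S.m = readout_idx.size();
  S.pscale = pscale;
  S.max_steps = max_steps;
  S.enumerate_mode = (mode == "enumerate");
  S.sse_bound = sse_bound;
  S.size_bound = size_bound >= 1e17 ? (long)1e17 : (long)std::floor(size_bound + 1e-9);
  S.cap = cap;
  S.best_sse = R_PosInf;
  S.best_size = 0;
  S.have_best = false;
  S.n_found = 0;
  S.clamps.resize((size_t)S.nc * N);
  for (int i = 0; i < S.nc; ++i)
    for (int v = 0; v < N; ++v) S.clamps[(size_t)i * N + v] = clamps(i, v);
  S.obs.resize((size_t)S.nc * S.m);
  for (int i = 0; i < S.nc; ++i)
    for (int j = 0; j < S.m; ++j)
      S.obs[(size_t)i * S.m + j] = obs(i, j) == NA_INTEGER ? INT_MIN : obs(i, j);
  S.readout_col.assign(N, -1);
  for (int j = 0; j < S.m; ++j) S.readout_col[readout_idx[j]] = j;

  std::vector<int> ord = topo_order(net);
  if (!ord.empty()) {
    DagCtx C;
    C.S = &S;
    C.sel.assign(net.E, 0);
    C.value.assign(N, std::vector<int>(S.nc, 0));
    C.base_sse = 0.0;
    // fixed values for non-target nodes; base residuals for non-target readouts
    std::vector<char> is_target(N, 0);
    for (int g = 0; g < net.E; ++g) is_target[net.gate_target[g]] = 1;
    for (int v = 0; v < N; ++v) {
      if (is_target[v]) continue;
      for (int i = 0; i < S.nc; ++i) {
        int cl = S.clamp_at(i, v);
        C.value[v][i] = cl >= 0 ? cl : 0;
      }
      int rc = S.readout_col[v];
      if (rc >= 0)
        for (int i = 0; i < S.nc; ++i) {
          int ob = S.obs_at(i, rc);
          if (ob != INT_MIN) C.base_sse += residual2(C.value[v][i], ob, S.pscale);
        }
    }
    // Admissible target order: any order compatible with the dependency
    // DAG works; scheduling readout targets as early as their inputs allow
    // makes residuals accrue sooner and tightens the bound.
    {
      std::vector<char> decided(N, 0);
      for (int v = 0; v < N; ++v) if (!is_target[v]) decided[v] = 1;
      std::vector<int> pending;
      for (int v : ord) if (is_target[v]) pending.push_back(v);
      while (!pending.empty()) {
        int pick = -1;
        for (int idx = 0; idx < (int)pending.size(); ++idx) {
          int t = pending[idx];
          bool ready = true;
          for (int g : net.gates_of[t]) {
            for (int k = net.gate_ptr[g]; k < net.gate_ptr[g + 1]; ++k)
              if (!decided[net.gate_src[k]] && net.gate_src[k] != t) {
                ready = false; break;
              }
            if (!ready) break;
          }
          if (!ready) continue;
          if (pick < 0) pick = idx;
          if (S.readout_col[t] >= 0) { pick = idx; break; }
        }
        if (pick < 0) pick = 0;  // unreachable in a DAG; keep topo order
        int t = pending[pick];
        C.targets.push_back(t);
        decided[t] = 1;
        pending.erase(pending.begin() + pick);
      }
    }
    int K = (int)C.targets.size();
    C.min_res.assign(K, 0.0);
    for (int d = 0; d < K; ++d) {
      int t = C.targets[d];
      int rc = S.readout_col[t];
      if (rc < 0) continue;
      double s = 0.0;
      for (int i = 0; i < S.nc; ++i) {
        int ob = S.obs_at(i, rc);
        if (ob == INT_MIN) continue;
        int cl = S.clamp_at(i, t);
        if (cl >= 0) s += residual2(cl, ob, S.pscale);
        else s += std::min(residual2(0, ob, S.pscale), residual2(1, ob, S.pscale));
      }
      C.min_res[d] = s;
    }
    C.suffix_min.assign(K + 1, 0.0);
    for (int d = K - 1; d >= 0; --d)
      C.suffix_min[d] = C.suffix_min[d + 1] + C.min_res[d];
    if (!S.prune(C.base_sse + C.suffix_min[0], 0))
      dag_dfs(C, 0, C.base_sse, 0);
  } else {
    FlatCtx C;
    C.S = &S;
    C.sel.assign(net.E, 0);
    // model-independent bound: per-entry best of {0,1,unresolved}
    double lb = 0.0;
    for (int i = 0; i < S.nc; ++i)
      for (int j = 0; j < S.m; ++j) {
        int ob = S.obs_at(i, j);
        if (ob == INT_MIN) continue;
        lb += std::min(residual2(0, ob, pscale), residual2(1, ob, pscale));
      }
    C.min_total = lb;
    std::vector<int> readout_nodes(readout_idx.begin(), readout_idx.end());
    flat_dfs(C, readout_nodes, 0, 0);
  }

  if (S.enumerate_mode) {
    int M = (int)S.out_sse.size();
    IntegerMatrix models(M, net.E);
    for (int r = 0; r < M; ++r)
      for (int g = 0; g < net.E; ++g)
        models(r, g) = S.out_sel[(size_t)r * net.E + g];
    NumericVector sse(S.out_sse.begin(), S.out_sse.end());
    NumericVector size(M);
    for (int r = 0; r < M; ++r) size[r] = (double)S.out_size[r];
    return List::create(_["models"] = models, _["sse"] = sse, _["size"] = size);
  }
  if (!S.have_best) stop("search space is empty under the given bounds");
  IntegerVector wit(net.E);
  for (int g = 0; g < net.E; ++g) wit[g] = S.best_sel[g];
  return List::create(_["sse_opt"] = S.best_sse, _["size_opt"] = (double)S.best_size,
                      _["witness"] = wit);
}
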