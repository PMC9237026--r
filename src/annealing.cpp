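#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Simulated-annealing maximisation of directed Newman modularity
//   Q = sum_c [ W_c / m  -  Sout_c * Sin_c / m^2 ]
// with W_c the total weight of links inside community c and Sout/Sin the
// community out-/in-strength sums. Proposals: single-node moves (to the
// community of another node or to a fresh empty community), merges of two
// communities, and random bipartition splits. Metropolis acceptance on
// dQ (dQ >= 0 always accepted). All randomness flows through R's RNG, so
// results are reproducible under set.seed().

namespace {

struct Net {
  int n;
  double m;
  std::vector<std::vector<std::pair<int,double> > > out_adj, in_adj;
  std::vector<double> sout, sin;
};

struct State {
  std::vector<int> comm;                  // node -> community slot
  std::vector<double> Sout, Sin, W;       // per-slot aggregates
  std::vector<std::vector<int> > members; // per-slot member lists
  std::vector<int> nonempty;              // list of nonempty slots
  std::vector<int> slot_pos;              // slot -> index in nonempty, -1 if empty
  std::vector<int> empty_stack;           // lazily maintained empty slots
  double q;
};

inline int ru(int k) {                    // uniform integer in [0, k)
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// weight between node v and community c members (both directions, self
// excluded); c membership read from state.comm
double node_comm_weight(const Net &net, const State &st, int v, int c) {
  double e = 0.0;
  for (size_t i = 0; i < net.out_adj[v].size(); ++i) {
    int u = net.out_adj[v][i].first;
    if (u != v && st.comm[u] == c) e += net.out_adj[v][i].second;
  }
  for (size_t i = 0; i < net.in_adj[v].size(); ++i) {
    int u = net.in_adj[v][i].first;
    if (u != v && st.comm[u] == c) e += net.in_adj[v][i].second;
  }
  return e;
}

double move_dq(const Net &net, const State &st, int v, int b) {
  int a = st.comm[v];
  double so = net.sout[v], si = net.sin[v], m = net.m;
  double ea = node_comm_weight(net, st, v, a);
  double eb = node_comm_weight(net, st, v, b);
  double da = -so * st.Sin[a] - si * st.Sout[a] + so * si; // v leaves a
  double db =  so * st.Sin[b] + si * st.Sout[b] + so * si; // v joins b
  return (eb - ea) / m - (da + db) / (m * m);
}

void set_nonempty(State &st, int c, bool now_nonempty) {
  if (now_nonempty && st.slot_pos[c] < 0) {
    st.slot_pos[c] = (int)st.nonempty.size();
    st.nonempty.push_back(c);
  } else if (!now_nonempty && st.slot_pos[c] >= 0) {
    int pos = st.slot_pos[c];
    int last = st.nonempty.back();
    st.nonempty[pos] = last;
    st.slot_pos[last] = pos;
    st.nonempty.pop_back();
    st.slot_pos[c] = -1;
    st.empty_stack.push_back(c);
  }
}

void apply_move(const Net &net, State &st, int v, int b, double dq) {
  int a = st.comm[v];
  double self = 0.0;
  for (size_t i = 0; i < net.out_adj[v].size(); ++i)
    if (net.out_adj[v][i].first == v) self += net.out_adj[v][i].second;
  double ea = node_comm_weight(net, st, v, a);
  double eb = node_comm_weight(net, st, v, b);
  st.W[a] -= ea + self;
  st.W[b] += eb + self;
  st.Sout[a] -= net.sout[v]; st.Sin[a] -= net.sin[v];
  st.Sout[b] += net.sout[v]; st.Sin[b] += net.sin[v];
  std::vector<int> &ma = st.members[a];
  for (size_t i = 0; i < ma.size(); ++i)
    if (ma[i] == v) { ma[i] = ma.back(); ma.pop_back(); break; }
  st.members[b].push_back(v);
  st.comm[v] = b;
  if (ma.empty()) set_nonempty(st, a, false);
  set_nonempty(st, b, true);
  st.q += dq;
}

// cross weight between communities a and b (both directions)
double comm_comm_weight(const Net &net, const State &st, int a, int b) {
  const std::vector<int> &src =
      st.members[a].size() <= st.members[b].size() ? st.members[a] : st.members[b];
  int other = (&src == &st.members[a]) ? b : a;
  double e = 0.0;
  for (size_t k = 0; k < src.size(); ++k) {
    int v = src[k];
    for (size_t i = 0; i < net.out_adj[v].size(); ++i)
      if (st.comm[net.out_adj[v][i].first] == other) e += net.out_adj[v][i].second;
    for (size_t i = 0; i < net.in_adj[v].size(); ++i)
      if (st.comm[net.in_adj[v][i].first] == other) e += net.in_adj[v][i].second;
  }
  return e;
}

double merge_dq(const Net &net, const State &st, int a, int b) {
  double m = net.m;
  return comm_comm_weight(net, st, a, b) / m -
         (st.Sout[a] * st.Sin[b] + st.Sout[b] * st.Sin[a]) / (m * m);
}

void apply_merge(const Net &net, State &st, int a, int b, double dq) {
  st.W[a] += st.W[b] + comm_comm_weight(net, st, a, b);
  st.W[b] = 0.0;
  st.Sout[a] += st.Sout[b]; st.Sin[a] += st.Sin[b];
  st.Sout[b] = 0.0; st.Sin[b] = 0.0;
  for (size_t k = 0; k < st.members[b].size(); ++k) {
    st.comm[st.members[b][k]] = a;
    st.members[a].push_back(st.members[b][k]);
  }
  st.members[b].clear();
  set_nonempty(st, b, false);
  st.q += dq;
}

int find_empty_slot(State &st) {
  // lazy cleanup: slots re-occupied since being pushed are skipped
  while (!st.empty_stack.empty() && st.slot_pos[st.empty_stack.back()] >= 0)
    st.empty_stack.pop_back();
  return st.empty_stack.empty() ? -1 : st.empty_stack.back();
}

double full_q(const Net &net, const State &st) {
  double q = 0.0;
  for (size_t c = 0; c < st.W.size(); ++c)
    q += st.W[c] / net.m - st.Sout[c] * st.Sin[c] / (net.m * net.m);
  return q;
}

} // namespace

// [[Rcpp::export(name = ".anneal_modularity")]]
List anneal_modularity(int n, IntegerVector from, IntegerVector to,
                       NumericVector w, double t0, double cooling,
                       double proposal_factor, int patience, int max_temps) {
  Net net;
  net.n = n;
  net.m = 0.0;
  net.out_adj.resize(n); net.in_adj.resize(n);
  net.sout.assign(n, 0.0); net.sin.assign(n, 0.0);
  for (int e = 0; e < from.size(); ++e) {
    int a = from[e], b = to[e];
    double we = w[e];
    net.out_adj[a].push_back(std::make_pair(b, we));
    net.in_adj[b].push_back(std::make_pair(a, we));
    net.sout[a] += we; net.sin[b] += we;
    net.m += we;
  }

  State st;
  st.comm.resize(n);
  st.Sout.assign(n, 0.0); st.Sin.assign(n, 0.0); st.W.assign(n, 0.0);
  st.members.resize(n);
  st.slot_pos.assign(n, -1);
  for (int v = 0; v < n; ++v) {           // singleton start
    st.comm[v] = v;
    st.members[v].push_back(v);
    st.Sout[v] = net.sout[v]; st.Sin[v] = net.sin[v];
    for (size_t i = 0; i < net.out_adj[v].size(); ++i)
      if (net.out_adj[v][i].first == v) st.W[v] += net.out_adj[v][i].second;
    set_nonempty(st, v, true);
  }
  st.q = full_q(net, st);

  RNGScope scope;

  // T0 calibration: mean |dQ| of 100 random worsening single-node moves,
  // scaled so the initial acceptance of a mean-size bad move is ~0.5
  if (t0 <= 0.0) {
    double acc = 0.0; int cnt = 0;
    for (int i = 0; i < 100 && n > 1; ++i) {
      int v = ru(n);
      int u = ru(n);
      if (u == v) continue;
      double dq = move_dq(net, st, v, st.comm[u]);
      if (dq < 0) { acc += -dq; ++cnt; }
    }
    t0 = cnt > 0 ? (acc / cnt) / std::log(2.0) : 1e-3;
    if (t0 <= 0.0) t0 = 1e-3;
  }

  std::vector<int> best_comm = st.comm;
  double best_q = st.q;
  int proposals = std::max(16, (int)(proposal_factor * n * n));
  double T = t0;
  int stale = 0;
  std::vector<double> trace_T, trace_q;
  std::vector<int> scratch(n, 0);

  for (int temp = 0; temp < max_temps && stale < patience; ++temp) {
    for (int it = 0; it < proposals; ++it) {
      double r = unif_rand();
      if (r < 0.90 || n < 2) {
        // single-node move: target = community of a random other node,
        // or (10% of the time) a fresh empty community
        int v = ru(n);
        int b;
        if (unif_rand() < 0.10) {
          b = find_empty_slot(st);
          if (b < 0) continue;
        } else {
          int u = ru(n);
          b = st.comm[u];
        }
        if (b == st.comm[v]) continue;
        double dq = move_dq(net, st, v, b);
        if (dq >= 0 || unif_rand() < std::exp(dq / T))
          apply_move(net, st, v, b, dq);
      } else if (r < 0.95) {
        // merge two random communities
        if (st.nonempty.size() < 2) continue;
        int ia = ru((int)st.nonempty.size());
        int ib = ru((int)st.nonempty.size());
        if (ia == ib) continue;
        int a = st.nonempty[ia], b = st.nonempty[ib];
        double dq = merge_dq(net, st, a, b);
        if (dq >= 0 || unif_rand() < std::exp(dq / T))
          apply_merge(net, st, a, b, dq);
      } else {
        // split: random bipartition of a random community
        int c = st.nonempty[ru((int)st.nonempty.size())];
        std::vector<int> &mem = st.members[c];
        if (mem.size() < 2) continue;
        int d = find_empty_slot(st);
        if (d < 0) continue;
        std::vector<int> part;
        for (size_t k = 0; k < mem.size(); ++k)
          if (unif_rand() < 0.5) part.push_back(mem[k]);
        if (part.empty() || part.size() == mem.size()) continue;
        // dQ of detaching `part` into empty slot d = -(merge dQ of the halves)
        for (size_t k = 0; k < part.size(); ++k) st.comm[part[k]] = d;
        double cross = 0.0, so = 0.0, si = 0.0;
        for (size_t k = 0; k < part.size(); ++k) {
          int v = part[k];
          so += net.sout[v]; si += net.sin[v];
          for (size_t i = 0; i < net.out_adj[v].size(); ++i)
            if (st.comm[net.out_adj[v][i].first] == c)
              cross += net.out_adj[v][i].second;
          for (size_t i = 0; i < net.in_adj[v].size(); ++i)
            if (st.comm[net.in_adj[v][i].first] == c)
              cross += net.in_adj[v][i].second;
        }
        double m = net.m;
        double dq = -(cross / m -
                      (so * (st.Sin[c] - si) + (st.Sout[c] - so) * si) / (m * m));
        if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
          // commit: move aggregates of `part` from c to d
          double wd = 0.0; // internal weight of part (self + within-part)
          for (size_t k = 0; k < part.size(); ++k) {
            int v = part[k];
            for (size_t i = 0; i < net.out_adj[v].size(); ++i)
              if (st.comm[net.out_adj[v][i].first] == d)
                wd += net.out_adj[v][i].second;
          }
          st.W[d] = wd;
          st.W[c] -= wd + cross;
          st.Sout[d] = so;  st.Sin[d] = si;
          st.Sout[c] -= so; st.Sin[c] -= si;
          std::vector<int> keep;
          keep.reserve(mem.size() - part.size());
          for (size_t k = 0; k < mem.size(); ++k)
            if (st.comm[mem[k]] == c) keep.push_back(mem[k]);
          st.members[c].swap(keep);
          st.members[d].assign(part.begin(), part.end());
          set_nonempty(st, d, true);
          st.q += dq;
        } else {
          for (size_t k = 0; k < part.size(); ++k) st.comm[part[k]] = c;
        }
      }
      if (st.q > best_q + 1e-12) {
        best_q = st.q;
        best_comm = st.comm;
        stale = -1; // reset below after temperature loop accounting
      }
    }
    trace_T.push_back(T);
    trace_q.push_back(best_q);
    stale = (stale == -1) ? 0 : stale + 1;
    T *= cooling;
  }
  (void)scratch;

  return List::create(_["q"] = best_q,
                      _["comm"] = IntegerVector(best_comm.begin(), best_comm.end()),
                      _["t0"] = t0,
                      _["trace_temperature"] = NumericVector(trace_T.begin(), trace_T.end()),
                      _["trace_best_q"] = NumericVector(trace_q.begin(), trace_q.end()));
}

// Curveball randomization on the columns of a binary matrix: each trade
// picks two columns and re-deals their non-shared rows at random, leaving
// every row and column sum unchanged.
// When fix_diagonal is true, an exclusive row equal to either traded
// column's index is pinned to its current column, so cell (i, i) can
// neither gain nor lose a 1: cannibal links are neither created nor
// destroyed by the randomization.
// [[Rcpp::export(name = ".curveball_cpp")]]
IntegerMatrix curveball_cpp(IntegerMatrix A, int n_trades, bool fix_diagonal) {
  int nr = A.nrow(), nc = A.ncol();
  std::vector<std::vector<int> > cols(nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (A(i, j) != 0) cols[j].push_back(i);

  RNGScope scope;
  std::vector<char> in2(nr, 0);
  for (int t = 0; t < n_trades; ++t) {
    if (nc < 2) break;
    int j1 = ru(nc), j2 = ru(nc);
    if (j1 == j2) continue;
    std::vector<int> &c1 = cols[j1], &c2 = cols[j2];
    for (size_t k = 0; k < c2.size(); ++k) in2[c2[k]] = 1;
    std::vector<int> only1, shared1;
    for (size_t k = 0; k < c1.size(); ++k) {
      int row = c1[k];
      if (in2[row]) { shared1.push_back(row); in2[row] = 2; }
      else if (fix_diagonal && (row == j1 || row == j2)) shared1.push_back(row);
      else only1.push_back(row);
    }
    std::vector<int> only2, pinned2;
    for (size_t k = 0; k < c2.size(); ++k) {
      int row = c2[k];
      if (in2[row] == 1) {
        if (fix_diagonal && (row == j1 || row == j2)) pinned2.push_back(row);
        else only2.push_back(row);
      }
      in2[row] = 0;
    }
    if (!only1.empty() && !only2.empty()) {
      std::vector<int> pool(only1);
      pool.insert(pool.end(), only2.begin(), only2.end());
      // Fisher-Yates with R's RNG
      for (int k = (int)pool.size() - 1; k > 0; --k) {
        int idx = ru(k + 1);
        std::swap(pool[k], pool[idx]);
      }
      // rows present in both columns (truly shared) stay in both; rows
      // pinned for the diagonal stay only where they were
      std::vector<char> was2(in2.size(), 0);
      // rebuild: recompute true shared = rows in both original columns
      c1.assign(shared1.begin(), shared1.end());
      c1.insert(c1.end(), pool.begin(), pool.begin() + only1.size());
      std::vector<int> newc2;
      for (size_t k = only1.size(); k < pool.size(); ++k)
        newc2.push_back(pool[k]);
      for (size_t k = 0; k < c2.size(); ++k) {
        int row = c2[k];
        bool traded = false;
        for (size_t t2 = 0; t2 < only2.size(); ++t2)
          if (only2[t2] == row) { traded = true; break; }
        if (!traded) newc2.push_back(row);   // shared or pinned rows remain
      }
      c2.swap(newc2);
      (void)was2; (void)pinned2;
    }
  }

  IntegerMatrix B(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (size_t k = 0; k < cols[j].size(); ++k)
      B(cols[j][k], j) = 1;
  B.attr("dimnames") = A.attr("dimnames");
  return B;
}
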