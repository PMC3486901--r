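// Event-driven core of the reticulum simulator.
//
// The network is a fixed set of L edges whose 2L endpoint slots are grouped
// into nodes of degree 1 (tip), 2 (bulk) or 3 (branching point).  Four
// elementary events rewrite the node partition; edges are never created or
// destroyed.  Nodes are ephemeral: each event deletes the participating
// nodes and allocates fresh ones.  Per-degree registries with swap-removal
// give O(1) sampling and update per event.  All randomness comes from R's
// RNG (unif_rand / exp_rand) so set.seed() controls runs exactly.

#include <Rcpp.h>
#include <array>
#include <vector>

using namespace Rcpp;

struct Net {
  int L;
  std::vector<int> slot_node;               // 2L slots -> node id
  std::vector<std::array<int, 3>> node_slots;
  std::vector<int> node_deg;                // 0 marks a free id
  std::vector<int> free_ids;
  std::vector<int> reg1, reg2, reg3;        // node ids by degree
  std::vector<int> reg_pos;                 // index of a node in its registry
  double t;
  bool absorbed;
};

static inline std::vector<int>& registry(Net& N, int deg) {
  return deg == 1 ? N.reg1 : (deg == 2 ? N.reg2 : N.reg3);
}

static int new_node(Net& N, int deg, int s0, int s1 = -1, int s2 = -1) {
  int id;
  if (!N.free_ids.empty()) {
    id = N.free_ids.back();
    N.free_ids.pop_back();
  } else {
    id = (int) N.node_deg.size();
    N.node_deg.push_back(0);
    N.node_slots.push_back({-1, -1, -1});
    N.reg_pos.push_back(-1);
  }
  N.node_deg[id] = deg;
  N.node_slots[id] = {s0, s1, s2};
  std::vector<int>& reg = registry(N, deg);
  N.reg_pos[id] = (int) reg.size();
  reg.push_back(id);
  if (s0 >= 0) N.slot_node[s0] = id;
  if (s1 >= 0) N.slot_node[s1] = id;
  if (s2 >= 0) N.slot_node[s2] = id;
  return id;
}

static void del_node(Net& N, int id) {
  std::vector<int>& reg = registry(N, N.node_deg[id]);
  int p = N.reg_pos[id];
  int last = reg.back();
  reg[p] = last;
  N.reg_pos[last] = p;
  reg.pop_back();
  N.node_deg[id] = 0;
  N.free_ids.push_back(id);
}

static inline int pick(int n) {
  int k = (int) (unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
SEXP ns_new_cpp(int L, std::string init) {
  if (L < 1) stop("L must be >= 1");
  Net* N = new Net();
  N->L = L;
  N->slot_node.assign(2 * L, -1);
  N->t = 0.0;
  N->absorbed = false;
  if (init == "fragmented") {
    for (int e = 0; e < L; ++e) {
      new_node(*N, 1, 2 * e);
      new_node(*N, 1, 2 * e + 1);
    }
  } else if (init == "chain" || init == "loop") {
    // edge e occupies slots 2e (left) and 2e+1 (right); bulk nodes join
    // right slot of e with left slot of e+1
    for (int e = 0; e + 1 < L; ++e) new_node(*N, 2, 2 * e + 1, 2 * (e + 1));
    if (init == "chain") {
      if (L == 1) {
        new_node(*N, 1, 0);
        new_node(*N, 1, 1);
      } else {
        new_node(*N, 1, 0);
        new_node(*N, 1, 2 * L - 1);
      }
    } else {
      new_node(*N, 2, 2 * L - 1, 0);
    }
  } else {
    delete N;
    stop("unknown initial state '%s'", init.c_str());
  }
  XPtr<Net> ptr(N, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector ns_census_cpp(SEXP net) {
  XPtr<Net> N(net);
  return IntegerVector::create((int) N->reg1.size(), (int) N->reg2.size(),
                               (int) N->reg3.size());
}

// [[Rcpp::export]]
double ns_time_cpp(SEXP net) {
  XPtr<Net> N(net);
  return N->t;
}

static void do_fuse_tip_tip(Net& N) {
  int n1 = (int) N.reg1.size();
  int i = pick(n1), j;
  do { j = pick(n1); } while (j == i);
  int a = N.reg1[i], b = N.reg1[j];
  int sa = N.node_slots[a][0], sb = N.node_slots[b][0];
  del_node(N, a);
  del_node(N, b);
  new_node(N, 2, sa, sb);
}

static void do_fiss_tip_tip(Net& N) {
  int id = N.reg2[pick((int) N.reg2.size())];
  int s0 = N.node_slots[id][0], s1 = N.node_slots[id][1];
  del_node(N, id);
  new_node(N, 1, s0);
  new_node(N, 1, s1);
}

static void do_fuse_tip_side(Net& N) {
  int tip = N.reg1[pick((int) N.reg1.size())];
  int bulk = N.reg2[pick((int) N.reg2.size())];
  int s = N.node_slots[tip][0];
  int p0 = N.node_slots[bulk][0], p1 = N.node_slots[bulk][1];
  del_node(N, tip);
  del_node(N, bulk);
  new_node(N, 3, s, p0, p1);
}

static void do_fiss_tip_side(Net& N) {
  int id = N.reg3[pick((int) N.reg3.size())];
  int k = pick(3);  // scission across one of the 3 incident edges
  std::array<int, 3> sl = N.node_slots[id];
  del_node(N, id);
  new_node(N, 1, sl[k]);
  new_node(N, 2, sl[(k + 1) % 3], sl[(k + 2) % 3]);
}

// total propensities of the four event types at the current census
static void props(const Net& N, double a1, double a2, double b, double* A) {
  double x1 = (double) N.reg1.size();
  double x2 = (double) N.reg2.size();
  double x3 = (double) N.reg3.size();
  A[0] = a1 * x1 * (x1 - 1.0);  // tip-to-tip fusion
  A[1] = b * x2;                // tip-to-tip fission
  A[2] = a2 * x1 * x2;          // tip-to-side fusion
  A[3] = 1.5 * b * x3;          // tip-to-side fission (b2 = 3/2 b per node)
}

// executes one event; returns event code 1..4 or 0 if absorbing
static int one_step(Net& N, double a1, double a2, double b) {
  double A[4];
  props(N, a1, a2, b, A);
  double tot = A[0] + A[1] + A[2] + A[3];
  if (tot <= 0.0) {
    N.absorbed = true;
    return 0;
  }
  N.t += exp_rand() / tot;
  double u = unif_rand() * tot;
  int ev;
  if (u < A[0]) ev = 1;
  else if (u < A[0] + A[1]) ev = 2;
  else if (u < A[0] + A[1] + A[2]) ev = 3;
  else ev = 4;
  switch (ev) {
    case 1: do_fuse_tip_tip(N); break;
    case 2: do_fiss_tip_tip(N); break;
    case 3: do_fuse_tip_side(N); break;
    case 4: do_fiss_tip_side(N); break;
  }
  return ev;
}

// [[Rcpp::export]]
List ns_step_cpp(SEXP net, double a1, double a2, double b) {
  XPtr<Net> N(net);
  double t0 = N->t;
  int ev = one_step(*N, a1, a2, b);
  return List::create(_["event"] = ev, _["dt"] = ev == 0 ? NA_REAL : N->t - t0,
                      _["absorbed"] = (ev == 0));
}

// [[Rcpp::export]]
List ns_advance_cpp(SEXP net, double a1, double a2, double b, double n_events) {
  XPtr<Net> N(net);
  double t0 = N->t;
  std::array<double, 4> counts = {0, 0, 0, 0};
  double done = 0;
  bool absorbed = false;
  for (double k = 0; k < n_events; ++k) {
    int ev = one_step(*N, a1, a2, b);
    if (ev == 0) { absorbed = true; break; }
    counts[ev - 1] += 1;
    done += 1;
  }
  return List::create(
      _["events"] = done, _["elapsed"] = N->t - t0, _["absorbed"] = absorbed,
      _["event_counts"] = NumericVector(counts.begin(), counts.end()));
}

// [[Rcpp::export]]
IntegerMatrix ns_snapshot_cpp(SEXP net) {
  XPtr<Net> N(net);
  IntegerMatrix m(N->L, 2);
  for (int e = 0; e < N->L; ++e) {
    m(e, 0) = N->slot_node[2 * e] + 1;
    m(e, 1) = N->slot_node[2 * e + 1] + 1;
  }
  return m;
}

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }
};

// Per-cluster edge count j and segment count r.  r is derived from the
// degree census inside the cluster, r = (x1 + 3*x3)/2, with the pure-loop
// cluster (no non-bulk node) counting as a single segment.
// [[Rcpp::export]]
List ns_cluster_stats_cpp(SEXP net) {
  XPtr<Net> N(net);
  int L = N->L;
  UF uf(L);
  int n_nodes = (int) N->node_deg.size();
  for (int id = 0; id < n_nodes; ++id) {
    int d = N->node_deg[id];
    if (d < 2) continue;
    int e0 = N->node_slots[id][0] / 2;
    for (int k = 1; k < d; ++k) uf.unite(e0, N->node_slots[id][k] / 2);
  }
  std::vector<int> root_index(L, -1);
  std::vector<int> j, ends;
  for (int e = 0; e < L; ++e) {
    int r = uf.find(e);
    if (root_index[r] < 0) {
      root_index[r] = (int) j.size();
      j.push_back(0);
      ends.push_back(0);
    }
    j[root_index[r]] += 1;
  }
  for (int id = 0; id < n_nodes; ++id) {
    int d = N->node_deg[id];
    if (d == 1 || d == 3) {
      int c = root_index[uf.find(N->node_slots[id][0] / 2)];
      ends[c] += d;  // a degree-d non-bulk node terminates d segment ends
    }
  }
  int nc = (int) j.size();
  IntegerVector jv(nc), rv(nc);
  int jmax = 0, imax = 0;
  for (int c = 0; c < nc; ++c) {
    jv[c] = j[c];
    rv[c] = ends[c] > 0 ? ends[c] / 2 : 1;
    if (j[c] > jmax) { jmax = j[c]; imax = c; }
  }
  double susc = NA_REAL;
  if (nc > 1) {
    double s = 0;
    for (int c = 0; c < nc; ++c) if (c != imax) s += rv[c];
    susc = s / (nc - 1);
  }
  return List::create(_["j"] = jv, _["r"] = rv,
                      _["largest_fraction"] = (double) jmax / L,
                      _["susceptibility"] = susc);
}

// Segment lengths and types.  A segment is a maximal run of edges joined
// only through bulk (degree-2) nodes; its type is the pair of end-node
// degrees: 11, 13, 33, or 22 for a disconnected loop.
// [[Rcpp::export]]
List ns_segment_census_cpp(SEXP net) {
  XPtr<Net> N(net);
  int L = N->L;
  std::vector<bool> visited(L, false);
  std::vector<int> len, type;
  int n_nodes = (int) N->node_deg.size();
  for (int id = 0; id < n_nodes; ++id) {
    int d = N->node_deg[id];
    if (d != 1 && d != 3) continue;
    for (int k = 0; k < d; ++k) {
      int s = N->node_slots[id][k];
      if (visited[s / 2]) continue;
      int cur = s, n = 0, end_deg;
      for (;;) {
        visited[cur / 2] = true;
        ++n;
        int other = cur ^ 1;
        int nd = N->slot_node[other];
        if (N->node_deg[nd] != 2) { end_deg = N->node_deg[nd]; break; }
        const std::array<int, 3>& sl = N->node_slots[nd];
        cur = (sl[0] == other) ? sl[1] : sl[0];
      }
      len.push_back(n);
      int lo = d < end_deg ? d : end_deg, hi = d < end_deg ? end_deg : d;
      type.push_back(10 * lo + hi);
    }
  }
  for (int e = 0; e < L; ++e) {  // leftovers are pure loops
    if (visited[e]) continue;
    int cur = 2 * e, n = 0;
    for (;;) {
      visited[cur / 2] = true;
      ++n;
      int other = cur ^ 1;
      int nd = N->slot_node[other];
      const std::array<int, 3>& sl = N->node_slots[nd];
      cur = (sl[0] == other) ? sl[1] : sl[0];
      if (cur / 2 == e) break;
    }
    len.push_back(n);
    type.push_back(22);
  }
  return List::create(_["length"] = IntegerVector(len.begin(), len.end()),
                      _["type"] = IntegerVector(type.begin(), type.end()));
}

// truncated pair convolution g_i = sum_{j=1}^{i-1} u_j u_{i-j}, i = 1..L
// [[Rcpp::export]]
NumericVector pair_convolve_cpp(NumericVector u) {
  int L = u.size();
  NumericVector g(L);
  for (int i = 2; i <= L; ++i) {
    double s = 0;
    int half = i / 2;
    for (int j = 1; j <= half; ++j) {
      double term = u[j - 1] * u[i - j - 1];
      s += (j == i - j) ? term : 2.0 * term;
    }
    g[i - 1] = s;
  }
  return g;
}
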