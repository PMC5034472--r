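// Compute-intensive kernels: Wagner (ordered-character) parsimony scoring by
// interval dynamic programming, greedy stepwise addition, NNI hill climbing,
// and the exact rectilinear Steiner tree solver (Hanan grid + Dreyfus-Wagner).

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <queue>
#include <set>
#include <utility>
#include <vector>

using namespace Rcpp;

typedef long long ll;
static const ll LLINF = (ll)4e18;

// ---------------------------------------------------------------------------
// Wagner parsimony up-pass
// ---------------------------------------------------------------------------

struct UpResult {
  std::vector<int> lo, hi;      // node-major N x d interval bounds
  std::vector<ll> m;            // minimal subtree cost at/below each node
  std::vector<int> parent;      // -1 root, -2 unreached
  std::vector<int> order;       // children-before-parents
  ll weight;
};

static void dfs_order(const std::vector<std::vector<int> >& adj, int root,
                      std::vector<int>& order, std::vector<int>& parent) {
  const int N = (int)adj.size();
  order.clear();
  order.reserve(N);
  parent.assign(N, -2);
  std::vector<int> st;
  st.push_back(root);
  parent[root] = -1;
  while (!st.empty()) {
    int v = st.back();
    st.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int w = adj[v][i];
      if (parent[w] == -2) {
        parent[w] = v;
        st.push_back(w);
      }
    }
  }
  std::reverse(order.begin(), order.end());
}

static inline ll igap(int x, int lo, int hi) {
  if (x < lo) return lo - x;
  if (x > hi) return x - hi;
  return 0;
}

// labels: node-major N*d; hasLabel: nodes pinned to their pattern.
// For an unlabeled node the per-probe state interval minimising the sum of
// distances to the children's intervals is [e_(k), e_(k+1)] of the 2k sorted
// interval endpoints; a labeled node is pinned to [x, x] and pays the gap to
// each child interval. Total weight = sum over probes of m at the root.
static void wagner_up_core(const std::vector<std::vector<int> >& adj,
                           const std::vector<int>& labels,
                           const std::vector<char>& hasLabel,
                           int N, int d, int root, UpResult& R) {
  dfs_order(adj, root, R.order, R.parent);
  R.lo.assign((size_t)N * d, 0);
  R.hi.assign((size_t)N * d, 0);
  R.m.assign((size_t)N * d, 0);
  std::vector<int> ends;
  std::vector<int> kids;
  for (size_t oi = 0; oi < R.order.size(); ++oi) {
    int v = R.order[oi];
    kids.clear();
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int c = adj[v][i];
      if (R.parent[c] == v) kids.push_back(c);
    }
    for (int j = 0; j < d; ++j) {
      ll msum = 0;
      if (hasLabel[v]) {
        int x = labels[(size_t)v * d + j];
        for (size_t ci = 0; ci < kids.size(); ++ci) {
          int c = kids[ci];
          msum += R.m[(size_t)c * d + j] +
                  igap(x, R.lo[(size_t)c * d + j], R.hi[(size_t)c * d + j]);
        }
        R.lo[(size_t)v * d + j] = x;
        R.hi[(size_t)v * d + j] = x;
        R.m[(size_t)v * d + j] = msum;
      } else {
        int k = (int)kids.size();
        if (k == 0) stop("unlabeled leaf in topology");
        ends.clear();
        for (size_t ci = 0; ci < kids.size(); ++ci) {
          int c = kids[ci];
          ends.push_back(R.lo[(size_t)c * d + j]);
          ends.push_back(R.hi[(size_t)c * d + j]);
          msum += R.m[(size_t)c * d + j];
        }
        std::sort(ends.begin(), ends.end());
        int L = ends[k - 1], H = ends[k];
        for (size_t ci = 0; ci < kids.size(); ++ci) {
          int c = kids[ci];
          msum += igap(L, R.lo[(size_t)c * d + j], R.hi[(size_t)c * d + j]);
        }
        R.lo[(size_t)v * d + j] = L;
        R.hi[(size_t)v * d + j] = H;
        R.m[(size_t)v * d + j] = msum;
      }
    }
  }
  R.weight = 0;
  for (int j = 0; j < d; ++j) R.weight += R.m[(size_t)root * d + j];
}

static std::vector<std::vector<int> > adjacency_from(
    const std::vector<std::array<int, 2> >& ed, int N) {
  std::vector<std::vector<int> > adj(N);
  for (size_t e = 0; e < ed.size(); ++e) {
    adj[ed[e][0]].push_back(ed[e][1]);
    adj[ed[e][1]].push_back(ed[e][0]);
  }
  return adj;
}

static ll score_edges(const std::vector<std::array<int, 2> >& ed,
                      const std::vector<int>& labels,
                      const std::vector<char>& hasLabel,
                      int N, int d, int root, UpResult& scratch) {
  std::vector<std::vector<int> > adj = adjacency_from(ed, N);
  wagner_up_core(adj, labels, hasLabel, N, d, root, scratch);
  return scratch.weight;
}

static void labels_node_major(const IntegerMatrix& labels,
                              std::vector<int>& out) {
  int N = labels.nrow(), d = labels.ncol();
  out.assign((size_t)N * d, 0);
  for (int v = 0; v < N; ++v)
    for (int j = 0; j < d; ++j) out[(size_t)v * d + j] = labels(v, j);
}

// [[Rcpp::export]]
List wagner_up_cpp(IntegerMatrix edges, IntegerMatrix labels,
                   LogicalVector hasLabel, int root) {
  int N = labels.nrow(), d = labels.ncol();
  if (root < 1 || root > N) stop("root out of range");
  std::vector<std::array<int, 2> > ed(edges.nrow());
  for (int e = 0; e < edges.nrow(); ++e) {
    ed[e][0] = edges(e, 0) - 1;
    ed[e][1] = edges(e, 1) - 1;
  }
  std::vector<int> lab;
  labels_node_major(labels, lab);
  std::vector<char> has(N);
  for (int v = 0; v < N; ++v) has[v] = hasLabel[v] ? 1 : 0;
  std::vector<std::vector<int> > adj = adjacency_from(ed, N);
  UpResult R;
  wagner_up_core(adj, lab, has, N, d, root - 1, R);
  IntegerMatrix lo(N, d), hi(N, d);
  NumericMatrix m(N, d);
  for (int v = 0; v < N; ++v)
    for (int j = 0; j < d; ++j) {
      lo(v, j) = R.lo[(size_t)v * d + j];
      hi(v, j) = R.hi[(size_t)v * d + j];
      m(v, j) = (double)R.m[(size_t)v * d + j];
    }
  IntegerVector parent(N), order(R.order.size());
  for (int v = 0; v < N; ++v)
    parent[v] = R.parent[v] == -2 ? NA_INTEGER : R.parent[v] + 1;
  for (size_t i = 0; i < R.order.size(); ++i) order[i] = R.order[i] + 1;
  return List::create(_["weight"] = (double)R.weight, _["lo"] = lo,
                      _["hi"] = hi, _["m"] = m, _["parent"] = parent,
                      _["order"] = order);
}

// [[Rcpp::export]]
double score_topology_cpp(IntegerMatrix edges, IntegerMatrix labels,
                          LogicalVector hasLabel, int root) {
  int N = labels.nrow(), d = labels.ncol();
  std::vector<std::array<int, 2> > ed(edges.nrow());
  for (int e = 0; e < edges.nrow(); ++e) {
    ed[e][0] = edges(e, 0) - 1;
    ed[e][1] = edges(e, 1) - 1;
  }
  std::vector<int> lab;
  labels_node_major(labels, lab);
  std::vector<char> has(N);
  for (int v = 0; v < N; ++v) has[v] = hasLabel[v] ? 1 : 0;
  UpResult scratch;
  return (double)score_edges(ed, lab, has, N, d, root - 1, scratch);
}

// ---------------------------------------------------------------------------
// Greedy stepwise addition
// ---------------------------------------------------------------------------

// Tips are inserted in the given order; each next tip is attached (via a new
// internal node) to the edge minimising the Wagner score of the grown tree.
// Ties keep the earliest edge in creation order, so the result is
// deterministic for a fixed order.
// [[Rcpp::export]]
IntegerMatrix stepwise_cpp(IntegerMatrix tipLabels, IntegerVector order) {
  int n = order.size(), d = tipLabels.ncol();
  if (n < 3) stop("stepwise addition needs at least 3 tips");
  int N = 2 * n - 2;
  std::vector<int> lab((size_t)N * d, 0);
  std::vector<char> has(N, 0);
  for (int i = 0; i < n; ++i) {
    has[i] = 1;
    for (int j = 0; j < d; ++j) lab[(size_t)i * d + j] = tipLabels(i, j);
  }
  std::vector<std::array<int, 2> > ed;
  int c0 = n;  // first internal node (0-based)
  std::array<int, 2> e1 = {{order[0] - 1, c0}};
  std::array<int, 2> e2 = {{order[1] - 1, c0}};
  std::array<int, 2> e3 = {{order[2] - 1, c0}};
  ed.push_back(e1);
  ed.push_back(e2);
  ed.push_back(e3);
  UpResult scratch;
  int root = order[0] - 1;
  for (int i = 3; i < n; ++i) {
    int leaf = order[i] - 1;
    int w = n + i - 2;  // new internal node, 0-based
    ll best = LLINF;
    int bestE = -1;
    size_t mEdges = ed.size();
    for (size_t e = 0; e < mEdges; ++e) {
      int u = ed[e][0], v = ed[e][1];
      ed[e][1] = w;
      std::array<int, 2> add1 = {{w, v}};
      std::array<int, 2> add2 = {{w, leaf}};
      ed.push_back(add1);
      ed.push_back(add2);
      ll sc = score_edges(ed, lab, has, N, d, root, scratch);
      ed.pop_back();
      ed.pop_back();
      ed[e][1] = v;
      ed[e][0] = u;
      if (sc < best) {
        best = sc;
        bestE = (int)e;
      }
    }
    int v = ed[bestE][1];
    ed[bestE][1] = w;
    std::array<int, 2> add1 = {{w, v}};
    std::array<int, 2> add2 = {{w, leaf}};
    ed.push_back(add1);
    ed.push_back(add2);
  }
  IntegerMatrix out(ed.size(), 2);
  for (size_t e = 0; e < ed.size(); ++e) {
    out(e, 0) = ed[e][0] + 1;
    out(e, 1) = ed[e][1] + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// NNI hill climbing
// ---------------------------------------------------------------------------

// Best-improvement nearest-neighbor-interchange search on an unrooted binary
// topology; deterministic (first of tied best swaps in edge order).
// [[Rcpp::export]]
List nni_cpp(IntegerMatrix edgesIn, IntegerMatrix tipLabels, int nTips,
             int maxRounds) {
  int d = tipLabels.ncol();
  int N = 2 * nTips - 2;
  std::vector<int> lab((size_t)N * d, 0);
  std::vector<char> has(N, 0);
  for (int i = 0; i < nTips; ++i) {
    has[i] = 1;
    for (int j = 0; j < d; ++j) lab[(size_t)i * d + j] = tipLabels(i, j);
  }
  std::vector<std::array<int, 2> > ed(edgesIn.nrow());
  for (int e = 0; e < edgesIn.nrow(); ++e) {
    ed[e][0] = edgesIn(e, 0) - 1;
    ed[e][1] = edgesIn(e, 1) - 1;
  }
  UpResult scratch;
  int root = 0;  // tip 1 is always present
  ll cur = score_edges(ed, lab, has, N, d, root, scratch);
  int rounds = 0;
  while (rounds < maxRounds) {
    ll bestSc = cur;
    int bestE = -1, bestEa = -1, bestEb = -1;
    for (size_t e = 0; e < ed.size(); ++e) {
      int u = ed[e][0], v = ed[e][1];
      if (u < nTips || v < nTips) continue;  // need an internal edge
      // neighbors of u (other than v) and of v (other than u), with the
      // indices of the edges carrying them
      int ea[2], an[2], eb[2], bn[2], na = 0, nb = 0;
      for (size_t f = 0; f < ed.size(); ++f) {
        if (f == e) continue;
        int a = ed[f][0], b = ed[f][1];
        if (a == u || b == u) {
          if (na < 2) {
            ea[na] = (int)f;
            an[na] = (a == u) ? b : a;
            ++na;
          }
        } else if (a == v || b == v) {
          if (nb < 2) {
            eb[nb] = (int)f;
            bn[nb] = (a == v) ? b : a;
            ++nb;
          }
        }
      }
      if (na != 2 || nb != 2) continue;
      for (int s = 0; s < 2; ++s) {
        // swap subtree an[1] (on u) with bn[s] (on v)
        int fe = ea[1], ge = eb[s];
        int aOld = an[1], bOld = bn[s];
        for (int k = 0; k < 2; ++k) {
          if (ed[fe][k] == aOld) ed[fe][k] = bOld;
          if (ed[ge][k] == bOld) ed[ge][k] = aOld;
        }
        ll sc = score_edges(ed, lab, has, N, d, root, scratch);
        for (int k = 0; k < 2; ++k) {
          if (ed[fe][k] == bOld) ed[fe][k] = aOld;
          if (ed[ge][k] == aOld) ed[ge][k] = bOld;
        }
        if (sc < bestSc) {
          bestSc = sc;
          bestE = (int)e;
          bestEa = fe;
          bestEb = ge;
        }
      }
    }
    if (bestE < 0) break;
    // re-identify the swap end-points and apply permanently
    int u = ed[bestE][0];
    int aOld = ed[bestEa][0] == u ? ed[bestEa][1] : ed[bestEa][0];
    int v = ed[bestE][1];
    int bOld = ed[bestEb][0] == v ? ed[bestEb][1] : ed[bestEb][0];
    for (int k = 0; k < 2; ++k) {
      if (ed[bestEa][k] == aOld) ed[bestEa][k] = bOld;
      if (ed[bestEb][k] == bOld) ed[bestEb][k] = aOld;
    }
    cur = bestSc;
    ++rounds;
  }
  IntegerMatrix out(ed.size(), 2);
  for (size_t e = 0; e < ed.size(); ++e) {
    out(e, 0) = ed[e][0] + 1;
    out(e, 1) = ed[e][1] + 1;
  }
  return List::create(_["edges"] = out, _["score"] = (double)cur,
                      _["rounds"] = rounds);
}

// ---------------------------------------------------------------------------
// Exact rectilinear Steiner tree: Hanan grid + Dreyfus-Wagner subset DP
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List exact_steiner_cpp(IntegerMatrix term, int maxVertices) {
  int t = term.nrow(), d = term.ncol();
  if (t < 2) stop("need at least 2 terminals");
  // Hanan grid
  std::vector<std::vector<int> > vals(d);
  for (int j = 0; j < d; ++j) {
    std::vector<int> v(t);
    for (int i = 0; i < t; ++i) v[i] = term(i, j);
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    vals[j] = v;
  }
  std::vector<int> k(d), stride(d);
  ll V = 1;
  for (int j = 0; j < d; ++j) {
    k[j] = (int)vals[j].size();
    stride[j] = (int)V;
    V *= k[j];
    if (V > maxVertices) stop("Hanan grid exceeds the vertex limit");
  }
  int nV = (int)V;
  std::vector<int> termVid(t);
  for (int i = 0; i < t; ++i) {
    int vid = 0;
    for (int j = 0; j < d; ++j) {
      int idx = (int)(std::lower_bound(vals[j].begin(), vals[j].end(),
                                       term(i, j)) -
                      vals[j].begin());
      vid += idx * stride[j];
    }
    termVid[i] = vid;
  }
  // DW over subsets of terminals 0..t-2, rooted at terminal t-1
  int q = t - 1;
  int nsub = 1 << (t - 1);
  int full = nsub - 1;
  std::vector<std::vector<ll> > f(nsub);
  std::vector<std::vector<signed char> > ptype(nsub);
  std::vector<std::vector<int> > pred(nsub);
  // singletons: distance in the grid equals the L1 distance
  for (int i = 0; i < t - 1; ++i) {
    int S = 1 << i;
    f[S].assign(nV, 0);
    ptype[S].assign(nV, 0);
    pred[S].assign(nV, i);
    for (int v = 0; v < nV; ++v) {
      ll dist = 0;
      for (int j = 0; j < d; ++j) {
        int idx = (v / stride[j]) % k[j];
        dist += std::abs(vals[j][idx] - term(i, j));
      }
      f[S][v] = dist;
    }
  }
  typedef std::pair<ll, int> QE;
  for (int S = 1; S <= full; ++S) {
    if (__builtin_popcount(S) < 2) continue;
    f[S].assign(nV, LLINF);
    ptype[S].assign(nV, 0);
    pred[S].assign(nV, -1);
    for (int v = 0; v < nV; ++v) {
      for (int sub = (S - 1) & S; sub; sub = (sub - 1) & S) {
        if (sub > (S ^ sub)) continue;  // each split once
        ll c = f[sub][v] + f[S ^ sub][v];
        if (c < f[S][v]) {
          f[S][v] = c;
          ptype[S][v] = 1;
          pred[S][v] = sub;
        }
      }
    }
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    for (int v = 0; v < nV; ++v)
      if (f[S][v] < LLINF) pq.push(QE(f[S][v], v));
    while (!pq.empty()) {
      QE top = pq.top();
      pq.pop();
      ll dv = top.first;
      int v = top.second;
      if (dv > f[S][v]) continue;
      for (int j = 0; j < d; ++j) {
        int idx = (v / stride[j]) % k[j];
        if (idx + 1 < k[j]) {
          int u = v + stride[j];
          ll nd = dv + (vals[j][idx + 1] - vals[j][idx]);
          if (nd < f[S][u]) {
            f[S][u] = nd;
            ptype[S][u] = 2;
            pred[S][u] = v;
            pq.push(QE(nd, u));
          }
        }
        if (idx > 0) {
          int u = v - stride[j];
          ll nd = dv + (vals[j][idx] - vals[j][idx - 1]);
          if (nd < f[S][u]) {
            f[S][u] = nd;
            ptype[S][u] = 2;
            pred[S][u] = v;
            pq.push(QE(nd, u));
          }
        }
      }
    }
  }
  ll W = f[full][termVid[q]];
  // backtrack, collecting unit grid edges
  std::set<std::pair<int, int> > eset;
  std::vector<std::pair<int, int> > stck;
  stck.push_back(std::make_pair(full, termVid[q]));
  while (!stck.empty()) {
    int S = stck.back().first;
    int v = stck.back().second;
    stck.pop_back();
    while (ptype[S][v] == 2) {
      int u = pred[S][v];
      eset.insert(std::make_pair(std::min(u, v), std::max(u, v)));
      v = u;
    }
    if (ptype[S][v] == 1) {
      int sub = pred[S][v];
      stck.push_back(std::make_pair(sub, v));
      stck.push_back(std::make_pair(S ^ sub, v));
    } else {
      // singleton: walk a canonical monotone grid path to the terminal
      int i = pred[S][v];
      int cur = v;
      for (int j = 0; j < d; ++j) {
        int tgt = (termVid[i] / stride[j]) % k[j];
        int idx = (cur / stride[j]) % k[j];
        while (idx != tgt) {
          int nxt = cur + (tgt > idx ? stride[j] : -stride[j]);
          eset.insert(
              std::make_pair(std::min(cur, nxt), std::max(cur, nxt)));
          cur = nxt;
          idx += (tgt > idx ? 1 : -1);
        }
      }
    }
  }
  // compact the used vertices
  std::set<int> used;
  for (std::set<std::pair<int, int> >::iterator it = eset.begin();
       it != eset.end(); ++it) {
    used.insert(it->first);
    used.insert(it->second);
  }
  for (int i = 0; i < t; ++i) used.insert(termVid[i]);
  std::vector<int> vids(used.begin(), used.end());
  std::vector<int> where(nV, -1);
  for (size_t i = 0; i < vids.size(); ++i) where[vids[i]] = (int)i;
  IntegerMatrix coords((int)vids.size(), d);
  for (size_t i = 0; i < vids.size(); ++i)
    for (int j = 0; j < d; ++j)
      coords(i, j) = vals[j][(vids[i] / stride[j]) % k[j]];
  IntegerMatrix eout((int)eset.size(), 2);
  IntegerVector elen((int)eset.size());
  int e = 0;
  for (std::set<std::pair<int, int> >::iterator it = eset.begin();
       it != eset.end(); ++it, ++e) {
    int a = where[it->first], b = where[it->second];
    eout(e, 0) = a + 1;
    eout(e, 1) = b + 1;
    ll len = 0;
    for (int j = 0; j < d; ++j) len += std::abs(coords(a, j) - coords(b, j));
    elen[e] = (int)len;
  }
  IntegerVector termIndex(t);
  for (int i = 0; i < t; ++i) termIndex[i] = where[termVid[i]] + 1;
  return List::create(_["weight"] = (double)W, _["coords"] = coords,
                      _["edges"] = eout, _["lengths"] = elen,
                      _["term_index"] = termIndex);
}
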