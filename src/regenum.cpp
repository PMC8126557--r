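// Exhaustive generation of connected pairwise nonisomorphic k-regular graphs.
//
// Strategy: depth-first search over partial graphs in which every vertex
// carries a remaining-capacity colour c(v) = k - deg(v).  At each step the
// vertex with the smallest positive capacity (ties: lowest index) is
// saturated in every admissible way; isomorphic partial states are pruned
// through a memo table keyed by a canonical certificate of the
// capacity-coloured graph.  Two capacity-coloured partial graphs with the
// same certificate have isomorphic sets of completions, so expanding one
// representative per class is exhaustive.  Regular but disconnected
// completions are pruned as soon as a saturated component seals itself off.
//
// The certificate is computed per connected component (isolated vertices are
// only counted): equitable refinement of the capacity partition followed by
// individualisation backtracking, taking the lexicographically maximal
// adjacency encoding over all discrete partitions reached.  Components are
// small (N <= 28), so the search stays cheap even for the rare symmetric
// states.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_set>
#include <vector>
#include <algorithm>

using std::string;
using std::vector;

namespace {

inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// ---- canonical certificate of a capacity-coloured component ----------------

struct ComponentCanon {
  int m;                       // component order
  vector<uint32_t> adj;        // local adjacency bitmasks
  vector<int> col;             // local colours (capacities)
  vector<uint8_t> best;        // best packed adjacency bits so far
  bool have_best;
  vector<int> best_label;      // position -> local vertex for best leaf

  // equitable refinement of an ordered partition; cells stay in place
  void refine(vector<vector<int>>& cells) const {
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t t = 0; t < cells.size() && !changed; ++t) {
        uint32_t tm = 0;
        for (int v : cells[t]) tm |= (uint32_t(1) << v);
        for (size_t c = 0; c < cells.size() && !changed; ++c) {
          if (cells[c].size() <= 1) continue;
          // group members by neighbour count into the target cell
          int cnt[32];
          bool split = false;
          for (size_t i = 0; i < cells[c].size(); ++i) {
            cnt[i] = popcount32(adj[cells[c][i]] & tm);
            if (cnt[i] != cnt[0]) split = true;
          }
          if (!split) continue;
          vector<std::pair<int, int>> keyed;  // (count, vertex)
          keyed.reserve(cells[c].size());
          for (size_t i = 0; i < cells[c].size(); ++i)
            keyed.push_back({cnt[i], cells[c][i]});
          std::stable_sort(keyed.begin(), keyed.end(),
                           [](const std::pair<int, int>& a,
                              const std::pair<int, int>& b) {
                             return a.first < b.first;
                           });
          vector<vector<int>> sub;
          int prev_count = keyed[0].first - 1;
          for (auto& kv : keyed) {
            if (kv.first != prev_count) {
              sub.push_back(vector<int>());
              prev_count = kv.first;
            }
            sub.back().push_back(kv.second);
          }
          // rebuild the ordered partition with cell c replaced in place
          vector<vector<int>> out;
          out.reserve(cells.size() + sub.size() - 1);
          for (size_t j = 0; j < cells.size(); ++j) {
            if (j == c)
              for (auto& s : sub) out.push_back(s);
            else
              out.push_back(cells[j]);
          }
          cells.swap(out);
          changed = true;
        }
      }
    }
  }

  void leaf(const vector<vector<int>>& cells) {
    vector<int> label(m);
    for (int p = 0; p < m; ++p) label[p] = cells[p][0];
    // pack upper-triangular adjacency bits row-wise under this labelling
    int nbits = m * (m - 1) / 2;
    vector<uint8_t> bits((nbits + 7) / 8, 0);
    int b = 0;
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j, ++b)
        if (adj[label[i]] & (uint32_t(1) << label[j]))
          bits[b >> 3] |= (uint8_t(1) << (b & 7));
    if (!have_best || bits > best) {
      best = bits;
      best_label = label;
      have_best = true;
    }
  }

  void descend(vector<vector<int>> cells) {
    refine(cells);
    size_t i = 0;
    while (i < cells.size() && cells[i].size() == 1) ++i;
    if (i == cells.size()) {
      leaf(cells);
      return;
    }
    for (int v : cells[i]) {
      vector<vector<int>> nxt;
      nxt.reserve(cells.size() + 1);
      for (size_t j = 0; j < i; ++j) nxt.push_back(cells[j]);
      nxt.push_back(vector<int>{v});
      vector<int> rest;
      for (int w : cells[i])
        if (w != v) rest.push_back(w);
      nxt.push_back(rest);
      for (size_t j = i + 1; j < cells.size(); ++j) nxt.push_back(cells[j]);
      descend(std::move(nxt));
    }
  }

  // returns the certificate string: [m][colour histogram by cell][bits]
  string run() {
    have_best = false;
    // initial ordered partition: group by colour, ascending
    vector<int> order(m);
    for (int i = 0; i < m; ++i) order[i] = i;
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return col[a] < col[b]; });
    vector<vector<int>> cells;
    for (int v : order) {
      if (cells.empty() || col[cells.back()[0]] != col[v])
        cells.push_back(vector<int>());
      cells.back().push_back(v);
    }
    descend(cells);
    string s;
    s.push_back(char(m));
    // colour sequence by position is partition-invariant: record per initial
    // cell (colour value, size)
    for (int v : order) s.push_back(char(col[v]));
    s.append(reinterpret_cast<const char*>(best.data()), best.size());
    return s;
  }
};

struct Enumerator {
  int N, k;
  vector<uint32_t> adj;
  vector<int> deg;
  std::unordered_set<string> seen;
  vector<std::pair<string, vector<std::pair<int, int>>>> found;
  long long states = 0;

  Enumerator(int N_, int k_) : N(N_), k(k_), adj(N_, 0), deg(N_, 0) {}

  string certificate(vector<int>* canon_label) {
    // components over vertices with deg > 0; isolated vertices only counted
    int iso = 0;
    vector<int> comp(N, -1);
    int nc = 0;
    for (int v = 0; v < N; ++v) {
      if (deg[v] == 0) { ++iso; continue; }
      if (comp[v] >= 0) continue;
      // BFS
      vector<int> stack{v};
      comp[v] = nc;
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        uint32_t nb = adj[u];
        while (nb) {
          int w = __builtin_ctz(nb);
          nb &= nb - 1;
          if (comp[w] < 0) { comp[w] = nc; stack.push_back(w); }
        }
      }
      ++nc;
    }
    vector<string> parts(nc);
    vector<vector<int>> memb(nc);
    for (int v = 0; v < N; ++v)
      if (comp[v] >= 0) memb[comp[v]].push_back(v);
    vector<vector<int>> labels(nc);
    for (int c = 0; c < nc; ++c) {
      ComponentCanon cc;
      cc.m = (int)memb[c].size();
      cc.adj.assign(cc.m, 0);
      cc.col.assign(cc.m, 0);
      vector<int> local(N, -1);
      for (int i = 0; i < cc.m; ++i) local[memb[c][i]] = i;
      for (int i = 0; i < cc.m; ++i) {
        int v = memb[c][i];
        cc.col[i] = k - deg[v];
        uint32_t nb = adj[v];
        while (nb) {
          int w = __builtin_ctz(nb);
          nb &= nb - 1;
          cc.adj[i] |= (uint32_t(1) << local[w]);
        }
      }
      parts[c] = cc.run();
      if (canon_label) {
        labels[c].resize(cc.m);
        for (int p = 0; p < cc.m; ++p) labels[c][p] = memb[c][cc.best_label[p]];
      }
    }
    vector<int> ord(nc);
    for (int c = 0; c < nc; ++c) ord[c] = c;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return parts[a] < parts[b]; });
    string cert;
    cert.push_back(char(iso));
    for (int c : ord) {
      cert.push_back(char(2));  // component separator
      cert += parts[c];
    }
    if (canon_label) {
      canon_label->clear();
      for (int c : ord)
        for (int v : labels[c]) canon_label->push_back(v);
    }
    return cert;
  }

  bool feasible() {
    uint32_t capmask = 0;
    for (int v = 0; v < N; ++v)
      if (deg[v] < k) capmask |= (uint32_t(1) << v);
    for (int v = 0; v < N; ++v) {
      int cap = k - deg[v];
      if (cap <= 0) continue;
      uint32_t elig = capmask & ~adj[v] & ~(uint32_t(1) << v);
      if (popcount32(elig) < cap) return false;
    }
    // sealed-component check: a component with zero total capacity must span
    vector<int> comp(N, -1);
    for (int v = 0; v < N; ++v) {
      if (comp[v] >= 0) continue;
      vector<int> stack{v};
      comp[v] = v;
      int size = 0;
      int capsum = 0;
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        ++size;
        capsum += k - deg[u];
        uint32_t nb = adj[u];
        while (nb) {
          int w = __builtin_ctz(nb);
          nb &= nb - 1;
          if (comp[w] < 0) { comp[w] = v; stack.push_back(w); }
        }
      }
      if (capsum == 0 && size < N) return false;
    }
    return true;
  }

  void emit() {
    // all degrees equal k here; connectivity guaranteed by the sealed check
    vector<int> label;
    string cert = certificate(&label);
    if (!seen.insert(cert).second) return;  // already emitted this class
    // canonical edge list under the certificate labelling
    vector<int> pos(N);
    for (int p = 0; p < N; ++p) pos[label[p]] = p;
    vector<std::pair<int, int>> edges;
    for (int v = 0; v < N; ++v) {
      uint32_t nb = adj[v];
      while (nb) {
        int w = __builtin_ctz(nb);
        nb &= nb - 1;
        if (v < w) edges.push_back({std::min(pos[v], pos[w]),
                                    std::max(pos[v], pos[w])});
      }
    }
    std::sort(edges.begin(), edges.end());
    found.push_back({cert, edges});
  }

  void dfs() {
    ++states;
    if ((states & 0xFFF) == 0) Rcpp::checkUserInterrupt();
    int v = -1, bestcap = k + 1;
    for (int i = 0; i < N; ++i) {
      int cap = k - deg[i];
      if (cap > 0 && cap < bestcap) { bestcap = cap; v = i; }
    }
    if (v < 0) { emit(); return; }
    string cert = certificate(nullptr);
    if (!seen.insert(std::move(cert)).second) return;
    uint32_t capmask = 0;
    for (int i = 0; i < N; ++i)
      if (deg[i] < k) capmask |= (uint32_t(1) << i);
    uint32_t eligmask = capmask & ~adj[v] & ~(uint32_t(1) << v);
    vector<int> elig;
    for (uint32_t nb = eligmask; nb; nb &= nb - 1)
      elig.push_back(__builtin_ctz(nb));
    int c = k - deg[v];
    if ((int)elig.size() < c) return;
    vector<int> idx(c);
    // iterate over c-subsets of elig
    for (int i = 0; i < c; ++i) idx[i] = i;
    while (true) {
      for (int i = 0; i < c; ++i) {
        int w = elig[idx[i]];
        adj[v] |= (uint32_t(1) << w);
        adj[w] |= (uint32_t(1) << v);
        ++deg[v];
        ++deg[w];
      }
      if (feasible()) dfs();
      for (int i = 0; i < c; ++i) {
        int w = elig[idx[i]];
        adj[v] &= ~(uint32_t(1) << w);
        adj[w] &= ~(uint32_t(1) << v);
        --deg[v];
        --deg[w];
      }
      // next combination
      int i = c - 1;
      while (i >= 0 && idx[i] == (int)elig.size() - c + i) --i;
      if (i < 0) break;
      ++idx[i];
      for (int j = i + 1; j < c; ++j) idx[j] = idx[j - 1] + 1;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".enum_regular_cpp")]]
Rcpp::List enum_regular_cpp(int N, int k) {
  if (N < 2 || k < 1) Rcpp::stop("need N >= 2 and k >= 1");
  if (N > 28) Rcpp::stop("enumeration supports N <= 28");
  if (k >= N) Rcpp::stop("infeasible: need k <= N - 1");
  if ((N * k) % 2 != 0) Rcpp::stop("parity violation: N * k must be even");
  Enumerator e(N, k);
  e.dfs();
  std::sort(e.found.begin(), e.found.end());
  Rcpp::List out(e.found.size());
  for (size_t i = 0; i < e.found.size(); ++i) {
    const auto& edges = e.found[i].second;
    Rcpp::IntegerMatrix m((int)edges.size(), 2);
    for (size_t j = 0; j < edges.size(); ++j) {
      m(j, 0) = edges[j].first + 1;  // 1-based for R/igraph
      m(j, 1) = edges[j].second + 1;
    }
    out[i] = m;
  }
  return out;
}
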