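// Coalescing-random-walk machinery, dense path.
//
// Pairwise coalescence times tau_ij solve, for i != j,
//   tau_ij = 1 + (1/2) sum_w (p_iw tau_wj + p_jw tau_iw),  tau_ii = 0,
// with step probabilities p_iw = e_iw / k_i.  The system has C(N,2)
// unknowns and is solved densely here; the R layer provides a sparse
// fallback for large graphs (chains).  From tau_ij the remeeting times are
//   tau_i = 1 + sum_j p_ij tau_ij,
// and the effective population size is N_eff = sum_i pi_i tau_i with
// pi_i = k_i / sum_j k_j.
//
// perturb_scan removes single edges (or unordered pairs of edges) incident
// to the vertices of maximal remeeting time, skips removals that disconnect
// the graph, and recomputes N_eff on each perturbed graph.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#include <algorithm>
#include <array>
#include <vector>

using Rcpp::IntegerMatrix;
using Rcpp::List;
using Rcpp::NumericVector;
using std::vector;

namespace {

struct Graph {
  int N;
  vector<vector<int>> nb;
  Graph(const IntegerMatrix& edges, int N_) : N(N_), nb(N_) {
    for (int e = 0; e < edges.nrow(); ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      if (a < 0 || b < 0 || a >= N || b >= N || a == b)
        Rcpp::stop("invalid edge row %d", e + 1);
      nb[a].push_back(b);
      nb[b].push_back(a);
    }
  }
  bool connected() const {
    if (N == 0) return true;
    vector<char> vis(N, 0);
    vector<int> stack{0};
    vis[0] = 1;
    int cnt = 0;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      ++cnt;
      for (int w : nb[u])
        if (!vis[w]) { vis[w] = 1; stack.push_back(w); }
    }
    return cnt == N;
  }
};

inline int pair_index(int i, int j, int N) {
  // lexicographic index of the pair (i, j), i < j, both 0-based
  return i * N - i * (i + 1) / 2 + (j - i - 1);
}

// solves the coalescence system; returns remeeting times and, optionally,
// the full pair matrix
bool coalescence_core(const Graph& g, arma::vec& tau_i, arma::mat* tau_pair) {
  const int N = g.N;
  const int P = N * (N - 1) / 2;
  arma::mat M(P, P, arma::fill::zeros);
  arma::vec rhs(P, arma::fill::ones);
  for (int i = 0; i < N; ++i) {
    const double wi = 0.5 / g.nb[i].size();
    for (int j = i + 1; j < N; ++j) {
      const int p = pair_index(i, j, N);
      M(p, p) += 1.0;
      for (int w : g.nb[i]) {
        if (w == j) continue;  // tau_jj = 0
        int a = std::min(w, j), b = std::max(w, j);
        M(p, pair_index(a, b, N)) -= wi;
      }
      const double wj = 0.5 / g.nb[j].size();
      for (int w : g.nb[j]) {
        if (w == i) continue;
        int a = std::min(i, w), b = std::max(i, w);
        M(p, pair_index(a, b, N)) -= wj;
      }
    }
  }
  arma::vec tau;
  if (!arma::solve(tau, M, rhs, arma::solve_opts::no_approx)) return false;
  tau_i.set_size(N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int w : g.nb[i]) {
      int a = std::min(i, w), b = std::max(i, w);
      s += tau(pair_index(a, b, N));
    }
    tau_i(i) = 1.0 + s / g.nb[i].size();
  }
  if (tau_pair) {
    tau_pair->zeros(N, N);
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double v = tau(pair_index(i, j, N));
        (*tau_pair)(i, j) = v;
        (*tau_pair)(j, i) = v;
      }
  }
  return true;
}

double n_eff_of(const Graph& g, const arma::vec& tau_i) {
  double ksum = 0.0;
  for (int i = 0; i < g.N; ++i) ksum += g.nb[i].size();
  double s = 0.0;
  for (int i = 0; i < g.N; ++i) s += g.nb[i].size() / ksum * tau_i(i);
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".coalescence_cpp")]]
List coalescence_cpp(IntegerMatrix edges, int N) {
  Graph g(edges, N);
  for (int i = 0; i < N; ++i)
    if (g.nb[i].empty()) Rcpp::stop("vertex %d is isolated", i + 1);
  if (!g.connected())
    Rcpp::stop("coalescence undefined (singular system): graph is disconnected");
  arma::vec tau_i;
  arma::mat tau_pair;
  if (!coalescence_core(g, tau_i, &tau_pair))
    Rcpp::stop("coalescence undefined (singular system)");
  return List::create(
      Rcpp::Named("tau_pair") = tau_pair,
      Rcpp::Named("tau_remeet") = NumericVector(tau_i.begin(), tau_i.end()),
      Rcpp::Named("n_eff") = n_eff_of(g, tau_i));
}

// [[Rcpp::export(name = ".perturb_scan_cpp")]]
List perturb_scan_cpp(IntegerMatrix edges, int N, int n_remove,
                      double tie_tol) {
  if (n_remove != 1 && n_remove != 2) Rcpp::stop("n_remove must be 1 or 2");
  Graph g(edges, N);
  if (!g.connected()) Rcpp::stop("graph is disconnected");
  const size_t k = g.nb[0].size();
  for (int i = 0; i < N; ++i)
    if (g.nb[i].size() != k)
      Rcpp::stop("perturbation method is defined for regular graphs only");
  arma::vec tau_i;
  if (!coalescence_core(g, tau_i, nullptr))
    Rcpp::stop("coalescence undefined (singular system)");
  const double tmax = tau_i.max();
  vector<int> pivots;
  for (int i = 0; i < N; ++i)
    if (tau_i(i) >= tmax * (1.0 - tie_tol)) pivots.push_back(i);

  // removal candidates: single incident edges or unordered pairs of them
  vector<std::array<int, 4>> cand;  // v, w1, v, w2 (w2 = -1 for singles)
  for (int v : pivots) {
    const auto& nbv = g.nb[v];
    if (n_remove == 1) {
      for (int w : nbv) cand.push_back({v, w, -1, -1});
    } else {
      for (size_t a = 0; a < nbv.size(); ++a)
        for (size_t b = a + 1; b < nbv.size(); ++b)
          cand.push_back({v, nbv[a], v, nbv[b]});
    }
  }

  const int nc = (int)cand.size();
  Rcpp::IntegerMatrix rem(nc, 4);
  Rcpp::NumericVector neff(nc);
  Rcpp::LogicalVector conn(nc);
  for (int c = 0; c < nc; ++c) {
    Graph h = g;
    for (int s = 0; s < n_remove; ++s) {
      int a = cand[c][2 * s], b = cand[c][2 * s + 1];
      auto& na = h.nb[a];
      na.erase(std::find(na.begin(), na.end(), b));
      auto& nbv = h.nb[b];
      nbv.erase(std::find(nbv.begin(), nbv.end(), a));
    }
    rem(c, 0) = cand[c][0] + 1;
    rem(c, 1) = cand[c][1] + 1;
    rem(c, 2) = cand[c][2] >= 0 ? cand[c][2] + 1 : NA_INTEGER;
    rem(c, 3) = cand[c][3] >= 0 ? cand[c][3] + 1 : NA_INTEGER;
    if (!h.connected()) {
      conn[c] = false;
      neff[c] = NA_REAL;
      continue;
    }
    conn[c] = true;
    arma::vec ti;
    if (!coalescence_core(h, ti, nullptr))
      Rcpp::stop("singular perturbed system");
    neff[c] = n_eff_of(h, ti);
  }
  Rcpp::IntegerVector piv(pivots.size());
  for (size_t i = 0; i < pivots.size(); ++i) piv[i] = pivots[i] + 1;
  return List::create(
      Rcpp::Named("tau_remeet") = NumericVector(tau_i.begin(), tau_i.end()),
      Rcpp::Named("pivots") = piv,
      Rcpp::Named("removed") = rem,
      Rcpp::Named("n_eff") = neff,
      Rcpp::Named("connected") = conn);
}
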