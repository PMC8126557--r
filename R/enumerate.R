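#' Enumerate connected nonisomorphic k-regular graphs
#'
#' Generates every connected pairwise nonisomorphic k-regular graph of order
#' `N` exactly once, in a deterministic canonical order (sorted by the
#' graph6 string of the canonically labelled graph).  The generator performs
#' a depth-first search over capacity-coloured partial graphs with canonical
#' -form memoization, so each isomorphism class is expanded once.
#'
#' A pre-computed graph6 file (for example from an external generator) can
#' be supplied as a drop-in backend via `backend_file`; the stream is then
#' read, validated and returned in the same sorted order.
#'
#' @param N graph order; requires `N >= k + 1`.
#' @param k degree; `N * k` must be even.
#' @param backend_file optional path to a graph6 file replacing internal
#'   generation (each graph is validated to be connected and k-regular).
#' @return a list of igraph objects; `length()` equals the number of
#'   connected nonisomorphic k-regular graphs of order `N`.
#' @examples
#' length(enumerate_regular(8, 3))   # 5
#' @export
enumerate_regular <- function(N, k, backend_file = NULL) {
  N <- as.integer(N)
  k <- as.integer(k)
  if (N <= k) stop("infeasible: need N >= k + 1")
  if ((N * k) %% 2L != 0L) stop("parity violation: N * k must be even")
  if (!is.null(backend_file)) {
    graphs <- read_graph6(backend_file)
    for (g in graphs) check_graph(g, connected = TRUE, regular = k)
    if (any(vapply(graphs, igraph::vcount, numeric(1)) != N))
      stop("backend file contains graphs of the wrong order")
  } else {
    edge_lists <- .enum_regular_cpp(N, k)
    graphs <- lapply(edge_lists, graph_from_edges, n = N)
  }
  g6 <- vapply(graphs, .g6_encode_one, character(1))
  graphs[order(g6, method = "radix")]
}

#' Brute-force enumeration oracle
#'
#' Independent reference for small orders: generates every labelled
#' k-regular graph by backtracking over adjacency rows, keeps the connected
#' ones, and deduplicates isomorphism classes through igraph canonical
#' permutations (BLISS).  Exponential in `N`; intended for `N <= 8`.
#'
#' @inheritParams enumerate_regular
#' @return a list of igraph objects, one per isomorphism class.
#' @export
enumerate_regular_bruteforce <- function(N, k) {
  N <- as.integer(N)
  k <- as.integer(k)
  if (N <= k) stop("infeasible: need N >= k + 1")
  if ((N * k) %% 2L != 0L) stop("parity violation: N * k must be even")
  seen <- new.env(parent = emptyenv())
  out <- list()
  deg <- integer(N)
  adj <- matrix(FALSE, N, N)
  recurse <- function(v) {
    if (v > N) {
      g <- igraph::graph_from_adjacency_matrix(adj * 1L, mode = "undirected")
      if (!igraph::is_connected(g)) return(invisible())
      perm <- igraph::canonical_permutation(g)$labeling
      key <- .g6_encode_one(igraph::permute(g, perm))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <<- g
      }
      return(invisible())
    }
    need <- k - deg[v]
    if (need < 0) return(invisible())
    if (need == 0) return(recurse(v + 1L))
    cand <- which(seq_len(N) > v & deg < k & !adj[v, ])
    if (length(cand) < need) return(invisible())
    subsets <- if (length(cand) == 1L) list(cand)
               else utils::combn(cand, need, simplify = FALSE)
    for (S in subsets) {
      adj[v, S] <<- TRUE; adj[S, v] <<- TRUE
      deg[v] <<- deg[v] + need; deg[S] <<- deg[S] + 1L
      recurse(v + 1L)
      adj[v, S] <<- FALSE; adj[S, v] <<- FALSE
      deg[v] <<- deg[v] - need; deg[S] <<- deg[S] - 1L
    }
    invisible()
  }
  recurse(1L)
  out
}
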