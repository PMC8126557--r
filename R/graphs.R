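#' Population-structure graphs
#'
#' Graphs are plain [igraph::igraph] objects: vertices are individuals, edges
#' are interaction partners.  All analysis entry points require simple
#' connected undirected graphs; these helpers validate and construct them.
#'
#' @name transamp-graphs
NULL

#' Validate a population graph
#'
#' Checks that `g` is an undirected simple graph (no loops, no multi-edges),
#' optionally connected and optionally k-regular.
#'
#' @param g an igraph object.
#' @param connected require a single component (default `TRUE`).
#' @param regular if non-`NULL`, require all degrees equal to this value.
#' @return `g`, invisibly, after validation.
#' @export
check_graph <- function(g, connected = TRUE, regular = NULL) {
  if (!igraph::is_igraph(g)) stop("expected an igraph object")
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    stop("graph must be simple (no self-loops, no multi-edges)")
  if (connected && !igraph::is_connected(g))
    stop("graph must be connected")
  if (!is.null(regular)) {
    deg <- igraph::degree(g)
    if (any(deg != regular))
      stop(sprintf("graph must be %d-regular (vertex %d has degree %d)",
                   regular, which(deg != regular)[1], deg[deg != regular][1]))
  }
  invisible(g)
}

#' @rdname transamp-graphs
#' @param edges two-column integer matrix of 1-based vertex pairs.
#' @param n number of vertices.
#' @return an igraph object.
#' @export
graph_from_edges <- function(edges, n) {
  g <- igraph::graph_from_edgelist(cbind(as.integer(edges[, 1]),
                                         as.integer(edges[, 2])),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' @rdname transamp-graphs
#' @return `edge_matrix()`: two-column integer matrix of 1-based vertex pairs.
#' @export
edge_matrix <- function(g) {
  m <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Complete graph fixture
#'
#' @param N number of vertices (`N >= 2`).
#' @return an igraph object with `N (N - 1) / 2` edges.
#' @export
complete_graph <- function(N) {
  if (N < 2) stop("complete graph needs N >= 2")
  igraph::make_full_graph(N)
}

#' Cycle graph fixture
#'
#' @param N number of vertices (`N >= 3`).
#' @return a 2-regular igraph object with `N` edges.
#' @export
cycle_graph <- function(N) {
  if (N < 3) stop("cycle graph needs N >= 3")
  igraph::make_ring(N)
}

#' Random connected k-regular graph
#'
#' Seeded, reproducible sampler; retries until a connected realization is
#' drawn.
#'
#' @param N number of vertices.
#' @param k degree; `N * k` must be even and `k < N`.
#' @param seed integer seed making the draw reproducible.
#' @param max_tries bounded number of redraws before giving up.
#' @return a connected simple k-regular igraph object.
#' @export
random_regular <- function(N, k, seed, max_tries = 100L) {
  if ((N * k) %% 2 != 0) stop("parity violation: N * k must be even")
  if (k >= N) stop("infeasible: need k <= N - 1")
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    g <- igraph::sample_k_regular(N, k)
    if (igraph::is_connected(g) && !igraph::any_multiple(g) &&
        !igraph::any_loop(g))
      return(g)
  }
  stop(sprintf("no connected simple %d-regular graph drawn in %d tries",
               k, max_tries))
}
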