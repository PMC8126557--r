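# shared helpers and a lazy cache for expensive census objects

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# the unique amplifier constructor of a (N, k) slice, as an igraph object
unique_constructor <- function(N, k) {
  cached(sprintf("constructor_%d_%d", N, k), {
    gs <- enumerate_regular(N, k)
    hits <- Filter(function(g) perturb_search(g)$is_constructor, gs)
    stopifnot(length(hits) == 1)
    hits[[1]]
  })
}

# canonical graph6 string, for isomorphism-class comparisons
canon_g6 <- function(g) {
  perm <- igraph::canonical_permutation(g)$labeling
  write_graph6(igraph::permute(g, perm))
}

# best single-edge perturbation of a graph, as the perturbed igraph object
best_perturbed <- function(g) {
  out <- perturb_search(g)
  per <- out$per_removal
  b <- which(per$connected)[which.max(per$n_eff[per$connected])]
  igraph::delete_edges(g, igraph::get_edge_ids(g, c(per$v1[b], per$w1[b])))
}
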