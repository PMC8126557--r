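#' Chain constructions from amplifier-constructor building blocks
#'
#' Larger amplifier constructors can be assembled by chaining copies of a
#' known k-regular constructor: a head and a tail (and optionally
#' mid-sections between them).  The head drops one designated edge
#' (`head_cut`), the tail another (`tail_cut`), mid-sections drop both, and
#' consecutive blocks are joined by two connector edges pairing the
#' dangling head-side vertices of one block with the dangling tail-side
#' vertices of the next, which restores k-regularity.
#'
#' Because published drawings fix the cut and connector choices only
#' through their vertex labelling, [chain_search()] enumerates all cut and
#' connector choices for a block and reports the resulting effective
#' population sizes.
#'
#' @param block a connected k-regular igraph object.
#' @param head_cut,tail_cut length-2 vertex vectors: the edge dropped by
#'   the head (forward side) and by the tail (backward side).
#' @param connectors `c(1, 2)` or `c(2, 1)`: pairing of `head_cut`
#'   endpoints with `tail_cut` endpoints of the following block.
#' @return an object of class `chain_spec`.
#' @export
chain_spec <- function(block, head_cut, tail_cut, connectors = c(1, 2)) {
  check_graph(block, connected = TRUE)
  deg <- igraph::degree(block)
  if (length(unique(deg)) != 1) stop("chain block must be regular")
  head_cut <- as.integer(head_cut)
  tail_cut <- as.integer(tail_cut)
  n0 <- igraph::vcount(block)
  for (cut in list(head_cut, tail_cut))
    if (length(cut) != 2 || any(cut < 1) || any(cut > n0) ||
        igraph::get_edge_ids(block, cut) == 0)
      stop(sprintf("cut edge %d-%d does not exist in the block",
                   cut[1], cut[2]))
  if (all(sort(head_cut) == sort(tail_cut)))
    stop("head and tail cuts must be distinct edges")
  if (!identical(as.integer(sort(connectors)), c(1L, 2L)))
    stop("connectors must be a permutation of 1:2")
  structure(list(block = block, head_cut = head_cut, tail_cut = tail_cut,
                 connectors = as.integer(connectors),
                 k = deg[1], n0 = igraph::vcount(block)),
            class = "chain_spec")
}

#' @rdname chain_spec
#' @param spec a `chain_spec`.
#' @param n_blocks number of blocks (`>= 2`: head and tail, plus
#'   `n_blocks - 2` mid-sections).
#' @return `build_chain()`: a simple connected k-regular igraph object of
#'   order `n_blocks * vcount(block)`.
#' @examples
#' \dontrun{
#' cen <- run_census(12, 3)
#' blk <- read_graph6(cen$graph6[cen$is_constructor])[[1]]
#' sr <- chain_search(blk)            # best cut/connector choice
#' g2 <- build_chain(sr$best_spec, 2) # 24-vertex chained constructor
#' }
#' @export
build_chain <- function(spec, n_blocks) {
  stopifnot(inherits(spec, "chain_spec"))
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2) stop("chain needs head and tail (n_blocks >= 2)")
  n0 <- spec$n0
  base <- edge_matrix(spec$block)
  ekey <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  hkey <- paste(min(spec$head_cut), max(spec$head_cut))
  tkey <- paste(min(spec$tail_cut), max(spec$tail_cut))
  rows <- list()
  for (b in seq_len(n_blocks)) {
    off <- (b - 1L) * n0
    keep <- rep(TRUE, nrow(base))
    key <- ekey(base)
    if (b < n_blocks) keep <- keep & key != hkey   # head + mids drop forward
    if (b > 1L) keep <- keep & key != tkey         # tail + mids drop backward
    rows[[length(rows) + 1L]] <- base[keep, , drop = FALSE] + off
    if (b < n_blocks) {
      off2 <- b * n0
      rows[[length(rows) + 1L]] <- rbind(
        c(spec$head_cut[1] + off, spec$tail_cut[spec$connectors[1]] + off2),
        c(spec$head_cut[2] + off, spec$tail_cut[spec$connectors[2]] + off2))
    }
  }
  edges <- do.call(rbind, rows)
  if (anyDuplicated(ekey(edges)))
    stop("chain construction yields a multi-edge")
  g <- graph_from_edges(edges, n_blocks * n0)
  deg <- igraph::degree(g)
  if (any(deg != spec$k))
    stop(sprintf("chain is not %d-regular: vertex %d has degree %d",
                 spec$k, which(deg != spec$k)[1], deg[deg != spec$k][1]))
  if (!igraph::is_connected(g))
    stop("chain construction yields a disconnected graph")
  g
}

#' @rdname chain_spec
#' @param n_blocks number of blocks used during the search (default 2).
#' @param progress print progress.
#' @return `chain_search()`: list with `table` (one row per
#'   symmetry-inequivalent cut/connector choice: cuts, connector order,
#'   chain `max_tau`, best perturbed `n_eff`) and `best_spec`, the
#'   `chain_spec` maximizing the perturbed effective population size.
#' @export
chain_search <- function(block, n_blocks = 2L, progress = FALSE) {
  check_graph(block, connected = TRUE)
  edges <- edge_matrix(block)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  best <- NULL
  best_neff <- -Inf
  for (hi in seq_len(nrow(edges))) for (ti in seq_len(nrow(edges))) {
    if (hi == ti) next
    for (conn in list(c(1L, 2L), c(2L, 1L))) {
      spec <- chain_spec(block, edges[hi, ], edges[ti, ], conn)
      g <- tryCatch(build_chain(spec, n_blocks), error = function(e) NULL)
      if (is.null(g)) next
      perm <- igraph::canonical_permutation(g)$labeling
      key <- .g6_encode_one(igraph::permute(g, perm))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out <- perturb_search(g)
      rows[[length(rows) + 1L]] <- data.frame(
        head_cut = paste(edges[hi, ], collapse = "-"),
        tail_cut = paste(edges[ti, ], collapse = "-"),
        connectors = paste(conn, collapse = ""),
        max_tau = max(out$tau_remeet),
        n_eff_best = out$best_n_eff,
        is_constructor = out$is_constructor)
      if (isTRUE(out$best_n_eff > best_neff)) {
        best_neff <- out$best_n_eff
        best <- spec
      }
      if (progress)
        message(sprintf("chain %s | %s | %s: n_eff %.4f",
                        rows[[length(rows)]]$head_cut,
                        rows[[length(rows)]]$tail_cut,
                        rows[[length(rows)]]$connectors, best_neff))
    }
  }
  list(table = do.call(rbind, rows), best_spec = best)
}
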