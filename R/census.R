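#' Census of regular graphs as amplifier constructors
#'
#' Runs the full pipeline over every connected nonisomorphic k-regular
#' graph of order N: coalescence system, edge-removal perturbation at the
#' maximum-remeeting vertex, normalized-Laplacian spectrum, and (optionally,
#' for constructors) the transient-amplification range r_max from exact
#' fixation probabilities.  One row per graph, in the canonical enumeration
#' order, so repeated runs produce identical tables.
#'
#' @param N graph order.
#' @param k degree.
#' @param n_remove edges removed at the pivot (1 or 2).
#' @param fixation compute `r_max` for constructors (`"constructors"`),
#'   for no graphs (`"none"`, default), or all graphs (`"all"`).
#' @param fixation_cap skip the fixation stage (with a warning) when `N`
#'   exceeds this cap.
#' @param graphs optional pre-enumerated list of igraph objects (e.g. from
#'   [read_graph6()]); defaults to [enumerate_regular()].
#' @param checkpoint optional CSV path; completed rows are appended after
#'   every `checkpoint_every` graphs and a rerun resumes after the last
#'   complete row.
#' @param checkpoint_every flush interval for checkpointing.
#' @return a `data.frame` with columns `graph6`, `n`, `k`, `max_tau`,
#'   `var_tau`, `lambda2`, `entropy`, `n_eff_best`, `is_constructor`,
#'   `removed_edges` (best removal, `v-w` within and `;` between edges) and
#'   `r_max` (NA where not computed), with attributes `L` (census size) and
#'   `A` (number of constructors).
#' @examples
#' \dontrun{
#' cen <- run_census(12, 3)
#' attr(cen, "A")    # 1 constructor among the 85 cubic graphs of order 12
#' }
#' @export
run_census <- function(N, k, n_remove = 1L,
                       fixation = c("none", "constructors", "all"),
                       fixation_cap = 14L, graphs = NULL,
                       checkpoint = NULL, checkpoint_every = 200L) {
  fixation <- match.arg(fixation)
  if (is.null(graphs)) graphs <- enumerate_regular(N, k)
  rows <- vector("list", length(graphs))
  start <- 1L
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read.csv(checkpoint, stringsAsFactors = FALSE)
    if (nrow(done) > 0) {
      rows[seq_len(nrow(done))] <- split(done, seq_len(nrow(done)))
      start <- nrow(done) + 1L
    }
  }
  do_fix <- fixation != "none"
  if (do_fix && N > fixation_cap) {
    warning(sprintf("fixation stage skipped: order %d exceeds cap %d",
                    N, fixation_cap))
    do_fix <- FALSE
  }
  for (i in seq(from = start, length.out = length(graphs) - start + 1L)) {
    g <- graphs[[i]]
    out <- perturb_search(g, n_remove = n_remove)
    spec <- normalized_laplacian_spectrum(g)
    per <- out$per_removal
    ok <- per$connected
    best_row <- if (any(ok)) which(ok)[which.max(per$n_eff[ok])] else NA
    removed <- if (is.na(best_row)) "" else {
      e1 <- sprintf("%d-%d", per$v1[best_row], per$w1[best_row])
      if (!is.na(per$v2[best_row]))
        paste(e1, sprintf("%d-%d", per$v2[best_row], per$w2[best_row]),
              sep = ";")
      else e1
    }
    r_max <- NA_real_
    if (do_fix && (fixation == "all" ||
                   (fixation == "constructors" && out$is_constructor))) {
      h <- .remove_edges(g, per, best_row)
      r_max <- find_r_max(h)$r_max
    }
    rows[[i]] <- data.frame(
      graph6 = .g6_encode_one(g), n = N, k = k,
      max_tau = max(out$tau_remeet),
      var_tau = stats::var(out$tau_remeet),
      lambda2 = spec$lambda2, entropy = spec$entropy,
      n_eff_best = out$best_n_eff,
      is_constructor = out$is_constructor,
      removed_edges = removed, r_max = r_max,
      stringsAsFactors = FALSE)
    if (!is.null(checkpoint) &&
        (i %% checkpoint_every == 0L || i == length(graphs))) {
      flushed <- do.call(rbind, rows[seq_len(i)])
      write.csv(flushed, checkpoint, row.names = FALSE)
    }
  }
  census <- do.call(rbind, rows)
  rownames(census) <- NULL
  attr(census, "L") <- nrow(census)
  attr(census, "A") <- sum(census$is_constructor)
  census
}

.remove_edges <- function(g, per, row) {
  rem <- rbind(c(per$v1[row], per$w1[row]),
               if (!is.na(per$v2[row])) c(per$v2[row], per$w2[row]))
  ids <- igraph::get_edge_ids(g, t(rem))
  igraph::delete_edges(g, ids)
}

#' Census summary counts
#'
#' @param census a census table from [run_census()].
#' @return list with `L` (number of graphs), `A` (constructors) and the
#'   ratio `A/L`.
#' @export
census_summary <- function(census) {
  L <- nrow(census)
  A <- sum(census$is_constructor)
  list(L = L, A = A, ratio = A / L)
}

#' Export scatter and density tables from a census
#'
#' Writes the figure-level data as plain CSV files: remeeting-time scatter
#' (variance and maximum versus `N_eff/N`), spectral-gap and entropy
#' scatters, the `N_eff/N` versus `r_max` relation (when computed), and the
#' smoothed family densities with the constructor/rest family distances.
#'
#' @param census census table from [run_census()].
#' @param dir output directory (created if missing).
#' @param graphs optional list of igraph objects matching the census rows;
#'   defaults to decoding the `graph6` column.
#' @return invisibly, the list of written file paths.
#' @export
export_figure_data <- function(census, dir, graphs = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  N <- census$n[1]
  k <- census$k[1]
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, sprintf("%s_N%d_k%d.csv", name, N, k))
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  ratio <- census$n_eff_best / census$n
  put(data.frame(n_eff_ratio = ratio, var_tau = census$var_tau,
                 max_tau = census$max_tau,
                 is_constructor = census$is_constructor),
      "remeeting_scatter")
  put(data.frame(n_eff_ratio = ratio, lambda2 = census$lambda2,
                 max_tau = census$max_tau, entropy = census$entropy,
                 is_constructor = census$is_constructor),
      "spectral_scatter")
  if (any(!is.na(census$r_max)))
    put(data.frame(n_eff_ratio = ratio, r_max = census$r_max,
                   is_constructor = census$is_constructor)[
          !is.na(census$r_max), ],
        "rmax_scatter")
  if (any(census$is_constructor)) {
    if (is.null(graphs)) graphs <- read_graph6(census$graph6)
    grid <- density_grid()
    fam_all <- family_spectral(graphs, grid)
    fam_cons <- family_spectral(graphs[census$is_constructor], grid)
    fam_rest <- family_spectral(graphs[!census$is_constructor], grid)
    put(data.frame(x = grid, all = fam_all$density,
                   constructors = fam_cons$density,
                   rest = fam_rest$density,
                   kesten_mckay = kesten_mckay_density(grid, k)),
        "family_density")
    put(data.frame(
      comparison = c("constructors_vs_all", "rest_vs_all",
                     "constructors_vs_rest"),
      distance = c(family_distance(fam_cons, fam_all),
                   family_distance(fam_rest, fam_all),
                   family_distance(fam_cons, fam_rest))),
        "family_distance")
  } else {
    warning("no constructors in slice: family density export skipped")
  }
  invisible(paths)
}
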