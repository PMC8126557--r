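#!/usr/bin/env Rscript

# Chains of amplifier constructors: head + tail (+ mid-sections).
#
# Searches all cut/connector choices for two-block chains built from the
# two smallest constructors, then extends the best choice with mid-sections
# and tracks N_eff/N as the chain grows.  The ratio peaks for short chains
# and decays toward 1 from above: the single-edge perturbation loses its
# leverage as the isothermal limit takes over.
#
# Chain lengths default to orders up to ~120 vertices so the script stays
# in the minutes range; raise `max_blocks` to follow the decay further
# (the coalescence solve switches to a sparse path for large orders).

suppressPackageStartupMessages(library(transamp))

max_blocks <- 10L
args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 2 && args[1] == "--max-blocks")
  max_blocks <- as.integer(args[2])

out_dir <- "results/chains"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

locate <- function(N, k) {
  gs <- enumerate_regular(N, k)
  hits <- Filter(function(g) perturb_search(g)$is_constructor, gs)
  hits[[1]]
}

for (spec in list(c(11, 4), c(12, 3))) {
  N0 <- spec[1]; k <- spec[2]
  blk <- locate(N0, k)
  message(sprintf("block: %d-regular constructor of order %d", k, N0))
  sr <- chain_search(blk, n_blocks = 2)
  write.csv(sr$table,
            file.path(out_dir, sprintf("two_block_search_N%d_k%d.csv",
                                       N0, k)),
            row.names = FALSE)
  message(sprintf("  %d inequivalent two-block chains; best N_eff = %.4f",
                  nrow(sr$table), max(sr$table$n_eff_best, na.rm = TRUE)))
  rows <- lapply(2:max_blocks, function(m) {
    g <- build_chain(sr$best_spec, m)
    out <- perturb_search(g)
    message(sprintf("  blocks = %2d (N = %3d): N_eff/N = %.6f (%s)",
                    m, igraph::vcount(g),
                    out$best_n_eff / igraph::vcount(g),
                    if (out$is_constructor) "constructor" else "no"))
    data.frame(blocks = m, N = igraph::vcount(g),
               max_tau = max(out$tau_remeet),
               n_eff_best = out$best_n_eff,
               ratio = out$best_n_eff / igraph::vcount(g),
               is_constructor = out$is_constructor)
  })
  write.csv(do.call(rbind, rows),
            file.path(out_dir, sprintf("chain_growth_N%d_k%d.csv", N0, k)),
            row.names = FALSE)
}
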