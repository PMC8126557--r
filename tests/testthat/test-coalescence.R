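test_that("pairwise coalescence times match closed forms", {
  # K2: the single equation collapses to tau = 1
  s <- coalescence_times(complete_graph(2))
  expect_equal(s$tau_pair[1, 2], 1, tolerance = 1e-12)
  # complete graphs: tau_ij = N - 1 off the diagonal
  for (N in c(4, 7)) {
    s <- coalescence_times(complete_graph(N))
    off <- s$tau_pair[upper.tri(s$tau_pair)]
    expect_equal(off, rep(N - 1, length(off)), tolerance = 1e-10)
    expect_equal(s$tau_remeet, rep(N, N), tolerance = 1e-10)
  }
  # cycles: tau_ij = d (N - d) with d the cycle distance
  for (N in c(5, 8)) {
    s <- coalescence_times(cycle_graph(N))
    for (i in 1:(N - 1)) for (j in (i + 1):N) {
      d <- min(j - i, N - (j - i))
      expect_equal(s$tau_pair[i, j], d * (N - d), tolerance = 1e-10)
    }
    expect_equal(s$tau_remeet, rep(N, N), tolerance = 1e-10)
  }
})

test_that("identity condition and isothermal property hold on regular graphs", {
  cases <- list(complete_graph(6), cycle_graph(9),
                random_regular(12, 3, seed = 2),
                random_regular(14, 4, seed = 3),
                random_regular(10, 5, seed = 4))
  for (g in cases) {
    s <- coalescence_times(g)
    expect_equal(sum(s$pi^2 * s$tau_remeet), 1, tolerance = 1e-9)
    expect_equal(s$n_eff, s$n, tolerance = 1e-9)
    expect_equal(mean(s$tau_remeet), s$n, tolerance = 1e-9)
    expect_true(all(s$tau_pair >= 0))
    expect_equal(s$tau_pair, t(s$tau_pair))
  }
})

test_that("linear-system times agree with the simulated half-lazy walk", {
  g <- random_regular(6, 3, seed = 5)
  s <- coalescence_times(g)
  for (pair in list(c(1, 2), c(1, 6))) {
    est <- simulate_coalescence_time(g, pair[1], pair[2],
                                     reps = 4e4, seed = 11)
    truth <- s$tau_pair[pair[1], pair[2]]
    # 4 sigma of the Monte Carlo error, meeting times are roughly
    # exponential so sd is about the mean
    expect_lt(abs(est - truth), 4 * truth / sqrt(4e4))
  }
})

test_that("sparse and dense solvers agree", {
  g <- random_regular(16, 3, seed = 6)
  dense <- coalescence_times(g)
  sparse <- transamp:::.solve_coalescence_sparse(g, igraph::degree(g))
  expect_equal(sparse$tau_pair, dense$tau_pair, tolerance = 1e-9)
  expect_equal(sparse$tau_remeet, dense$tau_remeet, tolerance = 1e-9)
})

test_that("summary accessors expose the documented quantities", {
  s <- coalescence_times(complete_graph(5))
  expect_equal(remeeting_times(s), rep(5, 5), tolerance = 1e-10)
  expect_equal(effective_population_size(s), 5, tolerance = 1e-10)
  st <- remeeting_statistics(s)
  expect_equal(unname(st), c(5, 0, 5), tolerance = 1e-10)
})

test_that("degenerate inputs raise the documented errors", {
  disconnected <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  expect_error(coalescence_times(disconnected), "connected")
  expect_error(perturb_search(igraph::delete_edges(complete_graph(4), 1)),
               "regular")
})

test_that("removing one edge from K4 lowers the effective size below 4", {
  g <- igraph::delete_edges(complete_graph(4), 1)
  expect_lt(coalescence_times(g)$n_eff, 4)
})

test_that("perturbation search rejects K5 and accepts the quartic N=11
           constructor with its four symmetric removals", {
  out <- perturb_search(complete_graph(5))
  expect_false(out$is_constructor)
  expect_true(all(out$per_removal$n_eff < 5))

  g <- unique_constructor(11, 4)
  out <- perturb_search(g)
  expect_true(out$is_constructor)
  expect_equal(nrow(out$per_removal), 4)
  expect_true(all(out$per_removal$connected))
  expect_equal(round(out$per_removal$n_eff, 4), rep(11.0008, 4))
})

test_that("first-order perturbation estimate has the exact sign", {
  g <- unique_constructor(11, 4)
  out <- perturb_search(g)
  expect_true(all(out$per_removal$delta_first_order > 0))
  base <- coalescence_times(g)
  expect_identical(first_order_delta(base, NULL), 0)
  # K5: all remeeting times are equal, so the first-order term vanishes
  # exactly even though the exact change of N_eff is negative
  k5 <- perturb_search(complete_graph(5))
  expect_lt(max(abs(k5$per_removal$delta_first_order)), 1e-12)
  expect_true(all(k5$per_removal$n_eff - 5 < 0))
})

test_that("two-edge removals work simultaneously and sequentially", {
  g <- unique_constructor(11, 4)
  sim <- perturb_search(g, n_remove = 2, mode = "simultaneous")
  expect_equal(nrow(sim$per_removal), choose(4, 2))
  expect_true(all(is.finite(sim$per_removal$n_eff[sim$per_removal$connected])))
  seqd <- perturb_search(g, n_remove = 2, mode = "sequential")
  expect_true(nrow(seqd$per_removal) >= 1)
  # every recorded perturbed graph in either mode is connected or skipped
  expect_true(all(!is.na(seqd$per_removal$n_eff[seqd$per_removal$connected])))
})
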