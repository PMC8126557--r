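test_that("chain preconditions are enforced", {
  blk <- unique_constructor(12, 3)
  e <- edge_matrix(blk)
  spec <- chain_spec(blk, e[1, ], e[5, ])
  expect_error(build_chain(spec, 1), "head and tail")
  expect_error(chain_spec(blk, e[1, ], e[1, ]), "distinct")
  expect_error(chain_spec(blk, c(1, 99), e[2, ]), "does not exist")
})

test_that("two chained copies of the quartic N=11 constructor give a
           connected 4-regular graph of order 22, and some cut/connector
           choice reproduces the published chain values", {
  blk <- unique_constructor(11, 4)
  sr <- cached("chain_search_q11", chain_search(blk, n_blocks = 2))
  tab <- sr$table
  # every built chain satisfies the construction contract
  g <- build_chain(sr$best_spec, 2)
  expect_equal(igraph::vcount(g), 22)
  expect_silent(check_graph(g, regular = 4))
  # the drawn construction (tau 33.9780, N_eff 22.0709) is among the
  # symmetry-inequivalent choices
  expect_true(any(round(tab$max_tau, 4) == 33.9780 &
                  round(tab$n_eff_best, 4) == 22.0709))
  expect_true(any(tab$is_constructor))
})

test_that("chains of the cubic N=12 constructor stay amplifier
           constructors with N_eff/N falling toward 1", {
  blk <- unique_constructor(12, 3)
  sr <- cached("chain_search_c12", chain_search(blk, n_blocks = 2))
  # published 2-block values appear among the choices
  expect_true(any(round(sr$table$max_tau, 4) == 38.1158 &
                  round(sr$table$n_eff_best, 4) == 24.0134))
  ratios <- vapply(2:5, function(m) {
    g <- build_chain(sr$best_spec, m)
    expect_silent(check_graph(g, regular = 3))
    expect_equal(igraph::vcount(g), 12 * m)
    out <- perturb_search(g)
    expect_true(out$is_constructor)
    out$best_n_eff / igraph::vcount(g)
  }, numeric(1))
  expect_true(all(ratios > 1))
  expect_true(all(diff(ratios) < 0))
})
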