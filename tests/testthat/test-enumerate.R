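test_that("enumeration counts match the published census sizes", {
  counts <- list(c(4, 3, 1), c(6, 3, 2), c(8, 3, 5), c(10, 3, 19),
                 c(12, 3, 85), c(11, 4, 265))
  for (ck in counts)
    expect_length(enumerate_regular(ck[1], ck[2]), ck[3])
})

test_that("every emitted graph is simple, connected and k-regular, and the
           stream has no isomorphic duplicates", {
  for (spec in list(c(10, 3), c(9, 4))) {
    gs <- enumerate_regular(spec[1], spec[2])
    for (g in gs) expect_silent(check_graph(g, regular = spec[2]))
    keys <- vapply(gs, canon_g6, character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("orderly generation agrees graph-by-graph with brute force at small N", {
  for (spec in list(c(6, 3), c(8, 3), c(7, 4))) {
    fast <- enumerate_regular(spec[1], spec[2])
    slow <- enumerate_regular_bruteforce(spec[1], spec[2])
    expect_setequal(vapply(fast, canon_g6, character(1)),
                    vapply(slow, canon_g6, character(1)))
  }
})

test_that("the stream order is canonical and reproducible", {
  a <- vapply(enumerate_regular(10, 3), write_graph6, character(1))
  b <- vapply(enumerate_regular(10, 3), write_graph6, character(1))
  expect_identical(a, b)
  expect_identical(a, sort(a, method = "radix"))
})

test_that("infeasible orders raise argument errors", {
  expect_error(enumerate_regular(7, 3), "parity")
  expect_error(enumerate_regular(3, 3), "infeasible")
})

test_that("a graph6 file acts as a drop-in enumeration backend", {
  gs <- enumerate_regular(8, 3)
  path <- tempfile(fileext = ".g6")
  write_graph6(gs, path)
  again <- enumerate_regular(8, 3, backend_file = path)
  expect_identical(vapply(again, write_graph6, character(1)),
                   vapply(gs, write_graph6, character(1)))
})

test_that("fixture graphs have the promised shapes and are reproducible", {
  expect_equal(igraph::ecount(complete_graph(5)), 10)
  expect_true(all(igraph::degree(complete_graph(5)) == 4))
  expect_equal(igraph::ecount(cycle_graph(6)), 6)
  expect_true(all(igraph::degree(cycle_graph(6)) == 2))
  g1 <- random_regular(20, 3, seed = 1)
  g2 <- random_regular(20, 3, seed = 1)
  expect_identical(edge_matrix(g1), edge_matrix(g2))
  expect_silent(check_graph(g1, regular = 3))
})
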