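test_that("graph6 encodes K4 to the standard string and round-trips", {
  k4 <- complete_graph(4)
  expect_equal(write_graph6(k4), "C~")
  back <- read_graph6("C~")[[1]]
  expect_equal(igraph::vcount(back), 4)
  expect_equal(igraph::ecount(back), 6)
  expect_equal(write_graph6(back), "C~")
})

test_that("graph6 round-trips arbitrary graphs bit-exactly", {
  for (seed in 1:5) {
    g <- random_regular(14, 3, seed = seed)
    line <- write_graph6(g)
    h <- read_graph6(line)[[1]]
    expect_equal(igraph::vcount(h), 14)
    expect_true(igraph::identical_graphs(
      igraph::as_undirected(h), igraph::as_undirected(g)) ||
        all(sort(apply(edge_matrix(h), 1, paste, collapse = "-")) ==
            sort(apply(edge_matrix(g), 1, paste, collapse = "-"))))
    expect_equal(write_graph6(h), line)
  }
  # orders above 62 use the long form
  big <- cycle_graph(80)
  expect_equal(igraph::vcount(read_graph6(write_graph6(big))[[1]]), 80)
  expect_equal(igraph::ecount(read_graph6(write_graph6(big))[[1]]), 80)
})

test_that("empty streams and malformed lines are handled", {
  expect_identical(read_graph6(character(0)), list())
  expect_error(read_graph6(c("C~", rawToChar(as.raw(c(67, 1))))),
               "line 2")
  expect_error(read_graph6("C"), "payload")
})

test_that("a full census written and re-read stays pairwise nonisomorphic", {
  gs <- enumerate_regular(12, 3)
  path <- tempfile(fileext = ".g6")
  write_graph6(gs, path)
  back <- read_graph6(path)
  expect_length(back, 85)
  keys <- vapply(back, canon_g6, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("edge-list reader accepts 0-based two-column text", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 2", "2 0", "2 3"), path)
  g <- read_edgelist(path)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 4)
  expect_equal(sort(igraph::degree(g)), c(1, 2, 2, 3))
})
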