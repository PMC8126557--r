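test_that("neutral mutants fix with probability 1/N on any graph", {
  for (g in list(complete_graph(6), cycle_graph(7),
                 random_regular(10, 3, seed = 7))) {
    N <- igraph::vcount(g)
    expect_equal(fixation_db_exact(g, 1), 1 / N, tolerance = 1e-12)
  }
})

test_that("the Markov solver reproduces the complete-graph closed form", {
  for (N in c(4, 8, 12)) {
    g <- complete_graph(N)
    for (r in c(0.5, 0.9, 1.1, 2)) {
      exact <- fixation_db_exact(g, r)
      expect_equal(exact, rho_complete(N, r), tolerance = 1e-10)
    }
  }
})

test_that("the Markov solver reproduces the cycle closed form", {
  for (N in c(5, 10, 12)) {
    g <- cycle_graph(N)
    for (r in c(0.5, 0.9, 1.1, 1.2, 2)) {
      exact <- fixation_db_exact(g, r)
      expect_equal(exact, rho_cycle(N, r), tolerance = 1e-10)
    }
  }
})

test_that("closed forms handle limits and coincidences", {
  expect_equal(rho_complete(2, 0.3), 0.5)
  expect_equal(rho_complete(2, 5), 0.5)
  expect_equal(rho_complete(9, 1), 1 / 9)
  expect_equal(rho_complete(9, 1e8), 8 / 9, tolerance = 1e-7)
  expect_equal(rho_cycle(8, 1), 1 / 8)
  # C3 = K3
  for (r in c(0.5, 1.3, 3)) expect_equal(rho_cycle(3, r), rho_complete(3, r),
                                         tolerance = 1e-12)
})

test_that("fixation probability increases with fitness on test graphs", {
  g <- random_regular(9, 4, seed = 8)
  rs <- seq(0.6, 2, by = 0.2)
  vals <- vapply(rs, function(r) fixation_db_exact(g, r), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
})

test_that("argument and resource errors are explicit", {
  expect_error(fixation_db_exact(complete_graph(4), -1), "positive")
  expect_error(fixation_db_exact(complete_graph(4), 1.1, cap = 3), "cap")
  expect_error(rho_complete(5, 0), "positive")
})

test_that("complete graphs classify as neutral-equivalent with no r_max", {
  fc <- find_r_max(complete_graph(6))
  expect_identical(fc$classification, "neutral_equivalent")
  expect_true(is.na(fc$r_max))
})

test_that("the perturbed quartic N=11 constructor is a transient amplifier
           with r_max matching exact bisection of the ratio", {
  h <- best_perturbed(unique_constructor(11, 4))
  fc <- find_r_max(h)
  expect_identical(fc$classification, "transient_amplifier")
  # bisection on the exactly computed ratio, independent of the Lagrange
  # interpolation used by find_r_max
  ratio <- function(r) fixation_db_exact(h, r) / rho_complete(11, r)
  lo <- 1.0001
  hi <- 1.01
  for (i in 1:30) {
    m <- (lo + hi) / 2
    if (ratio(m) > 1) lo <- m else hi <- m
  }
  expect_equal(fc$r_max, (lo + hi) / 2, tolerance = 1e-5)
})
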