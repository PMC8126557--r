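test_that("normalized-Laplacian spectra match closed forms", {
  expect_equal(normalized_laplacian_spectrum(complete_graph(2))$eigenvalues,
               c(0, 2), tolerance = 1e-12)
  for (N in c(5, 9)) {
    ev <- normalized_laplacian_spectrum(complete_graph(N))$eigenvalues
    expect_equal(ev, c(0, rep(N / (N - 1), N - 1)), tolerance = 1e-10)
  }
  for (N in c(6, 11)) {
    ev <- normalized_laplacian_spectrum(cycle_graph(N))$eigenvalues
    expect_equal(ev, sort(1 - cos(2 * pi * (0:(N - 1)) / N)),
                 tolerance = 1e-10)
  }
})

test_that("spectral invariants hold on arbitrary regular graphs", {
  for (seed in 1:4) {
    g <- random_regular(12, 3, seed = seed)
    s <- normalized_laplacian_spectrum(g)
    expect_equal(s$eigenvalues[1], 0, tolerance = 1e-9)
    expect_lte(max(s$eigenvalues), 2 + 1e-9)
    expect_equal(sum(s$eigenvalues), 12, tolerance = 1e-8)
    # regular equivalence: lambda(L) = 1 - mu/k elementwise
    a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    mu <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(s$eigenvalues, 1 - mu / 3, tolerance = 1e-9)
  }
})

test_that("smoothed densities integrate to N and respect identity", {
  grid <- density_grid()
  ev <- normalized_laplacian_spectrum(complete_graph(4))$eigenvalues
  # integrate over a wide grid so no kernel mass is clipped
  wide <- seq(-2, 4, length.out = 6001)
  phi <- smoothed_density(ev, sigma = 1 / 12, grid = wide)
  expect_equal(sum(diff(wide) * (phi[-1] + phi[-length(phi)]) / 2), 4,
               tolerance = 1e-6)
  # single eigenvalue: unit-mass Gaussian centered there
  one <- smoothed_density(1, sigma = 0.05, grid = wide)
  expect_equal(wide[which.max(one)], 1, tolerance = 1e-3)
  expect_equal(sum(diff(wide) * (one[-1] + one[-length(one)]) / 2), 1,
               tolerance = 1e-6)
  # identical spectra give pointwise identical densities
  expect_identical(smoothed_density(ev, grid = grid),
                   smoothed_density(ev, grid = grid))
})

test_that("spectral distance is a pseudometric on the common grid", {
  k4 <- complete_graph(4)
  c4 <- cycle_graph(4)
  expect_equal(spectral_distance(k4, k4), 0)
  d1 <- spectral_distance(k4, c4)
  expect_gt(d1, 0)
  expect_equal(d1, spectral_distance(c4, k4))
  # triangle inequality on a random cubic triple
  gs <- lapply(1:3, function(s) random_regular(10, 3, seed = s))
  d <- function(i, j) spectral_distance(gs[[i]], gs[[j]])
  expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-9)
  expect_error(spectral_distance(rep(1, 10), rep(1, 11), grid = density_grid()),
               "grid")
})

test_that("von Neumann entropy matches closed forms and bounds", {
  expect_equal(von_neumann_entropy(c(0, 2), 2), 0)
  for (N in c(5, 8))
    expect_equal(normalized_laplacian_spectrum(complete_graph(N))$entropy,
                 log2(N - 1), tolerance = 1e-10)
  # C4 by hand: eigenvalues {0, 1, 1, 2}, nu = {0, 1/4, 1/4, 1/2}
  expect_equal(normalized_laplacian_spectrum(cycle_graph(4))$entropy, 1.5,
               tolerance = 1e-12)
  for (g in list(cycle_graph(9), random_regular(12, 3, seed = 9))) {
    s <- normalized_laplacian_spectrum(g)$entropy
    expect_gte(s, 0)
    expect_lte(s, log2(igraph::vcount(g)))
  }
})

test_that("Kesten-McKay reference density behaves as documented", {
  for (k in 3:4) {
    hw <- 2 * sqrt(k - 1) / k
    expect_equal(kesten_mckay_density(c(1 - hw, 1 + hw), k), c(0, 0),
                 tolerance = 1e-6)
    mass <- stats::integrate(function(x) kesten_mckay_density(x, k),
                             1 - hw, 1 + hw, rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  # the curve as commonly printed (mass 1/k): value sqrt(2)/(3 pi) at x = 1
  expect_equal(kesten_mckay_density(1, 3, normalize = FALSE),
               sqrt(2) / (3 * pi), tolerance = 1e-12)
})

test_that("the spectral-gap bound on remeeting times holds, tight on K_N", {
  for (N in c(5, 9)) {
    g <- complete_graph(N)
    rb <- remeeting_bound(coalescence_times(g),
                          normalized_laplacian_spectrum(g))
    expect_true(rb$holds)
    expect_equal(rb$slack, 0, tolerance = 1e-9)
  }
  g <- cycle_graph(8)
  rb <- remeeting_bound(coalescence_times(g),
                        normalized_laplacian_spectrum(g))
  expect_true(rb$holds)
  expect_gt(rb$slack, 1)
})

test_that("family densities average members and family distance is sane", {
  gs <- list(complete_graph(6), cycle_graph(6))
  fam <- family_spectral(gs)
  half <- (smoothed_density(normalized_laplacian_spectrum(gs[[1]])$eigenvalues) +
           smoothed_density(normalized_laplacian_spectrum(gs[[2]])$eigenvalues)) / 2
  expect_equal(fam$density, half, tolerance = 1e-12)
  expect_equal(family_distance(fam, fam), 0)
})
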