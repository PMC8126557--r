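#' Normalized-Laplacian spectral summary
#'
#' The normalized Laplacian is \eqn{L = I - D^{-1/2} A D^{-1/2}}; its
#' spectrum lies in \[0, 2\], with \eqn{\lambda_1 = 0} and the spectral gap
#' \eqn{\lambda_2} measuring conductance and bottlenecks.  For k-regular
#' graphs \eqn{L = I - A/k}, so normalized-Laplacian and adjacency spectra
#' are affinely related.
#'
#' @param g a simple igraph object without isolated vertices.
#' @return an object of class `spectral_summary`: sorted `eigenvalues`,
#'   `lambda2` (spectral gap), `entropy` (von Neumann entropy, bits), `n`.
#' @examples
#' normalized_laplacian_spectrum(complete_graph(4))$lambda2  # 4/3
#' @export
normalized_laplacian_spectrum <- function(g) {
  check_graph(g, connected = FALSE)
  deg <- igraph::degree(g)
  if (any(deg == 0)) stop("graph must have no isolated vertices")
  N <- igraph::vcount(g)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  s <- 1 / sqrt(deg)
  L <- diag(N) - t(a * s) * s
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (any(ev < -1e-9) || any(ev > 2 + 1e-9))
    stop("eigenvalues escaped [0, 2] beyond round-off")
  ev <- pmin(pmax(ev, 0), 2)
  structure(
    list(n = N, eigenvalues = ev, lambda2 = ev[2],
         entropy = von_neumann_entropy(ev, N)),
    class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("Spectral summary: N = %d, lambda2 = %.6f, S = %.4f bits\n",
              x$n, x$lambda2, x$entropy))
  invisible(x)
}

#' Default evaluation grid for smoothed spectral densities
#'
#' 2001 equidistant points on \[0, 2\].
#'
#' @param points number of grid points.
#' @return numeric vector.
#' @export
density_grid <- function(points = 2001L) seq(0, 2, length.out = points)

#' Smoothed spectral density
#'
#' Convolves the eigenvalues with a Gaussian kernel of standard deviation
#' `sigma` (default `1/(3N)`):
#' \deqn{\varphi(x) = \sum_i (2\pi\sigma^2)^{-1/2}
#'       \exp\left(-\frac{(x - \lambda_i)^2}{2\sigma^2}\right).}
#' The density integrates to N over the real line; kernel mass falling
#' outside \[0, 2\] is not renormalized.
#'
#' @param eigenvalues numeric vector of eigenvalues (or a
#'   `spectral_summary`).
#' @param sigma kernel standard deviation; defaults to `1/(3N)` where `N`
#'   is the number of eigenvalues.
#' @param grid evaluation grid, defaults to [density_grid()].
#' @return numeric vector of density samples on `grid`.
#' @export
smoothed_density <- function(eigenvalues, sigma = NULL, grid = density_grid()) {
  if (inherits(eigenvalues, "spectral_summary"))
    eigenvalues <- eigenvalues$eigenvalues
  if (is.null(sigma)) sigma <- 1 / (3 * length(eigenvalues))
  if (sigma <= 0) stop("sigma must be positive")
  d <- outer(grid, eigenvalues, "-")
  rowSums(exp(-d^2 / (2 * sigma^2))) / sqrt(2 * pi * sigma^2)
}

#' Spectral distance between two graphs or densities
#'
#' The L1 distance between smoothed spectral densities on \[0, 2\],
#' \eqn{d = \int_0^2 |\varphi_A - \varphi_B| dx}, evaluated by trapezoidal
#' quadrature.  A pseudometric: symmetric, nonnegative, zero for
#' cospectral graphs.
#'
#' @param a,b igraph objects, `spectral_summary` objects, or density
#'   sample vectors on the common grid.
#' @param grid common evaluation grid.
#' @return nonnegative scalar.
#' @export
spectral_distance <- function(a, b, grid = density_grid()) {
  dens <- function(x) {
    if (igraph::is_igraph(x)) x <- normalized_laplacian_spectrum(x)
    if (inherits(x, "spectral_summary"))
      return(smoothed_density(x$eigenvalues, grid = grid))
    if (!is.numeric(x)) stop("expected a graph, spectral summary, or density")
    if (length(x) != length(grid))
      stop("mismatched grids: density length differs from grid length")
    x
  }
  .trapz(grid, abs(dens(a) - dens(b)))
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' von Neumann graph entropy
#'
#' Shannon entropy (base 2) of the rescaled spectrum \eqn{\nu_i =
#' \lambda_i / N}: \eqn{S = -\sum_i \nu_i \log_2 \nu_i} with
#' \eqn{0 \log_2 0 = 0}.  Complete graphs give \eqn{\log_2(N - 1)}; long
#' paths and nontrivial symmetries raise the entropy.
#'
#' @param eigenvalues normalized-Laplacian eigenvalues.
#' @param N graph order (defaults to the number of eigenvalues).
#' @return entropy in bits.
#' @export
von_neumann_entropy <- function(eigenvalues, N = length(eigenvalues)) {
  nu <- eigenvalues / N
  nz <- nu > 0
  -sum(nu[nz] * log2(nu[nz]))
}

#' Kesten-McKay spectral density for random k-regular graphs
#'
#' The limiting (N to infinity) normalized-Laplacian spectral density of
#' random k-regular graphs,
#' \deqn{\varphi_{KM}(x) = \frac{\sqrt{4(k-1) - k^2 (1-x)^2}}
#'       {2\pi (2 - x) x},}
#' supported on \eqn{|1 - x| \le 2\sqrt{k-1}/k} and zero outside.  This is
#' the adjacency-spectrum Kesten-McKay law transported through
#' \eqn{\lambda = 1 - \mu/k} and integrates to 1 over the support.  The
#' same curve is often quoted with an extra factor k in the denominator
#' (mass 1/k); since it is used as a reference shape, set
#' `normalize = FALSE` to obtain that scaling.
#'
#' @param x evaluation points.
#' @param k degree, `k >= 3`.
#' @param normalize if `TRUE` (default) the density integrates to 1 over
#'   the support; if `FALSE` the curve is divided by k.
#' @return density values.
#' @export
kesten_mckay_density <- function(x, k, normalize = TRUE) {
  if (k < 3) stop("Kesten-McKay reference needs k >= 3")
  half_width <- 2 * sqrt(k - 1) / k
  inside <- abs(1 - x) <= half_width & x > 0 & x < 2
  out <- numeric(length(x))
  xi <- x[inside]
  out[inside] <- sqrt(pmax(4 * (k - 1) - k^2 * (1 - xi)^2, 0)) /
    (2 * pi * (2 - xi) * xi)
  if (!normalize) out <- out / k
  out
}

#' Spectral bound on remeeting times
#'
#' Verifies \eqn{\tau_i \le (N - 1)/\lambda_2 + (2N - 1)/N} for every
#' vertex (equality on complete graphs).
#'
#' @param summary a `coalescence_summary`.
#' @param spectrum a `spectral_summary` of the same graph.
#' @return list with `holds` (logical), `bound`, and `slack` (minimal
#'   bound minus remeeting time over vertices).
#' @export
remeeting_bound <- function(summary, spectrum) {
  stopifnot(inherits(summary, "coalescence_summary"),
            inherits(spectrum, "spectral_summary"))
  if (spectrum$lambda2 <= 1e-12)
    stop("spectral gap is zero (disconnected graph)")
  N <- summary$n
  bound <- (N - 1) / spectrum$lambda2 + (2 * N - 1) / N
  slack <- bound - max(summary$tau_remeet)
  list(holds = slack >= -1e-9, bound = bound, slack = slack)
}

#' Family spectral density and distances
#'
#' The density of a family of graphs is the arithmetic mean of the member
#' densities (equivalently, the kernel estimate over the pooled eigenvalue
#' multiset divided by the family size).
#'
#' @param graphs list of igraph objects or eigenvalue vectors.
#' @param grid evaluation grid.
#' @param sigma kernel width; default `1/(3N)` per member.
#' @return object of class `family_spectral`: `density`, `grid`, `size`.
#' @export
family_spectral <- function(graphs, grid = density_grid(), sigma = NULL) {
  if (!length(graphs)) stop("family must contain at least one graph")
  dens <- vapply(graphs, function(g) {
    ev <- if (igraph::is_igraph(g)) normalized_laplacian_spectrum(g)$eigenvalues
          else g
    smoothed_density(ev, sigma = sigma, grid = grid)
  }, numeric(length(grid)))
  structure(list(density = rowMeans(dens), grid = grid,
                 size = length(graphs)),
            class = "family_spectral")
}

#' @export
print.family_spectral <- function(x, ...) {
  cat(sprintf("Family spectral density over %d member(s), %d grid points\n",
              x$size, length(x$grid)))
  invisible(x)
}

#' Distance between graph families
#'
#' @param fa,fb `family_spectral` objects on the same grid.
#' @return L1 distance between the family densities.
#' @export
family_distance <- function(fa, fb) {
  stopifnot(inherits(fa, "family_spectral"), inherits(fb, "family_spectral"))
  if (length(fa$grid) != length(fb$grid) || any(fa$grid != fb$grid))
    stop("mismatched grids")
  .trapz(fa$grid, abs(fa$density - fb$density))
}
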