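#' Exact fixation probability under death-birth updating
#'
#' A population of residents (fitness 1) and mutants (fitness r) occupies
#' the vertices of a connected graph.  In each update step a vertex dies
#' uniformly at random and one of its neighbours, chosen with probability
#' proportional to fitness, places a copy of itself on the vacancy.  The
#' fixation probability of a single mutant placed uniformly at random is
#' computed exactly by solving the absorbing Markov chain over all
#' `2^N - 2` transient mutant-set states (subsets encoded as bitmasks):
#' the hitting probability x_S of the all-mutant state satisfies
#' \deqn{x_S = \frac1N \sum_u \left[ P_u(S)\, x_{S \cup u} +
#'   (1 - P_u(S))\, x_{S \setminus u} \right]}
#' with \eqn{P_u(S) = r m_u / (r m_u + k_u - m_u)} and m_u the number of
#' mutant neighbours of u, and the fixation probability is the average of
#' x over the N single-mutant states.
#'
#' @param g connected igraph object with at most `cap` vertices.
#' @param r mutant fitness, \code{r > 0}.
#' @param cap resource cap on the order (the chain has `2^N - 2` transient
#'   states); default 16.
#' @return fixation probability in (0, 1).
#' @examples
#' fixation_db_exact(cycle_graph(4), 1)      # 1/4 at neutrality
#' @export
fixation_db_exact <- function(g, r, cap = 16L) {
  check_graph(g, connected = TRUE)
  if (r <= 0) stop("mutant fitness r must be positive")
  N <- igraph::vcount(g)
  if (N < 2) stop("need N >= 2")
  if (N > cap)
    stop(sprintf(paste0("order %d exceeds the solver cap %d ",
                        "(2^N - 2 transient states); raise `cap` to force"),
                 N, cap))
  x <- .fixation_solve(g, r)
  mean(x[bitwShiftL(1L, 0:(N - 1))])
}

# solves for the fixation probabilities of all transient states; returns the
# vector x indexed by bitmask state id 1 .. 2^N - 2.
#
# A death-birth event changes the number of mutants by at most one, so
# grouping states by mutant count makes the system block-tridiagonal with
# level sizes choose(N, m); it is solved by block forward elimination
# (Thomas algorithm) with dense LAPACK solves per level, which keeps the
# cost at the sum of cubed level sizes instead of a general sparse LU.
.fixation_solve <- function(g, r) {
  N <- igraph::vcount(g)
  deg <- igraph::degree(g)
  full <- bitwShiftL(1L, N) - 1L
  states <- seq_len(full - 1L)
  pc <- .popcount_table(N)
  adj_mask <- vapply(igraph::as_adj_list(g), function(nb)
    sum(bitwShiftL(1L, as.integer(nb) - 1L)), numeric(1))
  adj_mask <- as.integer(adj_mask)
  ii <- jj <- xx <- vector("list", 2L * N)
  bvec <- numeric(length(states))
  diag_acc <- numeric(length(states))
  slot <- 0L
  for (u in seq_len(N)) {
    bit <- bitwShiftL(1L, u - 1L)
    m <- pc[bitwAnd(states, adj_mask[u]) + 1L]
    p_mut <- r * m / (r * m + (deg[u] - m))
    in_s <- bitwAnd(states, bit) > 0L
    # u dies (prob 1/N); mutant replacement -> S | bit, resident -> S & ~bit
    up <- ifelse(in_s, states, states + bit)
    down <- ifelse(in_s, states - bit, states)
    # self-transitions accumulate on the diagonal
    self_up <- up == states
    self_down <- down == states
    diag_acc <- diag_acc + ifelse(self_up, p_mut, 0) / N +
      ifelse(self_down, 1 - p_mut, 0) / N
    # absorbing targets: all-mutant contributes to the RHS, empty drops out
    absorb <- up == full & !self_up
    bvec[absorb] <- bvec[absorb] + p_mut[absorb] / N
    keep_up <- !self_up & !absorb
    keep_down <- !self_down & down != 0L
    slot <- slot + 1L
    ii[[slot]] <- states[keep_up]
    jj[[slot]] <- up[keep_up]
    xx[[slot]] <- p_mut[keep_up] / N
    slot <- slot + 1L
    ii[[slot]] <- states[keep_down]
    jj[[slot]] <- down[keep_down]
    xx[[slot]] <- (1 - p_mut[keep_down]) / N
  }
  rows <- c(states, unlist(ii))
  cols <- c(states, unlist(jj))
  vals <- c(1 - diag_acc, -unlist(xx))

  lev <- pc[states + 1L]                 # mutant count per state, 1..N-1
  M <- N - 1L
  sizes <- tabulate(lev, M)
  within <- integer(length(states))      # rank of a state inside its level
  ord <- order(lev, states)
  within[ord] <- sequence(sizes)

  D <- lapply(sizes, function(s) matrix(0, s, s))
  U <- vector("list", M)                 # level m -> m + 1
  L <- vector("list", M)                 # level m -> m - 1
  for (m in seq_len(M - 1L)) U[[m]] <- matrix(0, sizes[m], sizes[m + 1L])
  for (m in seq_len(M - 1L)) L[[m + 1L]] <- matrix(0, sizes[m + 1L], sizes[m])
  li <- lev[rows]
  lj <- lev[cols]
  fill <- function(blocks, sel, off) {
    for (m in unique(li[sel])) {
      s <- sel[li[sel] == m]
      blocks[[m]][cbind(within[rows[s]], within[cols[s]])] <- vals[s]
      # entries are unique per (state, target): plain assignment suffices
    }
    blocks
  }
  D <- fill(D, which(li == lj))
  U <- fill(U, which(lj == li + 1L))
  L <- fill(L, which(lj == li - 1L))
  bl <- split(bvec[ord], lev[ord])

  # forward elimination over levels, then back substitution
  S <- vector("list", M)
  y <- vector("list", M)
  S[[1]] <- D[[1]]
  y[[1]] <- bl[[1]]
  for (m in seq_len(M)[-1]) {
    W <- solve(S[[m - 1L]], cbind(U[[m - 1L]], y[[m - 1L]]))
    k <- ncol(U[[m - 1L]])
    S[[m]] <- D[[m]] - L[[m]] %*% W[, seq_len(k), drop = FALSE]
    y[[m]] <- bl[[m]] - as.numeric(L[[m]] %*% W[, k + 1L])
  }
  xlev <- vector("list", M)
  xlev[[M]] <- as.numeric(solve(S[[M]], y[[M]]))
  for (m in rev(seq_len(M - 1L)))
    xlev[[m]] <- as.numeric(solve(S[[m]], y[[m]] - U[[m]] %*% xlev[[m + 1L]]))
  x <- numeric(length(states))
  x[ord] <- unlist(xlev)
  x
}

.popcount_env <- new.env(parent = emptyenv())
.popcount_table <- function(N) {
  key <- as.character(N)
  tab <- .popcount_env[[key]]
  if (is.null(tab)) {
    vals <- 0:(2^N - 1)
    tab <- integer(length(vals))
    v <- vals
    while (any(v > 0)) {
      tab <- tab + bitwAnd(v, 1L)
      v <- bitwShiftR(v, 1L)
    }
    .popcount_env[[key]] <- tab
  }
  tab
}

#' Closed-form fixation probability on the complete graph
#'
#' \eqn{\rho_N(r) = \frac{N-1}{N}\,\frac{1 - r^{-1}}{1 - r^{-(N-1)}}}, with
#' the removable singularity at r = 1 evaluated as the limit 1/N.
#'
#' @param N order of the complete graph, `N >= 2`.
#' @param r mutant fitness, \code{r > 0}.
#' @return fixation probability.
#' @export
rho_complete <- function(N, r) {
  if (any(r <= 0)) stop("mutant fitness r must be positive")
  if (N < 2) stop("need N >= 2")
  out <- numeric(length(r))
  at1 <- abs(r - 1) < 1e-12
  out[at1] <- 1 / N
  rr <- r[!at1]
  out[!at1] <- (N - 1) / N * (1 - rr^(-1)) / (1 - rr^(-(N - 1)))
  out
}

#' Closed-form fixation probability on the cycle graph
#'
#' \eqn{\rho_C(r) = \frac{2(r-1)}{3r - 1 + r^{-(N-3)} - 3 r^{-(N-2)}}}, with
#' limit 1/N at r = 1.
#'
#' @param N order of the cycle, `N >= 3`.
#' @param r mutant fitness, \code{r > 0}.
#' @return fixation probability.
#' @export
rho_cycle <- function(N, r) {
  if (any(r <= 0)) stop("mutant fitness r must be positive")
  if (N < 3) stop("need N >= 3")
  out <- numeric(length(r))
  at1 <- abs(r - 1) < 1e-12
  out[at1] <- 1 / N
  rr <- r[!at1]
  out[!at1] <- 2 * (rr - 1) / (3 * rr - 1 + rr^(-(N - 3)) - 3 * rr^(-(N - 2)))
  out
}

#' Fixation curve and the transient-amplification range
#'
#' Evaluates the exact fixation probability on an equidistant fitness grid
#' starting at r = 1, forms the ratio to the complete-graph baseline, widens
#' the window geometrically until the ratio has fallen below 1, interpolates
#' the ratio with a Lagrange polynomial through the grid values and locates
#' r_max, the fitness where the ratio crosses 1 from above, by bisection on
#' the polynomial.  An optional window below r = 1 locates r_min.
#'
#' Classification: `transient_amplifier` if the ratio exceeds 1 on a finite
#' window (1, r_max); `transient_suppressor` if it is below 1 above 1 but
#' above 1 below 1; `neutral_equivalent` if the ratio is identically 1;
#' `other` otherwise.
#'
#' @param g connected igraph object.
#' @param points grid points per window (Lagrange degree `points - 1`).
#' @param window initial upper window, default `c(1, 1.01)`.
#' @param widen geometric widening factor of the window's upper end.
#' @param max_widen maximal number of widenings before giving up.
#' @param lower also evaluate a mirrored window below 1 and locate r_min.
#' @param cap order cap passed to [fixation_db_exact()].
#' @param tol amplification below this level counts as numerically neutral.
#' @return an object of class `fixation_curve`: `r_grid`, `rho_g`,
#'   `rho_complete`, `ratio`, `r_max`, `r_min`, `classification`.
#' @export
find_r_max <- function(g, points = 13L, window = c(1, 1.01), widen = 2,
                       max_widen = 12L, lower = FALSE, cap = 16L,
                       tol = 1e-10) {
  check_graph(g, connected = TRUE)
  N <- igraph::vcount(g)
  lo <- window[1]
  hi <- window[2]
  if (lo != 1) stop("the upper window must start at r = 1")
  ratio_at <- function(r) {
    vapply(r, function(ri)
      fixation_db_exact(g, ri, cap = cap) / rho_complete(N, ri), numeric(1))
  }
  grid <- ratio <- NULL
  for (w in seq_len(max_widen)) {
    grid <- seq(lo, hi, length.out = points)
    ratio <- ratio_at(grid)
    if (min(ratio[-1]) < 1 - tol || max(ratio[-1]) <= 1 + tol) break
    hi <- lo + (hi - lo) * widen
  }
  r_max <- .ratio_crossing(grid, ratio, tol)
  amplifier <- !is.na(r_max)
  flat <- max(abs(ratio - 1)) <= tol

  r_min <- NA_real_
  ratio_lo <- NULL
  grid_lo <- NULL
  if (lower) {
    span <- hi - lo
    grid_lo <- seq(1 - span, 1, length.out = points)
    ratio_lo <- ratio_at(grid_lo)
    # mirrored search: crossing below 1 approached from the left
    r_min <- .ratio_crossing(rev(2 - grid_lo), rev(ratio_lo), tol)
    if (!is.na(r_min)) r_min <- 2 - r_min
  }
  suppressed_above <- max(ratio[-1]) < 1 - tol
  raised_below <- if (is.null(ratio_lo)) NA
                  else max(ratio_lo[-points]) > 1 + tol
  classification <-
    if (flat) "neutral_equivalent"
    else if (amplifier) "transient_amplifier"
    else if (suppressed_above && isTRUE(raised_below)) "transient_suppressor"
    else "other"
  structure(
    list(r_grid = c(grid_lo, grid), rho_g = NULL,
         ratio = c(ratio_lo, ratio),
         rho_complete = rho_complete(N, c(grid_lo, grid)),
         r_max = r_max, r_min = r_min, n = N,
         classification = classification),
    class = "fixation_curve")
}

# locates the fitness > grid[1] where the Lagrange interpolant of
# (ratio - 1) crosses zero from above; NA if the ratio never rises above 1
.ratio_crossing <- function(grid, ratio, tol) {
  f <- .lagrange_fun(grid, ratio - 1)
  xs <- seq(grid[1], grid[length(grid)], length.out = 4096L)[-1]
  vals <- f(xs)
  above <- which(vals > tol)
  if (!length(above)) return(NA_real_)
  first <- above[1]
  below <- which(vals < -tol)
  below <- below[below > first]
  if (!length(below)) return(NA_real_)
  a <- xs[below[1] - 1L]
  b <- xs[below[1]]
  for (it in 1:200) {
    m <- (a + b) / 2
    if (f(m) > 0) a <- m else b <- m
    if (b - a < 1e-10) break
  }
  (a + b) / 2
}

# barycentric Lagrange interpolation through (x, y)
.lagrange_fun <- function(x, y) {
  n <- length(x)
  w <- vapply(seq_len(n), function(j) 1 / prod(x[j] - x[-j]), numeric(1))
  function(xx) {
    vapply(xx, function(p) {
      hit <- which(abs(p - x) < 1e-15)
      if (length(hit)) return(y[hit[1]])
      num <- w / (p - x)
      sum(num * y) / sum(num)
    }, numeric(1))
  }
}

#' @export
print.fixation_curve <- function(x, ...) {
  cat(sprintf("Fixation curve on order %d: %s\n", x$n, x$classification))
  if (!is.na(x$r_max)) cat(sprintf("  r_max = %.6f\n", x$r_max))
  if (!is.na(x$r_min)) cat(sprintf("  r_min = %.6f\n", x$r_min))
  invisible(x)
}
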