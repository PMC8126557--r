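---
title: "Constructing transient amplifiers of selection from regular graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing transient amplifiers of selection from regular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transamp)
```

## The question

Evolutionary dynamics on a graph places one individual on each vertex;
edges are interaction partners.  Under death–birth (dB) updating a vertex
dies uniformly at random and a neighbour, chosen proportionally to fitness,
fills the vacancy with a copy of its type.  The fixation probability
$\varrho_G(r)$ is the chance that a single mutant of fitness $r$, placed
uniformly at random, eventually occupies the whole graph.  A *transient
amplifier* beats the well-mixed benchmark — the complete graph of equal
order — on a finite fitness window $1 < r < r_{\max}$ and loses outside it.
For dB updating no graph amplifies universally, so transient amplification
is the strongest behaviour available, and for a long time hardly any
examples were known.

This package implements a systematic search: take *all* connected pairwise
nonisomorphic $k$-regular graphs of a given order $N$ (cubic $k=3$ and
quartic $k=4$ are the interesting degrees), perturb each one by deleting a
single edge at its most "remote" vertex, and test the perturbed graph for
amplification of weak selection.  Because complete enumerations are used,
the search covers the whole structural range these regular graphs can
express, which a sample of random graphs cannot guarantee.

## Coalescing random walks and the perturbation test

The machinery rests on meeting times of two half-lazy random walks: per
update step one of the two walkers, chosen with probability $\tfrac12$,
moves to a uniform neighbour.  The pairwise coalescence times solve the
$\binom N2$-equation linear system
$$\tau_{ij} = 1 + \tfrac12 \sum_w \left(p_{iw}\,\tau_{wj} +
  p_{jw}\,\tau_{iw}\right), \qquad \tau_{ii}=0,$$
with step probabilities $p_{iw} = e_{iw}/k_i$.  The remeeting time of a
vertex is $\tau_i = 1 + \sum_j p_{ij}\tau_{ij}$ and the effective
population size is the degree-weighted mean
$N_{\mathrm{eff}} = \sum_i \pi_i \tau_i$, $\pi_i = k_i / \sum_j k_j$.
Two exact identities make strong test oracles: $\sum_i \pi_i^2\tau_i = 1$
on every graph, and $N_{\mathrm{eff}} = N$ on every regular graph (the
isothermal property) — so a regular graph can never amplify weak selection
on its own.

A graph amplifies weak selection precisely when $N_{\mathrm{eff}} > N$.
First-order perturbation of the identity condition shows
$\Delta N_{\mathrm{eff}} \approx -\sum_i \Delta\pi_i\,\tau_i$: removing an
edge *lowers* $\pi$ exactly at its two endpoints, so deleting an edge at
the vertex with the largest remeeting time is the most promising move.
`perturb_search()` implements the full test: find all vertices tying for
$\max_i \tau_i$ (relative tolerance $10^{-9}$), delete each incident edge
(or unordered pair of edges), skip deletions that disconnect the graph —
coalescence times diverge on disconnected graphs and the linear system
becomes singular, so such removals cannot be scored — and recompute
$N_{\mathrm{eff}}$ exactly on each perturbed graph.  A regular graph whose
best removal achieves $N_{\mathrm{eff}} > N + 10^{-9}$ is an *amplifier
constructor*.  The printed margins are $\ge 8\cdot10^{-4}$, orders of
magnitude above both the threshold and the solver residual ($\le
10^{-10}$), so the strictness of the threshold is immaterial in practice.

```{r quartic11}
gs <- enumerate_regular(11, 4)           # all 265 quartic graphs of order 11
hits <- Filter(function(g) perturb_search(g)$is_constructor, gs)
out <- perturb_search(hits[[1]])         # the unique constructor
out
round(out$per_removal$n_eff, 4)          # 4 symmetric removals
```

## Exact fixation probabilities

Weak-selection amplification is tangential at $r = 1$; the fitness window
is bounded by $r_{\max}$, which requires the fixation probability itself.
`fixation_db_exact()` solves the absorbing Markov chain over all
$2^N - 2$ mutant subsets with no Monte Carlo error: since a dB event
changes the mutant count by at most one, grouping states by count makes
the system block-tridiagonal with level sizes $\binom Nm$, and a block
forward elimination (Thomas algorithm) solves it with dense per-level
LAPACK solves.  The only inaccuracy is round-off, which the test suite
pins below $10^{-10}$ relative against the closed forms for the complete
graph and the cycle,
$$\varrho_N(r) = \frac{N-1}{N}\,\frac{1-r^{-1}}{1-r^{-(N-1)}},\qquad
  \varrho_C(r) = \frac{2(r-1)}{3r-1+r^{-(N-3)}-3r^{-(N-2)}}.$$
Both forms evaluate the removable singularity at $r=1$ by its limit $1/N$
rather than by the raw expression.

`find_r_max()` evaluates $\varrho_G/\varrho_N$ on an equidistant grid of
13 points starting at $r=1$ over the window $[1, 1.01]$, doubling the
window until the ratio has dropped below 1, interpolates the ratio with
the Lagrange polynomial through the grid (barycentric form, degree 12) and
polishes the crossing by bisection to $10^{-10}$.  The window and grid
size are our choices — only "equidistant grid" and "Lagrange polynomial"
are prescribed — but the result is insensitive to them: for the perturbed
quartic order-11 constructor the interpolated crossing agrees with direct
bisection of the exactly computed ratio to five decimals
($r_{\max} = 1.00082$).  The amplification amplitude is tiny (the ratio
peaks around $10^{-7}$ above 1), which is why an exact solver rather than
simulation is essential here.

```{r rmax}
per <- out$per_removal
b <- which(per$connected)[which.max(per$n_eff[per$connected])]
h <- igraph::delete_edges(out$base,
                          igraph::get_edge_ids(out$base,
                                               c(per$v1[b], per$w1[b])))
find_r_max(h)
```

## Enumeration

No installed backend enumerates nonisomorphic regular graphs, so the
generator is part of the package (C++): a depth-first search over partial
graphs in which each vertex carries its remaining degree capacity, always
saturating a vertex of minimal positive capacity.  Isomorphic partial
states are pruned through a memo table keyed by a canonical certificate of
the capacity-coloured graph (equitable refinement plus individualization
backtracking, per connected component), so every isomorphism class is
expanded exactly once, and saturated subgraphs that seal themselves off
are pruned because they could only complete to disconnected graphs.  The
stream is returned sorted by canonical graph6 string, making runs
reproducible and resumable.  Correctness is cross-checked two ways: against
an independent brute-force labelled generator with igraph/BLISS
deduplication for $N \le 8$, and against the published census counts
(e.g. 85 cubic graphs of order 12, 4060 of order 16, 265 quartic graphs
of order 11, 88168 of order 14).

## What the census shows

`run_census()` streams a full $(N,k)$ slice through the pipeline — one
deterministic row per graph with `max_tau`, `var_tau`, `lambda2`,
`entropy`, `n_eff_best`, the constructor verdict and optionally
$r_{\max}$ — with CSV checkpointing for the larger slices.  Constructors
are rare: 1/85 cubic graphs at $N=12$, 7/509 at $N=14$, 42/4060 at
$N=16$; 1/265 quartic graphs at $N=11$.  Our quartic $N=14$ run finds 109
constructors among the 88168 graphs.  Chains
(`chain_spec()`/`build_chain()`) splice cut copies of a constructor into
arbitrarily long $k$-regular graphs that keep the property, with
$N_{\mathrm{eff}}/N \to 1$ from above as the single removed edge loses
leverage against a growing graph; because the published drawings fix cuts
and connectors only via their vertex labelling, `chain_search()`
enumerates all inequivalent choices instead of guessing one.

## Spectral characterization

The normalized Laplacian $L = I - D^{-1/2}AD^{-1/2}$ has spectrum in
$[0,2]$; the gap $\lambda_2$ measures conductance.  Summaries per graph
(`normalized_laplacian_spectrum()`) are complemented by a smoothed
spectral density — eigenvalues convolved with a Gaussian kernel of width
$\sigma = 1/(3N)$, evaluated on 2001 grid points over $[0,2]$ (the kernel
formula is implemented with the standard negative exponent; mass outside
$[0,2]$ is not renormalized) — an $L^1$ pseudometric between densities by
trapezoidal quadrature, and the von Neumann entropy
$S = -\sum_i \nu_i \log_2 \nu_i$, $\nu_i = \lambda_i/N$.  Families of
graphs are summarized by the arithmetic mean of member densities; pooled
kernel estimates with other normalizations would change absolute
distances, so only distance *orderings* between families are asserted.
As a reference shape for the bulk we provide the Kesten–McKay law mapped
to the normalized-Laplacian axis; note the correctly normalized density
has no $k$ in the denominator (the commonly printed variant integrates to
$1/k$; `normalize = FALSE` reproduces it).

Amplifier constructors are structurally distinctive: low $\lambda_2$
(path-like, bottlenecked, cut vertices), low entropy, and strong
eigenvalue multiplicities at $\lambda = 1$ — fingerprints of repeated
subgraph motifs.  The remeeting bound
$\tau_i \le (N-1)/\lambda_2 + (2N-1)/N$ (equality on complete graphs)
links the two layers: very remote vertices force a small gap.  The
simple box classifier (`fit_and_score()`) exploits this: thresholds at
the smallest constructor $\max\tau_i$ and the largest constructor
$\lambda_2$, inclusive comparisons so recall is 100% by construction; on
the cubic $N=16$ slice it attains PRE = 22.7% with 143 false positives —
useful as a cheap pre-filter before the exponential fixation computation.
One caveat: the false-positive count is sensitive to exact spectral ties.
On this slice seven non-constructors share the threshold $\lambda_2$ with
the threshold-defining constructor to machine precision (a repeated
subgraph motif), so counts between 136 and 143 arise depending on how an
eigensolver rounds the tied gaps; the inclusive rule used here keeps all
ties and is deterministic.

## Numerical choices and scope

* Pair systems are solved densely up to order 100 ($\binom{100}{2}$
  unknowns) and sparsely beyond (long chains); residuals above $10^{-8}$
  abort rather than degrade.
* Pivot ties use a relative tolerance of $10^{-9}$; all tied vertices are
  tried and the best removal is reported.  Census verdicts at $N \le 16$
  are unchanged under first-pivot-only handling.
* Two-edge removals default to simultaneous deletion at the original
  pivot; `mode = "sequential"` re-identifies the pivot between removals.
  Published two-edge counts do not state which convention was used, so
  both are available.
* The exact fixation solver is capped at $N = 16$ ($2^{16}$ states) by
  default; the cap is an argument, not a limit of the method.
* Problem sizes in the tests and the acceptance script: full censuses at
  cubic $N \le 16$ and quartic $N \le 14$, fixation at $N \le 12$ plus
  the $N = 11$ worked example.  Cubic $N \le 22$ and quartic $N \le 16$
  run with the same code (hours of CPU), or via an external graph6 stream
  as a drop-in enumeration backend.
* The half-lazy walk simulator (`simulate_coalescence_time()`) exists as
  an independent oracle for the linear system, not as a production path.

Known limitations: the study design covers unweighted simple regular
graphs and single/double edge removals at the pivot only — removals at
non-pivot vertices, vertex deletions, edge weights and birth–death
updating are out of scope.  The spectral "fingerprint" of constructors is
descriptive, and the box classifier's precision degrades with growing
$N$; neither is a sufficient condition, as the false-positive counts
show.
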