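---
title: "Modelling the mitochondrial reticulum as a dynamic graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the mitochondrial reticulum as a dynamic graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoreticulum)
```

## The model

The cell-wide mitochondrial network (the chondriome) is a mesh of tubules
that continuously fuse and divide.  `mitoreticulum` represents it as a graph
of `L` persistent **edges** — each edge one fission/fusion quantum of tubule,
about `l = 0.2` µm, the spacing of the membrane-bound fission/fusion
machinery — whose `2L` endpoint slots are grouped into **nodes** of degree

* `k = 1`: a free tip,
* `k = 2`: a bulk (side) site along a tubule,
* `k = 3`: a branching point.

Image analysis of confocal skeletons shows that, after correcting for
overlay artifacts, essentially all true branching points have degree 3, so
the model excludes `k >= 4` by construction.  Two reversible reactions
rewrite the node partition:

* **tip-to-tip** fusion/fission, rate coefficients `a1` / `b1 = b`:
  two tips merge into a bulk node, or a bulk node splits into two tips;
* **tip-to-side** fusion/fission, `a2` / `b2 = (3/2) b`:
  a tip attaches to a bulk site forming a branching point, or a branching
  point is cut across one of its three edges.

A single fission machinery acts with equal probability per edge; a bulk
node straddles 2 edge ends and a branching point 3, whence `b2 = (3/2) b1`
exactly.  Edges are never created or destroyed: `L` is conserved (organelle
biogenesis and mitophagy act on far slower time scales) and the handshake
identity `x1 + 2 x2 + 3 x3 = 2L` holds at all times, where `x_k` counts
nodes of degree `k`.

The model is non-spatial and well-mixed: participants of an event are drawn
uniformly among eligible nodes, justified by the fast cell-wide transport of
mitochondria along the cytoskeleton.  Consequently self-interactions are
allowed — the two tips of one segment may close into a loop, and a tip may
fuse to a bulk site of its own cluster, creating a cycle.  A loop of a
single edge (both slots in one bulk node) is representable and permitted;
nothing in the kinetics forbids it, and the loop-length distribution needs a
smallest class.

## Deterministic (mean-field) description

Writing each propensity times its census increment gives

```
dx1/dt = -2 a1 x1 (x1 - 1) + 2 b x2 - a2 x1 x2 + (3/2) b x3
dx2/dt =    a1 x1 (x1 - 1) -   b x2 - a2 x1 x2 + (3/2) b x3
dx3/dt =    a2 x1 x2 - (3/2) b x3
```

with the conservation constraint `x1 + 2 x2 + 3 x3 = 2L` replacing one of
the three equations.  The tip-to-tip fusion term keeps the discrete-pair
form `x1 (x1 - 1)` — the number of tip pairs times the per-pair propensity
`2 a1` — rather than the continuum `x1^2`; at `L = 3e4` the difference is
negligible, but the discrete form is the one the propensities define.

The steady state depends only on `c1 = a1/b`, `c2 = a2/b` and `L`.  Setting
the balances to zero yields `x2 = c1 x1 (x1 - 1)` and
`x3 = (2/3) c2 x1 x2`, leaving a single scalar equation

```
x1 + 2 c1 x1 (x1 - 1) (1 + c2 x1) = 2 L
```

whose unique root on `(0, 2L]` is bracketed and bisected (`uniroot`,
relative tolerance 1e-12) and then polished by a handful of Newton steps —
the constraint becomes extremely steep in `x1` at large `c1`, where the
bracketing tolerance alone would leave a visible conservation residual.
Three limiting configurations anchor the phase diagram: fully fragmented
`(2L, 0, 0)` as `c1, c2 -> 0`; a single loop `(0, L, 0)` as `c1 -> Inf` at
`c2 = 0`; and the fully branched "crystal" `(0, 0, (2/3) L)` as
`c2 -> Inf`.  The limits are realized numerically at extreme finite
parameters (`c1 = 1e8`, `c2 = 1e6`), which reach the corners to better than
0.1% of `L`.

```{r}
ss <- steady_state(c1 = 0.1, c2 = 1.9e-5, L = 3e4)
ss
ss$x1 / ss$x3
```

A **segment** is a maximal run of edges joined only through bulk nodes; it
is typed by its end-node degrees (1-1 open, 2-2 loop, 1-3 surface, 3-3
internal).  Every non-loop segment ends in two slots held by degree-1 or
degree-3 nodes, so the segment count is `(x1 + 3 x3)/2` and the mean
non-loop segment length is `2L/(x1 + 3 x3)` edges.  Loop mass is a few
percent at physiological ratios and is neglected in this average, which is
therefore flagged approximate.

## Exact stochastic simulation

`simulate_network()` runs the Gillespie algorithm on the explicit graph.
The compiled core keeps per-degree node registries with swap-removal, so
drawing participants and applying an event is O(1) amortized; waiting times
are exponential in the summed propensity and the event type is categorical
by propensity.  For tip-to-tip fusion the pair is drawn uniformly among
unordered distinct tip pairs — the two tips of one segment are as eligible
as any other pair — and for tip-to-side fission the cut edge is uniform
among the three incident edges.  All randomness comes from R's RNG, so a
seed makes runs bit-identical.

Defaults: time is dimensionless with `b = 1`; `calibrate_rates()` provides
a physical-time mode that rescales `b` so the summed stationary event
frequency matches the experimentally observed ~0.25 events per cell per
second.  Burn-in defaults to `10 L` events from the fragmented start:
relaxation is rate-limited by the slow tip-to-side kinetics at
physiological ratios, and split-half comparisons of stationary means showed
no drift beyond sampling error after that (the package's own criterion; the
stationary tests below probe it continuously).  Snapshot statistics
(cluster sizes via union-find, segment censuses via traversal) are computed
in the compiled core as well.

At `L = 3e4` the stationary census means agree with the mean-field steady
state to well under 3% for the parameter sets studied; at small `L` the
agreement degrades as expected for a mean-field limit (about 4% at
`L = 200`, >10% at `L = 10` for the minority species), which the test suite
records as a property of the model rather than a defect.

## The tip-to-tip-only network: loops versus open chains

With `c2 = 0` only degrees 1 and 2 occur and the network is a mixture of
open (1-1) chains and disconnected (2-2) loops.  `master_rhs()` implements
the population equations for the expected numbers `u_open[i]`, `u_loop[i]`
of chains and loops of length `i`:

* fission: each bulk node breaks at rate `b`; a chain of length `m` has
  `m - 1`, a loop of length `i` has `i` (breaking a loop yields an open
  chain of the same length);
* fusion: each unordered tip pair fuses at rate `2 a1`, so two distinct
  chains (four tip pairs) merge at rate `8 a1` and a chain closes into a
  loop (its own single tip pair) at rate `2 a1`.

Products of populations use the standard mass-action (Smoluchowski)
closure, and fusions that would exceed the finite system size `L` are
excluded from gain and loss alike, so edge mass is conserved exactly and
populations stay non-negative.  The stationary solution is found by damped
fixed-point iteration (under-relaxation 0.3, mass projected back to `L`
each sweep, loop populations eliminated analytically via
`u_loop[i] = 2 c1 u_open[i] / i`) and certified against the full
`master_rhs()` residual at `1e-8` of the largest population.  The open
lengths come out geometric up to the finite-size correction; loops carry
the extra `1/i` factor, so loops dominate among short segments (whenever
`2 c1 > 1`) and open chains among long ones.  At `L = 300` the stationary
distribution is statistically indistinguishable from long Gillespie runs
(chi-square, 1% level), which adjudicated the coefficient choices above.

## Cluster statistics and percolation

For `c2 > 0` the network splits into **clusters** (connected components),
each with `j` edges and `r` segments.  Segment lengths are geometric with
end probability `p` (`fit_geometric()`, maximum likelihood `p = 1/mean`),
so the size of an `r`-segment cluster is a sum of `r` geometrics — a
negative binomial on `j >= r` (`negbin_pmf()`, truncated at `L` and
renormalized).  The integral size distribution
`n(j) = sum_r g(r) negbin_pmf(j, r, p)` weights by the simulated count
`g(r)` of `r`-segment clusters, which has no known closed form.  The
cluster-size-versus-segment-count scatter has slope equal to the mean
segment length, with residual spread that peaks near criticality.

The reticulum percolates in `c2`: above a critical ratio a giant cluster
spans the system.  `percolation_scan()` scans log-spaced `c2` values at
fixed `c1`, averaging over decorrelated stationary snapshots (>= 20 per
point, spaced `L` events after a `10 L` burn-in), and estimates the
critical point as the peak of the susceptibility — the mean segment count
over non-giant clusters, "non-giant" meaning all but the single largest
cluster per snapshot, which matches the definition without an arbitrary
size threshold.  Because the finite-`L` susceptibility peak is asymmetric
and flat-topped, the default estimator fits a quadratic in `log c2` through
the maximum and its two neighbours only, and an optional refinement stage
(`refine = TRUE`) re-scans 7 points spanning a factor 4 around the coarse
peak with four-fold snapshot counts before re-fitting.  For the HeLa-scale
conditions (`c1 = 0.1`, `L = 3e4`, 24-point grid over `2e-6`–`2e-4`) the
refined estimate is reproducibly `c2 ~ 1.9e-5`–`2.0e-5` with a stationary
largest-cluster fraction of roughly a quarter of the edge mass at the
estimated critical point.  No phase transition exists in `c1`, which only
lengthens segments.

The scaled-down variant used in the fast tests exploits that the critical
ratio scales like `1/L` (branching must offset a segment count that grows
with `L`): a `L = 3e3` system is scanned on a ten-fold larger `c2` window
and shows the same qualitative transition in seconds.

```{r, eval = FALSE}
scan <- percolation_scan(0.1, 3e4, 10^seq(log10(2e-6), log10(2e-4),
                                          length.out = 24),
                         n_snapshots = 40, seed = 1, refine = TRUE)
scan$c2_critical
```

## Skeleton images and the overlay correction

`build_skeleton_graph()` consumes an already binarized, skeletonized image
(thresholding raw micrographs is out of scope) and connects foreground
pixels under 8-connectivity, labelling clusters by depth-first search.  Two
corrections counter centerline oversampling: a diagonal adjacency is
dropped when the two pixels also share an orthogonal foreground neighbour
(the diagonal is redundant with a two-step orthogonal path), and junction
pixels (reduced degree >= 3) that touch are contracted into one logical
branch node whose degree is the number of branches leaving the set.  The
exact contraction rule is this package's own reconstruction — validated by
the synthetic round-trip property below — since only the intent of an
oversampling correction is documented for the original analysis.

`generate_synthetic_skeleton()` rasterizes one-pixel-wide motifs (straight
open strokes, T junctions, rectangular loops, and deliberate two-stroke
crossings that emulate the confocal overlay artifact) with a two-pixel
clearance between motifs, and returns the exact ground-truth census.  The
suite requires 100/100 random specifications to round-trip exactly.  What
the generator does *not* emulate — curvature, variable stroke width,
skeletonization noise, dense entanglement — bounds what passing tests say
about real micrographs: they certify the graph-extraction and census logic,
not robustness to segmentation errors.

Confocal slices are about twice the tubule diameter, so unrelated organelles
overlapping along the optical axis masquerade as branch points.  With an
apparent degree-4 share `f` (percent of branching points) and artifact rates
`q4`, `q3` (the estimated fractions of apparent degree-4 and degree-3 nodes
that are overlay artifacts, with documented defaults 0.80 and 0.07),
`overlay_correction()` returns the corrected degree-3 share
`100 (100 - f)(1 - q3) / [(100 - f)(1 - q3) + f (1 - q4)]`; the artifact
rates are taken as inputs rather than derived from an occupancy model,
whose parameters are not available to the package.

```{r}
overlay_correction(17.0, 0.80, 0.07)
```

## Numerical and design choices, at a glance

* Problem sizes: the full study conditions (`L = 3e4`) are used for the
  steady-state, distribution-law and percolation analyses; the chain
  master equations are compared with simulation at `L = 300`, and the
  fast qualitative percolation check runs at `L = 3e3`.
* Goodness-of-fit: chi-square with right-tail pooling to expected counts
  of at least 5, one degree of freedom deducted per estimated parameter,
  assessed at the 1% level.
* Degenerate inputs: an all-zero propensity vector signals an absorbing
  state (flagged on the trajectory, not an error); the mean segment length
  is undefined in the single-loop regime and errors explicitly; non-binary
  skeleton images are rejected.
* Tie-breaks: `edge_choice` in tip-to-side fission may name an edge whose
  both ends sit in the branching node (a one-edge cycle); one of its slots
  is detached, which is the only census-consistent reading.
* `edges_from_length()` rounds the physical length to the nearest edge
  count; a 5000 µm chondriome at `l = 0.2` µm gives `L = 25000`, and the
  commonly quoted HeLa-scale value `L = 3e4` corresponds to about 6000 µm
  of tubule.

## Limitations

The model is non-spatial: it cannot address local crowding, cytoskeleton
anisotropy at the extreme cell periphery, or correlated fission–fusion at
single-motor time scales.  `L` is constant, so biogenesis/mitophagy
dynamics are outside scope.  The mean-field equations are accurate only for
large `L`; the package reports both descriptions so the user can quantify
the gap.  The skeleton module starts at a binarized skeleton and does not
attempt 3-D reconstruction.
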