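---
title: "Enumerating anchored loop conformations with hydrogen interval restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating anchored loop conformations with hydrogen interval restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

A loop of $n$ residues is anchored at three fixed C$\alpha$ atoms.  Between
the anchors the backbone is organized into three rigid bodies: anchor 1 to
anchor 2, anchor 2 to anchor 3, and a closing body that runs from anchor 3
through the last residue back to the N and C$\alpha$ of the first residue.
Within a body, every heavy-atom pairwise distance is treated as known (read
from the reference structure); across bodies, only distances fixed by
covalent geometry (atoms within two bonds) are known a priori.  The loop
closure problem asks for *every* conformation of the loop consistent with
this distance information.

`loopBP` formulates this as a Discretizable Distance Geometry Problem
(DDGP): a weighted graph over the atoms together with a total vertex order
such that the first three vertices have fixed positions and every later
vertex has at least three already-placed neighbors at known distance.  Each
vertex then lies on the intersection of three spheres -- at most two points
-- and the search space is a binary tree explored depth-first by
Branch-and-Prune (BP): extra edges reject candidate positions, and the
search backtracks on an empty candidate set.

The distinguishing choice is to include the backbone amide (H) and alpha
(HA) hydrogens in the order.  Hydrogens bonded to N and C$\alpha$ carry the
short-range hydrogen-hydrogen distances that NMR experiments can measure.
Every hydrogen pair closer than a 5 A cutoff contributes an interval
restraint $[d-\tau,\, d+\delta-\tau]$ with $\tau \sim U[0,\delta]$, so the
interval has width exactly $\delta$ and contains the true distance $d$ at a
uniformly random offset.  Exactly one of these intervals is *structural*:
the distance between the amide hydrogen of the residue after the last
anchor and the alpha hydrogen of the last anchor residue is the unique
discretization edge that is neither intra-body nor covalent.  The solver
samples it at $K$ uniformly spaced radii (endpoints included), giving up to
$2K$ candidates for that one vertex.  All other hydrogen-hydrogen intervals
act purely as pruning edges.

The hydrogen-reduced order ("Hbar") keeps only the two hydrogens of the
discretization edge.  Comparing solution counts under the two orders, via
the ratio $n_H / (n_H + n_{\bar H})$, quantifies how much conformational
space the hydrogen restraints eliminate.

Two facts about this comparison deserve care.  First, a structural
guarantee: the reduced order's constraint set, restricted to its vertices,
is a subset of the full order's, so on the same sample grid every H-order
solution projects onto an Hbar-order solution -- hydrogen restraints never
admit a backbone the reduced graph forbids, and the number of *distinct
backbone conformations* can only shrink.  Second, a caveat about raw
counts: an H-order solution additionally fixes eleven hydrogens, and each
alpha hydrogen has a mirror placement (the direction its C$\beta$ would
occupy -- C$\beta$ is not in the graph) that its exact edges cannot
distinguish.  When the contact intervals fail to exclude those mirrors,
raw H-order counts carry a $2^k$ hydrogen multiplicity and can exceed the
reduced order's count even though the backbone set shrank.  On idealized
synthetic loops, whose reconstructed hydrogens are exactly consistent and
whose contact nets are sparser than in compact crystal loops, this is the
typical outcome; the strong raw-count reductions reported on crystal-loop
benchmarks rely on dense contact networks binding both the hydrogen
mirrors and the backbone branches.  The package reports both views: raw
counts and ratio via `compare_orders()`, and the projection comparison in
the test suite.

```{r}
library(loopBP)
co <- generate_loop(loop_spec(6, seed = 3))
cmp <- compare_orders(co, 6, spec = interval_spec(delta = 0.5, seed = 3),
                      config = bp_config(K = 1000))
cmp
```

## Parameters that matter

* `delta` (A): interval width; the study grid is 0.2 / 0.5 / 1.0 / 1.5,
  with 1.5 the most challenging (loosest restraints).  `delta = 0`
  collapses every interval to the exact distance.
* `cutoff` (A, default 5): strict detection threshold for
  hydrogen-hydrogen contacts, the range of typical NMR-measurable NOEs.
  A pair at exactly 5 A is excluded.  The one structural discretization
  interval is always created regardless of the cutoff, since worst-case
  bounds for it can be estimated even when it is not measured.
* `K` (default 1000): uniform samples inside the discretization interval,
  endpoints inclusive.  Resolution of the enumeration: each sample can seed
  two branches.
* `tol` (A, default 0.01): constraint tolerance.  Exact edges must match
  within `tol`, intervals within `[lo - tol, hi + tol]`; the same value
  bounds the reported `max_err` of every returned solution, matching the
  benchmark reporting convention.
* geometry table: N-CA 1.458, CA-C 1.525, C-N 1.329, N-H 1.010,
  CA-HA 1.090 A; N-CA-C 111.0, CA-C-N 116.2, C-N-CA 121.7 degrees; planar
  trans peptides (omega = 180) with the amide hydrogen splitting the
  remaining in-plane angle at N evenly; HA and CB on the two remaining
  tetrahedral directions of CA (L-configuration).  These standard values
  are centralized in `default_geometry()` and editable there, since loop
  enumeration counts are mildly sensitive to them.

## Numerical design

**Tangent placements.**  An amide hydrogen is coplanar with its three
predecessor centers, so its three-sphere intersection is tangent by
construction ($h^2 \approx 0$ off-plane).  The solver accepts the in-plane
point whenever $-h^2 \le 2 r_\min \cdot tol$, which is exactly the
condition that its sphere residuals stay within `tol`.  Without this,
upstream rounding of a few $10^{-13}$ A would make every amide-hydrogen
branch infeasible.

**Over-determined vertices.**  A vertex with four or more exact
predecessors is uniquely determined.  Rather than trusting the first three
spheres and reject-filtering on the rest, the solver seeds a Gauss-Newton
least-squares fit over *all* predecessor spheres from each trilateration
candidate and accepts it only if the worst residual is at most `tol`.
Balancing the residuals this way stops placement error from compounding
along the order; with reject-only filtering, a sampled-radius offset of
$10^{-4}$ A at the interval vertex can grow past `tol` within six
placements through near-tangent intermediate geometries.

**Sampling resolution.**  When the true discretization distance lies close
to an extremum of the radius realizable on the two-exact-sphere circle,
the candidate position depends on the sampled radius like a square root,
and $K = 1000$ may place no sample close enough to keep the ground-truth
branch alive.  This is an inherent property of interval discretization by
sampling -- benchmark studies of this approach report individual crystal
loops left unsolved at $K = 1000$ for exactly this reason -- and the
remedy is to increase `K` (in our synthetic experiments, loops unsolved at
$K = 10^3$ are recovered at $K = 4 \times 10^3$).  It also
means solution counts are *not* monotone in `delta`: a wider interval
loosens the pruning windows (admitting more branches) but spreads the same
$K$ samples more thinly (fewer land inside each feasible window), and
either effect can dominate.

**Branch order and identity.**  Deterministic: interval samples in
ascending radius, the candidate on the positive side of the predecessor
plane first.  Candidates closer than $10^{-6}$ A are merged (tangency
duplicates, and mirror seeds that converge to the same least-squares
point).  Two runs with the same instance and configuration return
byte-identical solution sets, and multi-model PDB output is numbered in
branch-signature order.

**Scoring.**  Anchored RMSD: solutions and reference share the anchor
frame by construction (the first three vertices are pinned), so RMSD is
computed directly in that frame with no Kabsch superposition.  This is a
deliberate convention -- superposition would hide deviation that the
anchors are supposed to fix.  `max_err` is the worst absolute edge
residual, with interval edges contributing their distance outside
$[lo, hi]$.

## The vertex order in detail

`build_h_order()` reproduces, for the six-residue loop anchored at
residues 1/3/5, the canonical 29-vertex template (anchors CA1, CA5, C5
first, then the closing body walked backwards from the last residue, then
the middle body, then the first).  Three conventions are worth naming:

* the amide hydrogen of the loop's first residue is not part of the model
  (the template has $5n-1$ vertices, 11 hydrogens for $n = 6$);
* the loop-entry amide nitrogen is treated as rigidly attached to the first
  body's anchor frame (its distances to first-body heavy atoms are read
  from the reference like intra-body pairs) -- the closure convention that
  makes the first-body vertices placeable;
* for the canonical template, three first-body vertices (C2, CA2, N2) use
  the template's slightly smaller predecessor sets; the omitted pairs
  remain in the instance as pruning edges, so the feasible set is
  unchanged.  Other loop lengths use every available known-distance
  predecessor.

The generalization to other lengths emits the same local motif per body
and is validated structurally (`validate_order()`) and by exact-limit
recovery at 4, 6 and 8 residues.

## What the synthetic generator does and does not emulate

`generate_loop()` builds geometrically exact backbones from internal
coordinates: ideal bond lengths and angles, exactly planar trans peptides,
torsions either prescribed or drawn from a coarse two-basin
Ramachandran-like prior (alpha basin at (-63, -43), beta at (-120, 135),
sd 15 degrees, equal weights).  Hydrogens are placed by the same rules the
reconstruction module uses, so strip-and-replace round trips are exact and
every fabricated instance is feasible for its own ground truth.

Real crystal structures differ: bond lengths and angles deviate from ideal
values (the hydrogen reconstruction then carries residuals up to the
geometry deviation, and enumeration counts shift with the geometry
constants used), omega dips a few degrees from planarity, prolines and
glycines break the uniform backbone assumption, and real NOE data carry
assignment ambiguity and systematic (not uniform-interval) error.  Passing
tests on synthetic loops therefore validate the machinery -- ordering,
enumeration, completeness against exhaustive search, recovery -- not the
field performance of the restraint model on experimental data.

## Problem sizes used by the test suite and acceptance script

Module tests run on 4-12 residue loops with $K \le 1000$.  The recovery
study is 20 seeded six-residue loops crossed with the full `delta` grid at
$K = 1000$; completeness is checked on 50 instances truncated to 10
vertices ($K \le 20$) against exhaustive full-tree enumeration; the
order comparison uses 8 loops at `delta = 0.5`, $K = 1000$.  The
acceptance script solves 10 loops at `delta = 1.5` plus 6 loops under both
orders across the grid.  These sizes were chosen to exercise every code
path at interactive runtimes; the solver itself handles 12-residue
crystal-loop instances at $K = 1000$.

## Known limitations

* Loops must start at the first anchor and the third anchor must precede
  the last residue (contiguous three-body layout); side chains beyond CB,
  proline amide geometry and terminal hydrogens are out of scope.
* Glycine alpha hydrogens: one HA is placed at the virtual-CB-completed
  tetrahedral direction; the second is ignored.
* Interval placements are handled by sampling, not by an analytic
  circular-arc representation; counts therefore depend on `K`, and
  near-extremal geometries need larger `K` (see above).
* The hydrogen-pruning comparison holds when pruning edges are consistent
  with the reference conformation (as generated here); with inconsistent
  experimental restraints the H-order can in principle also discard the
  true conformation.
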