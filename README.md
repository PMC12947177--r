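# loopBP

Enumerating protein loop conformations by Branch-and-Prune distance
geometry, with backbone hydrogens and NMR-style hydrogen–hydrogen interval
restraints.

## The problem

A loop of *n* residues is anchored at three fixed Cα atoms, its backbone
organized into three rigid bodies whose internal distances are known.  The
loop closure problem asks for **all** conformations consistent with that
geometry.  `loopBP` casts this as a Discretizable Distance Geometry
Problem (DDGP): a weighted graph over the atoms with a vertex order
v₁, …, v₅ₙ₋₁ such that every vertex from the fourth onward has at least
three already-placed neighbors at known distance

  ‖xᵢ − xⱼ‖ = dᵢⱼ  for every edge {vᵢ, vⱼ},

so each placement is an intersection of three spheres (≤ 2 points) and the
space of solutions is a binary tree.  Branch-and-Prune (BP) explores the
tree depth-first, rejecting candidates against every additional edge and
backtracking on empty intersections — enumerating the complete solution
set rather than a single minimum.

The package's distinguishing feature is a vertex order that includes the
backbone amide (H) and alpha (Hα) hydrogens.  Hydrogen pairs closer than
5 Å — the range NMR can measure — enter the graph as interval restraints
[d − τ, d + δ − τ], τ ~ U[0, δ].  Exactly one such distance (between the
amide H after the last anchor and the Hα of the last anchor residue) is
used to *place* an atom, sampled at K uniform radii (≤ 2K branches); all
the others prune.  Solutions are scored by anchored RMSD (no
superposition; the anchor frame is shared by construction) and by

  max_err = max over edges of the absolute distance residual,

which is ≤ 0.01 Å for every returned solution.  Dropping all hydrogens
except the discretizing pair gives the reduced "H̄" order; the ratio
n_H / (n_H + n_H̄) of solution counts measures how much conformational
space the hydrogen restraints eliminate.

Intended users: structural bioinformaticians studying loop modeling,
distance geometry, or the value of sparse NMR restraints in conformational
enumeration.

## Worked example

Generate a six-residue loop with known ground truth, wrap its
hydrogen–hydrogen contacts in 0.5 Å intervals, and enumerate every
conformation consistent with the restraints:

```r
library(loopBP)

inst <- fabricate_instance(loop_spec(6, seed = 7),
                           intervals = interval_spec(delta = 0.5, seed = 1))
sols <- bp_solve(inst, bp_config(K = 1000))
sols
#> BP solution set (H-order, 6-residue loop): 354 solutions
#>   max_err: max 0.009901 A (tol 0.01)
#>   anchored RMSD vs reference: min 0.0006 / mean 1.8824 / max 3.7782 A
#>   tree: 34706 candidates generated, 18734 pruned, 2.60 s
```

354 embeddings satisfy every exact distance within 0.01 Å and every
interval within its bounds; the closest is 0.0006 Å from the generating
conformation (recovery), while others are genuinely different loop
closures up to 3.8 Å away.  Comparing vertex orders on the same loop:

```r
co <- generate_loop(loop_spec(6, seed = 7))
compare_orders(co, 6, spec = interval_spec(delta = 0.5, seed = 7),
               config = bp_config(K = 1000))
#> H vs Hbar comparison: n_H = 86, n_Hbar = 82, ratio = 0.512
```

Raw solution counts are not directly comparable across orders — the
hydrogen-rich order multiplies each backbone by the placements of eleven
hydrogens (each alpha hydrogen has a mirror position the model cannot
always exclude, having no C&beta;) — but projected onto the reduced
order's atoms, the 86 H-order solutions collapse to 28 distinct backbone
closures, a strict subset of the 82 the reduced order admits: hydrogen
restraints never admit a backbone the hydrogen-free graph forbids, and
here they eliminated 54 of 82.  A command-line wrapper (`exec/loopbp`)
exposes the same
pipeline as `synth` / `build-instance` / `solve` / `compare-orders` /
`report` subcommands for PDB input.

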