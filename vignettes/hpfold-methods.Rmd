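---
title: "Folding HP strings on the triangular lattice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding HP strings on the triangular lattice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpfold)
```

## The model

The hydrophobic–polar (HP) model reduces a protein to a string over
\{H, P\}: H residues are hydrophobic, P residues polar.  A *conformation* is
a self-avoiding walk on a lattice, one residue per site, with consecutive
residues on neighbouring sites.  The energy is minus the number of *bonds*:
pairs of H residues that occupy neighbouring sites but are not consecutive
in the string.  `hpfold` works on the two-dimensional triangular lattice,
where every site has six neighbours — in axial integer coordinates $(q, r)$
the offsets $(\pm 1, 0)$, $(0, \pm 1)$, $(+1, -1)$, $(-1, +1)$.  Maximising
bonds on this lattice is the optimisation problem the package addresses;
`fold()` implements a polynomial-time approximation, `enumerate_optimal()`
the exact (exponential) reference for short strings.

## The hexagon family

Let SumH ($z$) be the total number of H's.  The engine confines H's to a
finite hexagonal sub-lattice.  A *regular* hexagon of depth $x$ holds

$$z(x) = 1 + 3x(x+1)$$

points (a centre plus rings of $6, 12, \dots, 6x$), and induces

$$E(x) = 3\,(3x(x+1) + 1) - 3 - 6x$$

lattice edges: interior points carry six edge-ends, the six corners three,
the remaining perimeter points four, and each edge is shared by two points.
A hexagon of depth $x$ and length $\ell$ is the regular shape elongated
rightward: it holds $(2x+1)\ell + x^2$ points, organised as a *cap* of $x^2$
points plus $\ell$ *bends* of $2x + 1$ points each (a bend is the bent line
along the two right-hand sides).  When the point budget does not divide
evenly, the final bend is *partial* — a distorted hexagon — so that the
shape holds exactly $z$ points.

`initial_depth(z)` returns the largest $x$ with $1 + 3x(x+1) \le z$, found
by integer search rather than by evaluating the equivalent closed-form
radical, so no floating-point edge case can shift the depth at the
boundaries $z = 7, 19, 37, \dots$  `build_hexagon(z, x)` starts from
$\ell = \lfloor (z - x^2) / (2x+1) \rfloor$ and appends the fewest bends
needed to reach capacity $\ge z$, making the last bend partial if the fit
is inexact.  For budgets below 7 (no depth-1 hexagon exists) the engine
clamps the starting depth to 1 and accepts the degenerate thin shapes this
produces; a budget of a single H devolves to one lattice point.

Two empirical facts motivate starting deep: among the shapes the algorithm
can build for a fixed budget ($x = 1, \dots,$ `initial_depth(z)`), the edge
count never decreases with depth, and the regular shape (when it exists) is
the maximiser.  The test suite verifies both for all budgets up to 120
points.  Beyond `initial_depth(z)` the "hexagon" degenerates (its length
falls below depth + 1) and the closed-form edge count
$E = 3z - 1 - 2(\ell + 2x)$ turns decreasing, so deeper-than-regular shapes
are never constructed.

## One depth iteration

For each candidate depth the whole chain is placed around the hexagon:

1. **Start at the longest H-run** (ties: first occurrence).  Runs are
   visited in circular order; geometrically this is realised with two
   frontiers.  The *forward pass* places the longest run and everything
   after it.  Before the first P-run is routed, one outside neighbour of
   the longest run's first residue is *reserved* as a docking point; the
   *backward pass* then grows the runs preceding the longest run backwards
   from that point, which keeps the chain connected across the wrap-around.
2. **H-runs of length $\ge 3$** get a *region*: starting from two adjacent
   free boundary points (the entry — a neighbour of the current chain end —
   plus a partner), free hexagon points with at least two neighbours already
   in the region are added one at a time, deepest first.  This rule keeps
   the region connected, cut-vertex-free and of minimum internal degree 2
   by construction.  Ties on depth are broken towards the most boxed-in
   candidate (most neighbours occupied, in-region or outside the hexagon),
   which empirically stops one-point pockets from being stranded, then by
   the canonical $(r, q)$ point order.  `fold(..., tie_seed =)` replaces the
   canonical order by a seeded pseudo-random one for robustness probes.
3. **Threading the region.**  The region is traversed by a row-wise
   serpentine path (left-to-right, then right-to-left; with an odd row
   count the last two rows are woven in a single zigzag).  Greedy-grown
   regions can be too ragged for a row serpentine, so when it fails an
   exact Hamiltonian-path search (depth-first, with connectivity and
   endpoint-degree pruning, compiled code) takes over before fill-failure
   is declared.  The path starts at the entry and must end on the hexagon
   boundary at a point that still has a free outside neighbour — otherwise
   the following P-run could not leave the hexagon.  Several entry points
   and partners are tried before a traversal with a buried end is accepted.
4. **H-runs of length < 3** take boundary points next to the frontier,
   with the same escape requirement on their final point.
5. **P-runs go outside** as two columns: out for $\lceil m/2 \rceil$
   points, one side-step, and back for $\lfloor m/2 \rfloor$ points, so the
   final P sits on the first outside ring adjacent to a free boundary point
   — the next H-run's entry.  For odd $m$ the turn uses a 60-degree step
   (the difference of two adjacent lattice directions), without which the
   return column would end two steps away from the hexagon and the next
   H-run could not start adjacent to the last P.  Among feasible column
   pairs the one whose end offers the snuggest re-entry (most boxed-in free
   boundary neighbour) is chosen.  If no column pair fits in a crowded
   neighbourhood, a bounded exact search for an outside path of the right
   length runs; as a last resort the chain is extended by a backtracking
   step-by-step search.
6. **Overflow.**  When a region stalls below the run length (the budget
   argument: occupied points can make every candidate have fewer than two
   region neighbours), the traversal retreats to its last point that still
   has an outside escape and the remaining H's continue outside the hexagon
   in a single straight row, shifted outward on collision.  Later runs may
   re-enter the hexagon if a free boundary point is reachable.

Bonds are then counted (`count_bonds()`): all H–H neighbour pairs minus
those adjacent in the string.  The depth loop starts at
`initial_depth(SumH)`, decreases by one per iteration, keeps the
best-scoring depth, and stops after depth 1 or as soon as a depth scores
*strictly* fewer bonds than the incumbent (equal scores continue, and the
later of tied depths is kept, matching the reference procedure's update
rule).

Two engineering departures keep `fold()` total, both recorded in the
iteration audit: a depth whose placement stalls still contributes its
achieved bonds to the stopping rule but cannot be returned, so the loop
keeps descending while no depth has yet produced a complete self-avoiding
placement; and if every depth entombs the chain end (observed only on
extreme P-dominated random strings), the result falls back to a plain
serpentine block, flagged with `fallback = TRUE`.

## Counting identities

For a hexagon completely filled with H's from $n(H)$ runs,

$$B \;=\; E - (z - n(H)),$$

because every H except the last of each run spends exactly one of its edges
on a chain link.  With a single run this is Lemma-style $B = E - z + 1$,
giving $6x^2$ for the regular depth-$x$ hexagon.  The expectation analysis
below uses the slightly smaller $B = E - z$ (it drops the $+\,n(H)$ term),
which for an elongated $(x, \ell)$ hexagon evaluates to
$2z - 2(\ell + 2x) - 1$; an actual single-run full fill counts exactly one
bond more.  The tests pin down both conventions.

The $n^2$-point cap $B \le 2n(n-1)$ inherits the single-run counting.  With
$n(H)$ runs the package's derived corollary is
$B \le 2n(n-1) + (n(H) - 1)$, and the raw cap genuinely fails outside its
scope: the exact oracle shows the optimal folding of
`H1P1H1P1H1P1H1` (SumH $= 4 = 2^2$) scores 5 bonds against a cap of 4.
`bonds_upper_bound()` returns the raw cap; its documentation and the tests
carry the scope.

## Expected approximation ratio

Treating the H-run lengths of a string with SumH $= n^2$ as the parts of a
random integer partition, the expected number of parts is

$$E[P] = \frac{\sqrt 6}{\pi}\, n \left(\log n + \gamma -
\log\frac{\pi}{\sqrt 6}\right) \;\le\; 2n \log n \quad (n \ge 5),$$

with $\gamma$ Euler's constant.  Chaining the expected run length through
the hexagon geometry yields the expected ratio bound

$$\frac{B_{Ex}}{B} \;\ge\; 1 - \frac{2\log n}{n-1}, \qquad n \ge 6.$$

All logarithms here are base 2: the published ratio table
(0.142 / 0.466 / 0.677 / 0.809 at $n = 8, 16, 32, 64$) is reproducible only
with $\log 8 = 3$, and the package uses the same base throughout
`expected_num_parts()` for internal consistency rather than mixing bases
(the partition asymptotics are base-sensitive; this is a documented
convention, not a claim about the asymptotic constant).  Printed ratios are
truncated, not rounded — 0.8095 prints as 0.809 — and the tests compare
truncated values.  The ratio is an asymptotic expectation over partitions;
it is not an observable of any single desk-scale fold, so the package
covers it analytically (`expected_ratio()`, `ratio_table()`) plus the bound
properties above, and makes no claim that `fold()` attains $B_{Ex}$ on a
particular string.

## Synthetic data

`generate_fillable_string(x)` emits strings whose H-run multiset is exactly
the profile needed to fill a regular depth-$x$ hexagon — one run of
$2x + 1$, two of $2x$, and three each of $2x-2, 2x-4, \dots, 2$, which sums
to $1 + 3x(x+1)$ identically — in a seed-randomised order, interleaved with
P-runs drawn uniformly from $1..2x$ (commensurate with the H-run scale, so
the outside routing is exercised without dwarfing the hexagon;
`p_run_lengths` overrides).  `random_hp_string(length, h_fraction)` draws
i.i.d. residues.  Both restore the caller's RNG state.

What these emulate — and do not: the generators produce abstract H/P
compositions, not hydrophobicity-translated real proteins; i.i.d. residues
have geometrically distributed runs, unlike natural sequences.  A passing
property suite therefore demonstrates correctness of the combinatorics and
robustness of the placement across composition extremes, not predictive
value for any particular protein family.

The run *order* of a fillable string is random, and the greedy engine fills
the hexagon completely only for favourable orders (the worked 37-H example
does; a shuffled profile may fall short of the full-fill bond count at the
starting depth and can even score best one depth down).  This is a property
of the greedy rule, not of the profile: completeness of fill is
order-sensitive, which is why the fillability criteria are stated as
necessary, not sufficient, conditions.

## Numerical and scale choices

Everything is integer arithmetic on packed $(q, r)$ keys; there is no
floating point anywhere a count is decided.  The exact searches carry node
budgets (2×10^5 for region traversals, 2×10^4 for outside paths, 5×10^3
for last-resort extensions) — generous for the region sizes the engine
produces (at most $2x + 1 \le 13$ points per run at the depths realistic
SumH values reach) and hit only by degenerate shapes, which then take the
documented fallbacks.  The exhaustive oracle refuses strings longer than 12
residues by default (`max_length` raises it), quotienting the lattice's
mirror symmetry (first step fixed, first off-axis step restricted to a
half-plane) and pruning with the admissible 4-bonds-per-interior-H bound.  The
test suite works at these sizes: oracle comparisons on 200 random strings
of length up to 12, shape sweeps to 120-point hexagons, fill checks to
depth 3 — chosen so the whole suite documents the engine's behaviour in
well under a minute while still crossing every code path.

## Known limitations

* The per-depth placement is greedy and not optimal for that depth; the
  depth loop mitigates but does not remove this (the exact oracle
  quantifies the gap on short strings).
* Full fills of distorted hexagons are order-sensitive; the engine may
  leave interior holes where a hand placement would not.
* The expected-ratio analysis is asymptotic and, for multi-run strings,
  its $2n(n-1)$ denominator bound is approximate (see the cap's scope
  above).
* No 3D lattices, no side chains, no local-search refinement (pull moves),
  and no translation from amino-acid sequences to H/P strings.
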