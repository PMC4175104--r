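# hpfold

Approximate protein folding in the HP model on the 2D triangular lattice.

In the hydrophobic–polar (HP) model a protein is a string over {H, P}; a
fold is a self-avoiding walk on a lattice with consecutive residues on
neighbouring sites, and its quality is the number of *bonds* — pairs of H
residues on neighbouring sites that are not consecutive in the string.
Finding the bond-maximising fold is the classic lattice protein structure
prediction problem.  `hpfold` is for people studying lattice protein
models: it provides a fast approximation algorithm for the triangular
lattice (where every site has six neighbours), the combinatorial analysis
that goes with it, and an exact reference solver for short strings.

The engine works at the level of *runs* (maximal blocks of equal residues).
Writing SumH = z for the total number of H's, it:

1. picks the deepest regular hexagon that fits, x = max { x : 1 + 3x(x+1) ≤ z };
2. builds a depth-x hexagon of length ℓ = ⌊(z − x²)/(2x+1)⌋ (plus extra
   bends of 2x+1 points, the last possibly partial, to reach capacity z);
3. starting from the longest H-run and wrapping circularly, grows a
   cut-vertex-free region of deepest-first lattice points for each H-run of
   length ≥ 3 and threads it with a serpentine Hamiltonian path, puts
   shorter H-runs on the hexagon boundary, routes each P-run outside as an
   out-and-back column pair that re-enters next to the following H-run, and
   sends overflow H's outside in single rows;
4. counts bonds, reduces the depth by one and repeats, returning the best
   conformation once a depth scores strictly fewer bonds than the incumbent.

For a hexagon completely filled by H's from n(H) runs the count obeys
B = E − (z − n(H)), with E the hexagon's edge count
3(3x(x+1)+1) − 3 − 6x in the regular case; a single run filling the regular
depth-x hexagon scores exactly 6x².  The package also evaluates the
expected approximation ratio 1 − 2·log₂(n)/(n−1) for strings whose SumH is
n² (the run lengths behave like parts of a random integer partition).

## Worked example

The 70-residue string below has SumH = 37, exactly the point count of the
regular depth-3 hexagon, and its H-run profile (one 7, two 6's, three 4's,
three 2's) meets the hexagon-filling criteria:

```r
library(hpfold)
s <- parse_hp("H6P5H2P6H4P5H6P3H2P5H4PH7P6H2P2H4")
s
#> <hp_string> length 70, SumH 37, 9 H-run(s): H6P5H2P6H4P5H6P3H2P5H4P1H7P6H2P2H4

f <- fold(s)
f
#> <hp_fold> 62 bonds at hexagon depth 3 (2 depth(s) tried)
f$iterations
#>   depth bonds complete
#> 1     3    62     TRUE
#> 2     2    55     TRUE

count_bonds(f$conformation)
#> <hp_score> 62 bonds (90 H-H edges, 28 on the chain)
```

The engine fills the 37-point hexagon completely: of the 90 lattice edges
among the H sites, 28 are used by the chain (37 H's in 9 runs), leaving
62 bonds — the full-fill identity E − (SumH − n(H)) = 90 − 28.  The depth-2
iteration scores 55, strictly worse, so iteration stops and the depth-3
fold is returned.  `render_conformation(f$conformation)` draws the fold in
the terminal; `write_fold_result(f, "fold.tsv", "fold.json")` exports the
coordinates table and a JSON score report.

For short strings the exact solver gives the optimality gap:

```r
enumerate_optimal("H2PH3P2H2")$optimal_bonds  # exhaustive branch and bound
```

and the analysis functions reproduce the published ratio table:

```r
ratio_table()
#>   log2_n  n    z     ratio
#> 1      3  8   64 0.1428571
#> 2      4 16  256 0.4666667
#> 3      5 32 1024 0.6774194
#> 4      6 64 4096 0.8095238
```

## Command-line interface

```sh
Rscript inst/cli/hpfold.R fold --string H3P2H2P1H4 --report out.json --render
Rscript inst/cli/hpfold.R oracle --string HPHPPH
Rscript inst/cli/hpfold.R score --coords fold.tsv
Rscript inst/cli/hpfold.R generate --depth 3 --seed 1 --count 5
Rscript inst/cli/hpfold.R table1
```

(After installation the script lives at `system.file("cli", "hpfold.R",
package = "hpfold")`.)

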