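# basicpathways

Steady-state analysis of metabolic networks in growing cells: construct a
*nonnegative* linear basis of the stoichiometric null space — the **basic
pathways** — in polynomial time, with exact rational arithmetic throughout.

## The problem and the method

At steady state a network of m metabolites and r internal reactions
satisfies S v = 0 with v ≥ 0 (irreversible reactions, or reversible ones
rewritten by column negation/splitting). The admissible fluxes form a
pointed convex polyhedral cone, and the classical generating sets for it —
extreme pathways, elementary flux modes, minimal spanning sets — are all
NP-hard to enumerate and explode combinatorially.

In an exponentially growing cell every metabolite is also drained by a
dilution pseudo-reaction, so the stoichiometric matrix has the block form
**S = (S₀ | −Λ)** with Λ the diagonal dilution-rate matrix. That structure
gives the null space a closed-form *fundamental* basis

```
G = ( I_r ; Λ⁻¹ S₀ )
```

and a Gauss-elimination-like sequence of positive column operations turns G
into a nonnegative basis W = (BP₁, …, BP_r) whose columns are chemically
feasible pathways. The operations are guided by **singleton theory**: a row
with exactly one nonzero pins its column's coefficient in any decomposition
(v[i(j)] = ρ_j·w[i(j),j]), so pivots are chosen to minimize the loss of
singleton rows (Type-I cost) and the creation of singleton-free columns
(Type-II cost). If W ends up singleton *complete*, v = Wρ ≥ 0 ⇔ ρ ≥ 0, and
the columns of W are exactly the extreme rays of the flux cone; when W is
singleton *deficient*, the package computes exact rational lower bounds on
the coefficients of the deficient columns and decomposes any pathway by a
small exact solve.

Everything is exact: coefficients are rationals, zero tests are exact, and
ranks come from fraction-free elimination.

## Worked example: coupled glycolysis / TCA cycle

The built-in case model has 13 species (A–P; K, L, T, P are NADH, NAD⁺,
ATP, ADP) and 12 internal reactions — glucose/NAD⁺/ADP import, the two
phases of glycolysis, the lactate branch, and a four-step TCA cycle.

```r
library(basicpathways)

model <- build_glycolysis_tca_model()
S <- augment_with_dilution(model)$S
dim(S$num); nullity(S)
#> [1] 13 25
#> [1] 12

G <- build_fundamental_null_basis(model)
singleton_profile(G$G)$row_rank; sparsity(G$G, 2)
#> [1] 13
#> [1] 0.84

basis <- eliminate_negatives(G)
basis
#> <basic_pathway_basis: 25 x 12, singleton row rank 11, deficiency index 2, sparsity 0.68>
```

The null space is 12-dimensional; G has 13 singleton rows and sparsity
0.84. The elimination produces 12 nonnegative basic pathways at a Type-I
cost of 2 (13 − 11 singleton rows), with two columns left singleton-free.
Each column is an interpretable flow mode: nutrient imports balancing
dilution, textbook glycolysis, anaerobic fermentation to lactate, and
progressively longer TCA prefixes. Subtracting the citrate-forming pathway
from the full-TCA pathway isolates a pure TCA cycle with no glycolysis:

```r
tca_only <- rat_sub(basis$W, j = 12) - rat_sub(basis$W, j = 7)
rat_format(tca_only)[, 1]
#> "0" "1" "3" "0" "0" "0" "0" "0" "1" "1" "1" "1" "0" "0" "0" "0" "0" "0" "0" "0" "0" "1" "0" "3" "0"
is_extreme_ray(S, tca_only)                  # the pure cycle is an extreme ray
#> [1] TRUE
is_extreme_ray(S, rat_sub(basis$W, j = 12))  # the full-TCA column is not
#> [1] FALSE

decompose_pathway(basis, tca_only)$coefficients |> rat_format()
#> ... coefficient -1 on BP7 and +1 on BP12: a legitimately negative
#> coordinate from a singleton-deficient basis
```

Reading the vector: one NAD⁺ import (v2), three ADP imports (v3), one unit
of flux around the cycle (v9–v12), one NADH and three ATP leaving by
dilution — respiration as a self-contained flow mode.

Reversibility is handled by column negation or splitting; degenerate
networks (metabolites that can never be produced) are diagnosed and removed
by `reduce_network()`, and the elimination itself detects the deeper
degeneracy where the flux cone fails to span the null space.

## Command line

A thin CLI wraps the same functions (`inst/scripts/basicpathways`):
subcommands `compute`, `reduce`, `inspect`, `decompose`, `check-extreme`,
`bounds`, `casestudy`; all matrices move as labelled TSV with exact `p/q`
cells, reports as JSON. See `?bp_cli`.

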