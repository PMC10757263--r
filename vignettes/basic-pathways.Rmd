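---
title: "Basic pathways: nonnegative null bases for growing-cell metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basic pathways: nonnegative null bases for growing-cell metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basicpathways)
```

## The model

A metabolic network with $m$ metabolites and $r$ internal reactions inside a
cell growing at a steady exponential rate is described at steady state by
$S v = 0$, where the $m \times n$ stoichiometric matrix ($n = r + m$) has the
block form

$$S = (S_0 \mid -\Lambda),$$

with $S_0$ the internal-reaction stoichiometry and $\Lambda =
\mathrm{diag}(\lambda_1, \dots, \lambda_m)$ the dilution (or degradation)
rates: exponential growth drains every metabolite through one pseudo-reaction
per species. The default is $\Lambda = I_m$ — a uniform growth rate absorbed
into the dilution fluxes; per-metabolite rates cover chemical degradation
with or without growth. All coefficients are exact rationals (decimal input
like `"0.5"` is converted exactly), because the quantities this package
reasons about — singleton rows, sparsity, ranks, admissibility — are
zero-pattern properties that floating point cannot test reliably.

Chemical feasibility is nonnegativity: the admissible fluxes form the
pointed convex polyhedral cone $N_+ = \{v \ge 0 : S v = 0\}$. Reversible
reactions are handled either by negating a column (choosing the reverse
direction as positive, `reverse_reactions()`) or by adding the negated
column alongside the original (`split_reversible()`); both keep the
nonnegativity convention.

## The fundamental null basis and the elimination

Because the dilution block is invertible, the null space of $S$ has
dimension $r$ and a closed-form basis

$$G = \begin{pmatrix} I_r \\ \Lambda^{-1} S_0 \end{pmatrix},$$

computed without any linear solve (`build_fundamental_null_basis()`). $G$ is
*singleton complete*: every column has a singleton row (a row with exactly
one nonzero), namely its identity row, so coordinates in this basis can be
read off directly. Its bottom block inherits any negative entries of $S_0$,
so its columns are not yet chemically feasible.

`eliminate_negatives()` converts $G$ into the basic-pathways matrix $W$,
whose columns are nonnegative null vectors that still form a basis, using
only the three basis-preserving column operations (positive scaling, swap,
adding a positive multiple of one column to another). A negative entry
$w_{ij} < 0$ in the working row $i$ is cleared by $c_j \leftarrow c_j + a
c_k$ with a pivot column $k$ satisfying $w_{ik} > 0$ and $a = -w_{ij} /
w_{ik}$.

Three design choices here were genuinely open and are frozen as follows.

* **Pivot rule.** Among candidate pivots, the operation with the
  lexicographically smallest key (measured Type-I singleton cost, measured
  Type-II singleton cost, nonzero count of the pivot column, column index)
  is preferred; negatives within a row are cleared left to right. Type-I
  cost is the drop in singleton row rank, Type-II the rise in the
  deficiency index (number of singleton-free columns); minimizing them
  keeps the final basis easy to invert (see decomposition below) and, as a
  byproduct, sparse.
* **Sweep order.** Rows of the dilution block are processed in metabolite
  order (rows $r+1$ up to $n$). Processed rows can never regain a negative
  entry whatever the sweep order, because every operation adds a positive
  multiple of a column that is nonnegative on all processed rows. The
  metabolite-order sweep clears each species' dilution row while the
  columns that produce that species are still simple, so pathway chains
  (glucose to pyruvate to the TCA cycle, in the case model) accumulate
  forward through the network; sweeping the other way forces early rows to
  absorb whole downstream subnetworks and produces a visibly denser basis.
  On the case model the difference is singleton row rank 11 and deficiency
  2 versus 10 and 3.
* **Completion by search.** A row of the working matrix whose entries are
  all $\le 0$ with at least one $< 0$ can never be repaired — positive
  column combinations only push its entries further down. A purely greedy
  pivot choice can manoeuvre the matrix into that dead end even when a
  nonnegative basis exists, so the elimination is implemented as a
  depth-first search over pivot choices in heuristic-key order, pruning
  any state containing such a stuck row. When greed succeeds the search
  *is* the greedy pass; backtracking happens only when a greedy prefix
  runs a later row out of positive entries. If no pivot sequence completes
  the elimination reports failure — which is a finding about the network,
  not a numerical accident: the flux cone then does not span the null
  space, and no nonnegative basis exists (the TCA-reversed case-model
  variant is exactly such a network; its cone spans only 7 of 12
  dimensions).

Columns of $W$ are finally scaled to primitive integer vectors, and every
operation (including those scalings) is logged, so replaying the log on $G$
reproduces $W$ bit-exactly.

The optional `sparsify()` pass looks for guarded column subtractions
$c_j \leftarrow c_j - a c_k$ with the largest $a > 0$ keeping $c_j \ge 0$,
accepted only if the (deficiency index, total nonzero count) pair strictly
decreases lexicographically. Subtraction is outside the positive-coefficient
elimination, which is why this is a separate pass; on the case model it
replaces the full-TCA column with the TCA-only pathway.

## Decomposition, bounds, extreme rays

If $W$ is singleton complete, $v = W \rho$ is nonnegative iff $\rho \ge 0$,
and each coefficient is read off a singleton row: $\rho_j =
v_{i(j)} / w_{i(j)j}$. The columns of a singleton-complete $W$ coincide (up
to scaling) with the extreme rays of $N_+$. When $W$ is deficient
(deficiency $d \ge 1$), `decompose_pathway()` reads off the complete-column
coefficients and solves an exact $d$-dimensional residual system for the
rest; the $r$ flux components used (singleton rows plus the solve's pivot
rows) are the independent parameters, and the remaining $m$ components are
reported as dependent — the compatibility relations enforcing $S v = 0$.

Deficient-column coefficients may be negative within explicit bounds:
for $d = 1$, $\rho_1 \ge -\min_i \left( \sum_{j \ge 2} \rho_j w_{ij} \right)
/ w_{i1}$ over rows with $w_{i1} > 0$ (`coefficient_lower_bounds()`); for
general $d$, the constraint system $\sum_k |\rho_k| w_{jk} \le c_j$ over
rows where every deficient entry is positive, plus a directional bound
`r_min_surface()` that returns the exact threshold magnitude along any
nonnegative direction. Two conventions are worth noting: the strict
inequalities of the underlying derivation are implemented as closures (the
admissible set is the closed cone, including boundary pathways with zero
fluxes), and the direction vector is used at its given rational scale
rather than normalized to unit Euclidean length, so thresholds stay exact
rationals.

`is_extreme_ray()` implements the support-rank criterion: an admissible
$v \neq 0$ spans an extreme ray iff
$\mathrm{rank}\, S[:, \mathrm{supp}(v)] = |\mathrm{supp}(v)| - 1$, with the
rank computed by exact fraction-free elimination.
`enumerate_extreme_rays_bruteforce()` enumerates supports and keeps the
nonnegative nullity-one survivors; it is exponential by nature, guarded to
16 columns, and exists as an independent oracle for the test suite, not as
a production enumerator.

## Degenerate networks

A metabolite whose $S_0$ row has no strictly positive entry can never be
produced, so at steady state its concentration goes to zero and every flux
touching it vanishes. `reduce_network()` removes such rows and their
incident columns, iterating to a fixed point because column removal can
expose new positive-free rows; the single-sweep description applies
recursively, and the fixed point is order-independent (verified by property
test rather than assumed). Removed metabolites are reported with this
steady-state interpretation, not silently dropped. Note the criterion is
necessary but not sufficient for the cone to span the null space — the
TCA-reversed variant passes reduction untouched yet still has no
nonnegative basis, which the elimination itself then detects.

## The case study

`build_glycolysis_tca_model()` reconstructs a 13-species, 12-reaction
coupled glycolysis/TCA model (species A–P, with K, L, T, P playing NADH,
NAD$^+$, ATP, ADP) whose augmented matrix is $13 \times 25$ with null-space
dimension 12. Two TCA coefficients are not stated numerically in the
narrative the model derives from; they are fixed by requiring the reference
TCA-only pathway (`bp12s_reference()`) to be an exact null vector, which
forces the oxidative leg to carry three ATP per turn and the
isocitrate-to-succinyl-CoA step to carry no cofactors. The reconstruction
is validated in the test suite by three constraints: $S \cdot
\mathrm{BP12s} = 0$ exactly, singleton row index of $G$ equal to 13, and
sparsity of $G$ equal to 0.84 at two decimals.

```{r case}
model <- build_glycolysis_tca_model()
basis <- eliminate_negatives(build_fundamental_null_basis(model))
basis
```

The computed $W$ has singleton row rank 11 (so the Type-I cost of the whole
transformation is $13 - 11 = 2$) and deficiency index 2, and the difference
between the full-TCA column and the citrate-forming column reproduces the
reference TCA-only pathway exactly, which passes the extreme-ray test while
the full-TCA column itself fails it:

```{r eq40}
S <- augment_with_dilution(model)$S
tca_only <- rat_sub(basis$W, j = 12) - rat_sub(basis$W, j = 7)
rat_equal(tca_only, bp12s_reference())
c(is_extreme_ray(S, tca_only), is_extreme_ray(S, rat_sub(basis$W, j = 12)))
```

The sparsity of this $W$ is 0.68 at two decimals (97 nonzero entries of
300). A substantially sparser nonnegative basis does not exist for this
network: exact enumeration shows the cone has 14 extreme rays, every
admissible vector's support is a union of ray supports, and the twelve
sparsest independent rays already carry 85 nonzeros (sparsity at most
0.72). Reported values of 0.84 for a 25-by-12 nonnegative basis of this
model are therefore not reproducible; 0.84 is exactly the sparsity of $G$.

Reversibility handling is exercised by three variants. Reversing `v9`
alone makes isocitrate degenerate (reduction removes it). Splitting `v9`
into a forward/reverse pair gives a 26-by-13 basis whose extra column is
the reverse direction. Reversing `v12` yields a singleton-complete $W$
whose twelve columns are exactly the twelve extreme rays of that variant's
cone. Reversing the whole TCA cycle leaves reduction with nothing to
remove, yet the elimination correctly reports that no nonnegative basis
exists — glycolysis in this model nets no spare ATP, so the reversed
ATP-consuming leg can never carry flux.

## What the random-model generator emulates

`random_model()` draws $S_0$ with small integer coefficients (magnitude 1–3,
the range of typical stoichiometries) at a chosen density, and resamples
each row until its sum is strictly positive. Positive row sums make the
uniform flux $v_0 = 1$ strictly admissible, so the flux cone is solid and a
nonnegative basis is guaranteed to exist — the property the test suite
needs in order to assert that the elimination always terminates with
$S W = 0$ exactly. Planted positive-free rows (option `degenerate_rows`)
exercise the reduction path with known ground truth. What these models do
not emulate: conservation relations (rank-deficient $S_0$ with moiety
conservation), reversible thermodynamic couplings, or networks whose cone
is nonempty but not solid; on real reconstructions with those features the
elimination may legitimately report that no nonnegative basis exists, as
the TCA-reversed variant shows. Passing property tests therefore certify
exactness and termination on productive networks, not universal
feasibility.

Problem sizes in the test suite (hundreds of models with $m \le 6$,
$r \le 8$, brute-force oracles up to 11 columns) are chosen so the whole
suite runs in well under a minute; the algorithms themselves are
polynomial in the network size except for the deliberately exponential
brute-force oracle.

## Numerical choices and limitations

* Rationals are stored as reduced integer pairs in doubles; arithmetic
  aborts if any intermediate exceeds $2^{53}$, rather than silently losing
  exactness. The case study peaks far below this.
* Ranks use Bareiss fraction-free elimination; no floating-point SVD or QR
  anywhere in the pipeline (a QR oracle appears only in tests, as an
  independent cross-check).
* The pivot heuristic is a greedy local minimization with deterministic
  tie-breaks; it does not prove global optimality of the total singleton
  cost, and no claim of maximum sparsity is made (the sparsest-null-basis
  problem is NP-hard).
* Basic-pathway bases are not unique. `permuted_basis()` exposes the row
  permutation degree of freedom explicitly: permuting metabolites, running
  the pipeline, and un-permuting yields a generally different valid basis.
  All bases produced this way satisfy the same invariants.
* The whole pipeline is deterministic given the model; the only randomness
  in the package is the fixture generator's seed.
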