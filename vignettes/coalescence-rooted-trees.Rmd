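---
title: "TMRCA inference from rooted gene trees: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TMRCA inference from rooted gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaltree)
```

## The inference problem

Given `n` aligned DNA sequences sampled at random from a large,
constant-size Wright–Fisher population, we want the time `t_n` to their
most recent common ancestor (TMRCA), in units of `N` generations.  The
package targets data like mitochondrial control-region samples: no
recombination, high mutation rate, substitutions that are effectively
unique and irreversible per site (the infinite-sites assumption).  Under
that assumption the only informative columns are the segregating sites;
identical sequences are collapsed into *lineages* carrying a multiplicity.

The prior ("predata") law is Kingman's coalescent: `t_n = sum_{j=2}^n w_j`
with independent `w_j ~ Exp(j(j-1)/2)`, tree length `l_n = sum_j j w_j`,
and closed-form moments implemented in `predata_moments()` — in particular
`E(t_n) = 2(1 - 1/n) -> 2`.  Mutations fall on branches as a Poisson
process of rate `theta/2` with `theta = 2 N mu` **assumed known** (supplied
by the user from external sources; the package never estimates it).
Conditional on the tree length, the number of segregating sites is
`Poisson(theta * l_n / 2)` (`mutation_count_pmf()`).  All times stay in
units of `N` generations; `to_years(t, N, Y)` is the single, explicit
conversion (generation time `Y` is conventionally 20–25 years for humans;
no default is applied).

## Rooted gene trees and the 0/1 matrix duality

At each segregating site exactly one of the two observed bases is the
mutant; a choice of mutant base per site is a *labeling*, i.e. a 0/1
lineage-by-site matrix `X`.  A labeling corresponds to a rooted gene tree
exactly when the column 1-sets form a laminar family — no pair of columns
shows the three gametes (0,1), (1,0), (1,1).  `is_valid_matrix()`
implements this as the pairwise three-gamete scan, `O(n s^2)`; at desk
scale (`s` a few tens) the quadratic cost is irrelevant and the scan is the
clearest correct formulation.  `build_rooted_tree()` then constructs the
tree: distinct column 1-sets become clades, sites with identical 1-sets
stack on one edge, lineages with all-zero rows hang directly beneath the
root.  `tree_to_matrix()` inverts it, and the pair round-trips exactly.

The data determine the *unrooted* gene tree uniquely (`to_unrooted()`:
contract mutation-free edges, suppress the root and any anonymous
pass-through vertices, concatenating mutation lists).  The root, however,
is only constrained to one of `s + 1` positions: at any vertex of the
unrooted tree, or between two adjacent mutations on an edge.
`enumerate_rooted_trees()` produces all of them by recomputing, for every
candidate position, which side of each mutation the root lies on — the
algebraic equivalent of sliding the root around the unrooted tree — and
verifies, as a postcondition, that exactly `s + 1` pairwise distinct valid
labelings result.

Two conventions make the enumeration deterministic:

* **Within-edge mutation order.**  Mutations stacked on one edge are not
  ordered by the data; the package fixes ascending site position within
  each segment.  A root placed "between two adjacent mutations" therefore
  splits an edge's mutation list at a gap of that canonical order.  The
  test suite accordingly compares a simulated true genealogy against the
  enumeration up to this within-edge convention (the true root may split
  stacked mutations in a non-canonical order; the geometric root position
  and all column 1-sets still match).
* **Tie-breaking in the starting labeling.**  `label_least_shared()` calls
  the *multiplicity-weighted* minority base mutant (the data model counts
  sequences, not distinct lineages) and breaks exact weight ties toward the
  lexicographically smaller base.

Sequences containing ambiguity codes are rejected rather than imputed, and
a column with three or more observed bases raises an
`coaltree_infinite_sites_violation` condition: such data needs upstream
cleaning (removal of sequences carrying repeat mutations at a site) that
this package deliberately does not automate, since the choice of which
sequences to drop is a study-level decision.

## The estimator

Writing `k = (k_2, ..., k_n)` for the number of mutations that occurred
while the sample had `i` ancestors, the conditional mean

`E(t_n | k, s, theta) = 2 * sum_i (k_i + 1) / (i (i + theta - 1))`

is exact and cheap (`posterior_mean_given_k()`); at `n = 2` it reduces to
the Gamma conjugate posterior mean `(k + 1)/(1 + theta)`, which the tests
use as an oracle, and at `k = 0`, `theta = 0` it telescopes to the predata
mean.  The difficulty is that `k` is unobserved.  `estimate_tmrca()`
treats the `s + 1` rooted trees as equally likely a priori (a uniform prior
over rootings, deliberately avoiding recursion-based tree probabilities)
and Monte-Carlo-averages the conditional mean over simulated histories.
Per replicate:

1. **Waiting times.**  One vector `w` is drawn by inverse CDF
   (`sample_waiting_times()`, `u` on the open unit interval so `log(1-u)`
   is finite) and shared by all `s + 1` trees — the replicate index is the
   only thing that varies across trees, which also reduces between-tree
   Monte-Carlo variance.
2. **Backward allocation** (`allocate_waiting_times()`): `w_n` is placed
   first, then `w_{n-1}`, ..., `w_2`.  Descending from the root, a child
   subtree with `c >= 2` active leaves is chosen with weight `c`; lineages
   already fully coalesced at the current node (available ancestors,
   including single-copy children) can merge among themselves with weight
   equal to their number; the rule is applied recursively inside the
   chosen subtree.  Which pair merges inside a group of identical leaves
   is irrelevant — only the active count decrements.  A fully coalesced
   clade becomes one available lineage of its parent scope, so a
   single-leaf top-level branch merges only at the root scope.  This is
   the leaf-count-proportional scheme applied globally at every step; on
   the packaged mitochondrial tree the first-step weights are
   `(3, 24, 5, 19, 3)/54` and, inside the 24-leaf clade, `(19, 4)/23`
   (marginally `(19, 2, 2)/23` over its sub-units), which the tests assert
   both structurally and empirically.
3. **Mutation placement** (`allocate_mutations()`): each tree segment
   spans the coalescent intervals between the step at which its clade
   finished coalescing and the step at which its ancestral lineage merged
   upward; the segment's mutations are split across those intervals by a
   multinomial draw with probabilities proportional to the allocated
   interval lengths.  By construction a segment with mutations always
   spans at least one interval; a defensive contract check raises rather
   than reallocating silently.  Summing over segments gives `k_r`, always
   conserving `sum(k_r) = s`.

The estimate is the running mean of
`2/(s+1) * sum_r sum_i (k_{r,i} + 1)/(i (i + theta - 1))`.  The factor 2
is used consistently with the `n = 2` conjugate oracle (one printed
variant of the formula chain omits it; the oracle settles the question).
Convergence is assessed by batch means of size `max(100, M/50)`: the run
stops when the relative change of the cumulative estimate between batches
falls below `tol` (default `1e-3`), reporting the replicate count used, a
Monte-Carlo standard error from the per-replicate values, and the
per-batch trace.  The replicate loop is implemented twice: a readable
recursive R reference and an iterative Rcpp core (`engine = "cpp"`,
default, roughly three orders of magnitude faster); the suite cross-checks
the two and, on tiny problems (`n <= 4`, `s <= 2`), checks both against
hand-derived brute-force simulators that share no code with the package.

`posterior_mean_given_s()` conditions on the mutation count alone by exact
enumeration of all compositions of `s` into `n - 1` intervals (guarded to
small problems).  The normalisation of this average is genuinely
ambiguous in the formula chain the estimator comes from: a `2/(s+1)`
prefactor is combined with a sum over compositions, but the number of
compositions equals `s + 1` only at `n = 3`.  The package defaults to
dividing by the number of compositions (a proper uniform average, which at
`n = 2` agrees with `posterior_mean_given_k`) and offers
`normalization = "printed"` for the literal form; the expectation applied
to each composition is likewise exposed as an argument rather than baked
in.

## The synthetic-data generator

`simulate_infinite_sites(n, theta)` draws a full coalescent genealogy
(uniform merge order over active pairs — the model the waiting-time prior
describes), drops Poisson(`theta/2` per unit length) mutations on every
branch, gives each mutation its own site, and encodes haplotypes as DNA
with a uniformly drawn ancestral base and its transition partner as mutant
(`encode_as_bases()`), mirroring the transition-only character of
control-region data; identical sequences are collapsed into lineages.  It
records every truth — waiting times, per-interval mutation counts, the true
labeling and its rooted tree, and the seed — so parameter-recovery and
pipeline properties are testable without any external data.

What it deliberately does **not** emulate: recombination, recurrent or
back mutation, transversions (unless `transitions_only = FALSE`),
population structure, growth, selection, sequencing error or missing
data.  Green tests on synthetic data therefore demonstrate correctness of
the inference machinery under the model's own assumptions, not robustness
to their violation in real data.

## Default problem sizes and numeric choices

The test suite and the acceptance script run at desk scale, chosen to make
Monte-Carlo assertions sharp at three standard errors while keeping the
default run in minutes: `1e5` replicates for predata moment checks (sample
sizes 2, 10, 55), `2e4`–`1e5` for the large-`n` limit at `n = 1000`,
`4e4` replicates against the brute-force oracles, and `M = 1e4` with
`tol = 1e-4` for the end-to-end mitochondrial runs (three seeds, pairwise
agreement within combined Monte-Carlo error).  The worked example fixes
`theta = 4` as an externally supplied control-region-scale rate; the
estimator treats it as known by assumption, and sensitivity to `theta` is
the user's analysis, not the package's.

Other numeric details: all RNG flows through R's stream (`set.seed()` at
the entry points; the Rcpp core uses R's own uniform generator, so results
are reproducible across engines at the distribution level, and exactly
reproducible per engine); multinomial cell probabilities are recomputed
per segment per replicate from the allocated waiting times; degenerate
inputs (`s = 0`) short-circuit to the closed form — with `theta = 0` the
estimator returns `2(1 - 1/n)` to machine precision on every replicate.

## Limitations

* Constant population size; no growth or structure extensions.
* `theta` must be supplied; mis-specification propagates directly into the
  estimate.
* The uniform prior over the `s + 1` rootings is a simplification: the
  recursion-based tree probabilities it replaces weight rootings
  unequally, so the two approaches can differ on strongly asymmetric
  trees.  The package reports a point estimate with Monte-Carlo error, not
  a full posterior distribution.
* The estimator conditions on the infinite-sites assumption holding
  exactly; violations must be resolved upstream.
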