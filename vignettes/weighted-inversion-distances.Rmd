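---
title: "Weighted inversion distances from confluent rewriting systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted inversion distances from confluent rewriting systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbinv)
```

## The problem

Bacterial chromosomes evolve in large part by *inversions*: a contiguous
block of regions is excised and reinserted in reverse orientation.  The
classical inversion distance between two gene arrangements counts the
minimum number of inversions separating them, implicitly weighting every
inversion equally.  Comparative evidence, however, repeatedly finds short
inversions over-represented relative to long ones, which motivates a
*weighted* distance: each inversion operator carries a positive cost, and
the distance between two arrangements is the minimum total cost over all
inversion scenarios transforming one into the other.

`kbinv` computes this weighted distance *exactly*, for any model in which
the allowed rearrangement operators are invertible, by working in the
permutation group the operators generate.

## Genomes, operators and the group

A chromosome with `n` regions is a map from positions `1..n` to regions,
i.e. a permutation `pi` (one-line notation: `pi[i]` is the region in
position `i`).  The inversion operator `t[i,j]` reverses positions
`i..j`; as a permutation of positions it is the involution
`(i,j)(i+1,j-1)...`, e.g. `t[1,4] = (1,4)(2,3)`.

Products are read left to right: in `a b`, the factor `a` acts first on a
position, so `compose(a, b)[x] = b[a[x]]`.  Applying an operator `t` to an
arrangement `pi` gives the arrangement `x -> pi[t[x]]`
(`apply_inversion()` and `compose()` agree by construction, and a test
pins this so the convention can never silently flip).  The element
separating arrangements `pi1`, `pi2` is `compose(pi2, inverse(pi1))`, and
the genome distance is the *weighted length* of that element: the least
total weight of any word in the generators spelling it.

Two concrete models ship with the package:

* **linear all-inversions** (`linear_inversion_model(n)`): all
  `n(n-1)/2` operators `t[i,j]`, default weights `j - i`
  (length-proportional; `"unit"` gives the uniform-cost comparison
  model);
* **circular adjacent-inversions** (`circular_adjacent_model(n)`):
  `s[i] = (i, i+1)` for `i < n` plus the wrap-around swap
  `s[n] = (1, n)`, all at unit weight, for circular chromosomes.

`generic_model()` accepts any inverse-closed set of labeled permutations
with positive weights.

## From presentation to confluent rewriting system

Minimal-weight words are found with string rewriting.  A presentation
supplies relations among the generators; oriented by a *reduction order*
they become rewrite rules, and Knuth–Bendix completion
(`knuth_bendix()`) extends them to a *confluent* system in which every
word has a unique normal form reachable regardless of rewriting
strategy.

The reduction order is the **weighted lexicographic order**
(`reduction_order()`): `u > v` when `u` has larger total weight, with
exact-weight ties broken at the first differing letter by a fixed
generator precedence.  With strictly positive weights this order is
total, translation-invariant and well-founded, so oriented rules always
terminate, and the normal form of any word for a group element `g` is
the *order-least* word for `g` — in particular a minimum-weight spelling.
That is the central mechanism of the package: build the system once, and
each distance query is one normalization.

### Faithful presentations

Care is needed in what "the presentation" is.  For an involution
generating set it is tempting to present the group by the pairwise power
relators `(g h)^m = e` (with `m` the order of the product `g h`) plus the
involutions `g g = e`.  Those relators form an abstract Coxeter-type
presentation, and for inversion generating sets the abstract group they
define is generally *infinite* — already for three regions the three
inversions carry the (3,3,3) triangle geometry.  A completion run against
such a presentation either converges to a system for the wrong (infinite)
group or fails to terminate.  `linear_inversion_presentation()` therefore
emits a third, equally verified family: for each `t[i,j]` with
`j - i >= 2`, a factorization relation expressing it as the bubble word
over adjacent inversions.  Adjacent transpositions present the symmetric
group, so the augmented presentation is faithful; and since the *reduced*
confluent system for a given order is uniquely determined by the group
and the order — not by which faithful presentation was completed — rule
counts and normal forms are unaffected by this choice.
`generic_model()` achieves faithfulness for arbitrary generator sets by
adding Cayley-graph relations `w_x s = w_{xs}` obtained from a
breadth-first enumeration of the concrete group, which restricts that
entry point to groups small enough to enumerate.  The circular model's
relation families (involutions, non-adjacent commutations, braid
relations, and the wrap-around relation defining `s[n]`) are already
faithful as given: eliminating `s[n]` leaves the Coxeter presentation.
Every relation of every presentation is verified by evaluation in the
concrete permutation group at construction time; an unverifiable
relation raises immediately.

### Completion strategy

Completion maintains a priority queue of unresolved equations (initial
relations, collapsed rules, critical pairs).  Each entry is keyed by the
weight of its larger side at creation — keys are immutable, so the queue
order never goes stale — and entries are processed smallest first with
FIFO tie-breaks.  Resolving an entry normalizes both sides, orients the
survivor into a rule, *interreduces* (rules whose left side the new rule
rewrites are retired and requeued; affected right sides are
renormalized), and enqueues the new rule's critical pairs against all
active rules, both orientations and self-overlaps included.  Critical
pairs whose parent rule has since been retired are dropped; the retired
rule's own requeued equation regenerates whatever is still needed.
Processing order matters enormously in practice: keying entries by
up-to-date small-first priorities lets small "real" rules collapse
transient junk early, where naive strategies wander.  The run is fully
deterministic — identical inputs give byte-identical systems — and a
limit breach (`max_rules`, `max_iter`) raises a `kb_incomplete`
condition carrying the partial system rather than returning a
non-confluent result silently.

`is_confluent()` re-certifies a finished system from scratch by
exhaustively resolving every critical pair of every rule pair, reporting
the number of pairs checked.

### Problem sizes

The test suite completes the linear model for `n = 3..6` (9, 44, 204 and
1049 rules; seconds on one CPU for `n <= 5`, under a minute for
`n = 6`) and the circular model through `n = 6`.  The linear `n = 7`
and circular `n = 8` systems build with the same entry points but take
hours rather than minutes at this implementation's maturity, so the
routine suite exercises distances at `n = 7` through the Cayley-graph
oracle instead;
exhaustive engine-vs-oracle equality is asserted at `n <= 5`, where the
whole group can be checked element by element.

## The independent oracle

Everything the rewriting engine computes is cross-checkable against an
implementation that shares none of its machinery: `cayley_graph()`
materializes the weighted Cayley graph (vertices the group elements,
edges one generator step, edge weight the generator weight) and
`geodesic_distance()` / `all_distances()` run Dijkstra on it via igraph.
Exhaustive agreement of `weighted_length()` with the oracle over every
element of the group (both models, `n = 4, 5`) is the decisive
correctness gate in the test suite, because a shortest path on an
explicit graph is immune to any subtlety in orders, orientations or
critical pairs.  For groups too small to justify completion the oracle
also serves as the fallback distance backend
(`distance_matrix(..., sys = NULL)`).

## Circular genomes

A circular chromosome has no distinguished origin or strand, so
arrangements differing by rotation or reflection of the position circle
are the same genome.  `circular_distance()` quotients this out: the
distance is the minimum of the weighted length over the dihedral orbit
`compose(compose(s, g2), inverse(g1))`, `s` ranging over the `2n`
rotations/reflections (`dihedral_elements()`).  This convention is
isolated in one function on purpose: other quotient conventions exist
(which side the symmetry acts on), and all invariance properties tested —
zero distance within an orbit, invariance under relabeling both genomes
simultaneously, symmetry — hold for any of them.  The adjacent-inversion
generator set is normalized by the dihedral group, which is what makes
the simultaneous-relabeling invariance exact.

## Trees and output formats

`distance_matrix()` produces a labeled symmetric matrix;
`write_phylip()` emits the square PHYLIP dialect (names padded to 10
characters, 6 decimals — the writer is the single formatting authority
and the bundled reader round-trips it).  `neighbor_joining()` performs
Saitou–Nei agglomeration (via ape's implementation behind this module's
surface) and recovers additive matrices exactly; negative branch lengths
on non-additive input are clamped to zero with a warning, leaving
topology untouched.  `write_newick()` rotates children into alphabetical
order before serializing so equal trees always produce identical text,
and `topology_split()` reports which quartet pairing an unrooted tree
separates — the statistic used to compare weighted against uniform
models, where the two weightings of the same inversion set can cluster
the same four genomes differently (`AC|BD` versus `AB|CD`).

## Numerical and design choices

* **Exact arithmetic end to end.**  Weights are exact rationals
  (`rational()`); for the completion engine they are scaled by the least
  common denominator to integers, so order comparisons are exact 64-bit
  integer arithmetic, never floating point.  Distances convert to
  decimal only in the PHYLIP writer.
* **Default precedence.**  Generator precedence (the tie-break in the
  order) defaults to ascending weight, ties broken by the model's label
  order (`t[i,j]` sorted by `(i, j)`).  Confluent-system *size* can
  depend on this choice, which is why it is configurable on every model
  constructor; the shipped defaults are the ones whose rule counts the
  acceptance suite pins.
* **Degenerate inputs.**  Relations orienting to `trivial` are dropped;
  the empty word never appears as a left side (it would contradict
  `lhs > rhs`); `read_rws()` rejects files whose rules violate the
  order or fail evaluation.
* **Interning.**  Group elements are interned by their one-line image
  string during enumeration; the Cayley graph is built once per model
  and reused across a matrix computation.

## What the fixtures do and do not show

Test genomes are either the four printed `S_7` permutations of the
clustering experiment or seeded uniform random permutations
(`random_genomes()`, Fisher–Yates).  Random permutations exercise the
full group and are the right stress test for exactness claims, but they
are not evolutionary simulations: real genome pairs are typically *few*
inversions apart, with length-biased inversion sizes.  Passing tests
therefore certify the algebra and the optimality of distances, not any
statement about statistical behavior on real bacterial data.

## Limitations

* State space grows as `n!`: completion is practical to `n ~ 7` linear /
  `n ~ 8` circular, and the oracle to `n ~ 7`.  The rewriting system
  answers *per-query* cost, not group growth.
* Unsigned permutations only: no orientation signs, no multi-chromosomal
  genomes, no insertions/deletions.  Operators must be invertible.
* The dihedral quotient convention for circular genomes is fixed but
  documented and swappable, as discussed above.
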