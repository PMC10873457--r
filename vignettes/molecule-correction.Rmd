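---
title: "Molecule auto-correction: model, policies and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecule auto-correction: model, policies and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molautofix)
```

## The problem

Virtual molecule generators routinely emit molecular graphs that no
chemist would accept: impossible valences, exotic charge states, bonding
patterns never seen in real compounds. `molautofix` treats such a graph
the way a spell checker treats a misspelled word. Local structural
features of the molecule are looked up in a dictionary built from
reference chemistry; features absent from the dictionary are *foreign*,
and a tree search edits the graph one perturbation at a time until every
feature is familiar, preferring repairs that stay structurally close to
the input.

The central design commitment is that **chemically invalid molecules are
first-class inputs**. `molgraph` performs no valence checking,
`parse_smiles()` accepts any syntactically well-formed SMILES, and every
downstream computation (keys, familiarity, perturbations) is defined on
arbitrary attributed graphs.

## Structural keys

Every atom is described by the integer tuple `(D, V, Z, Q, H)`: degree
(bonded heavy-atom neighbours), valence (sum of the atom's bond orders —
hydrogens and formal charge deliberately excluded, to avoid cyclic
dependencies between properties), atomic number, formal charge and
hydrogen count. The order encodes decreasing significance: a wrong
degree is a deeper structural problem than a wrong hydrogen count. The
four proper prefixes of the tuple are the *partial atom keys*; because
each extends the previous one, the shortest foreign prefix pinpoints the
property that went wrong. A *bond key* is the two endpoint atom keys
(sorted, so lookups are orientation-independent) plus the bond order; a
*circular environment key* is a Morgan-style iterative hash of the ball
of topological radius `r` around an atom, initialized from atom-key
hashes, in the spirit of ECFP features.

Hydrogens are counts on atoms, never graph nodes, and bond orders are
integers in `{1, 2, 3}`: aromatic input is kekulized on read (a
backtracking perfect matching over the aromatic bonds), and output
SMILES are always written in Kekulé form.

All hashing is 64-bit FNV-1a over serialized integer tuples — a fixed,
platform-independent scheme whose identifier (`fnv1a64/v1`) is written
into every persisted dictionary and checked on load, so dictionary files
are bit-portable. We accept the negligible 64-bit collision risk; a
frozen hash value in the test suite guards the scheme against accidental
change.

## The chemical dictionary and familiarity

`chemical_dictionary()` counts every key occurrence in every reference
molecule — occurrence counting rather than per-molecule presence, so
that successor-value rankings reflect abundance. A key is *familiar*
when its count strictly exceeds the threshold `t` (default 0; strict,
so that the default makes every once-seen key familiar).

Familiarity of a molecule with `n = n_a + n_b + n_e` keys of which `n_f`
are familiar is scored two ways:

* `f1 = n_f / n`, the fraction of familiar keys — a similarity
  coefficient to some unknown correct molecule, so `1 - f1` estimates
  the distance still to travel;
* `f2 = 1 / (n - n_f + 1)`, which depends only on the *number* of
  foreign keys. `f1` can be gamed by appending familiar atoms (both
  numerator and denominator grow); `f2` cannot, which makes it the
  better optimization target.

Key labels honour the containment hierarchy explicitly: a bond key is
labelled foreign if either endpoint atom key is foreign, and an
environment key is foreign if any member atom or in-environment bond is.
On a dictionary built from a reference set this cascade changes nothing
(counts are monotone along containment), but it keeps the dependency
property intact under arbitrary key ablation, e.g. in sensitivity
analyses with `dict_drop_keys()`.

## Diagnosis and the expansion policy

`diagnose()` finds the most significant foreign key. For atoms, that is
the shortest foreign prefix; the property extending the last familiar
prefix is the culprit (`(4,6,6)` foreign with `(4,6)` familiar blames
the atomic number of a hexavalent carbon). If all atom keys pass, a
foreign atom-key *pair* blames the bond, then a foreign full bond key
blames the order. If only environments are foreign, the atom or bond
participating in the most foreign environments is targeted, ties broken
by the rarest atom/bond key, atoms before bonds, then lowest index.

`candidate_perturbations()` enumerates the single-edit neighbourhood
lazily, targeted repairs first:

* culprit `Z`, `Q` or `H`: set that property, with replacement values
  ordered by their successor frequency under the familiar prefix;
* culprit `V`: bond-order changes on incident bonds first (ranked by the
  frequency of the resulting bond key), then bond and neighbour
  deletions;
* culprit `D`: bond deletions, then neighbour deletions — insertions are
  not used to fix degrees (high degrees are vanishingly rare in organic
  chemistry);
* culprit pair/order/environment: perturbation kinds in ascending
  significance (hydrogen < charge < element < bond type < bond deletion
  < atom deletion < bond insertion < atom insertion).

The remainder of the stream covers the complete neighbourhood in
(target priority, kind significance, value frequency) order, so an
exhausted stream *is* the brute-force one-edit neighbourhood — the test
suite asserts set equality against an independent enumeration oracle.

The edit universe is explicit: hydrogen counts `0..4`, charges `-2..2`,
elements from the organic subset `{B,C,N,O,F,P,S,Cl,Br,I}` (each universe
extended by any value present in the dictionary), bond orders `{1,2,3}`,
bond insertions only between atoms at topological distance ≥ 3 (no
3-membered-ring shortcuts), and atom insertions drawn from the
dictionary's degree-1 atom keys with the bond order matching the key's
valence. Deleting an articulation atom or bond keeps the largest
fragment (ties to the fragment holding the lowest index), so molecules
stay single-component as the dictionary assumes.

After each bond-changing edit, touched atoms are *sanitized*: the
hydrogen count is reset to `smallest standard valence >= V` minus `V`,
using a charge-adjusted valence table for the organic subset. Atoms
without a table entry, or already above their maximum standard valence,
are left alone — erasing the very defects the search must navigate would
be counterproductive. Sanitization is scoped to atoms whose incident
bonds changed: re-sanitizing after `set_hydrogens` would undo the edit
itself. An inserted atom is not sanitized either, since its invariants
are fully specified by the edit. The sanitizer can be disabled
throughout.

## The tree search and its selection policies

The input molecule is the root. Each iteration selects one eligible
vertex (foreign, not fully expanded, and above the depth limit) and
consumes one candidate edit; the child is discarded if it duplicates an
existing tree molecule or violates a user constraint, otherwise scored
and inserted. The search stops at the first vertex with `f1 = 1`, at the
tree-size budget, or when no eligible vertex remains; unsolved searches
report the best vertex so far (maximum `f2`, ties to the smallest
distance from the input). Structural distance is `1 -` Jaccard index of
radius-2 circular-substructure fingerprints folded to 2048 bits
(`ecfp4_tanimoto_distance()`).

Selection policies (ties always break by insertion order):

* **bfs** — shallowest first; the gold standard for output closeness but
  exponentially expensive with depth;
* **greedy_f2** (and **greedy_f1**, kept mainly to demonstrate the
  alkane-growth exploit that motivates `f2`) — exploitation only: cheap
  and almost always solves, but may drift far from the input;
* **greedy_ratio** — `f1 / d(u,v)`, with `d` replaced by `1/1024` at the
  root so the root stays maximally attractive without dividing by zero;
* **uct** — UCB1 descent from the root: a vertex is exploitable by the
  mean `f1` of its children (its own `f1` until it has any) plus
  `c * sqrt(ln N_v / n_v)`; unexpanded children score infinity. The
  default `c = 0.5` is the benchmark optimum. This is a plain tree
  search, not MCTS: no rollouts, the familiarity heuristic itself values
  vertices;
* **astar** — minimizes `d(u,v) + 1 - f1(v)`. Since `f1` also counts
  atom and bond keys, `1 - f1` is not strictly admissible as a bound on
  the fingerprint distance, but it very rarely overestimates, so A*
  behaves near-optimally; implemented with a priority heap and lazy
  deletion of stale entries;
* **mlr** — minimizes the linear prediction of the root-to-solution
  distance, `0.42 d(u,v) - 0.91 f1(v) + 1.18` by default. Training
  triples `(d(u,v), f1(v), d(u,w))` are collected along root-to-solution
  chains of budget-generous BFS corrections (`collect_training_triples()`;
  a solution at depth `k` yields `k + 1` triples, the solution included)
  and refit by ordinary least squares (`fit_mlr()`);
* **objective** — maximizes `f1(v) * o(v)` for a user objective
  `o ∈ [0, 1]`; the product, rather than a sum, prevents trading one
  objective for the other.

Duplicate detection uses a near-canonical graph hash: Morgan invariants
refined until the partition stabilizes, combined with sorted edge
records. Two isomorphic graphs always collide (good); two distinct
graphs colliding is astronomically unlikely and would merely merge a
vertex, never corrupt an output — solved outputs are re-verified
`f1 = 1` by construction. An iteration cap of `50 * max_tree_size`
guards against degenerate candidate streams.

## The breaker and what the benchmark shows

Benchmark inputs are made, not found: `random_perturbation_sequence()`
applies uniformly random edits (kind first among applicable kinds, then
target and value uniformly; the same value ranges as the edit universe),
sanitizing after each, which mimics how broken molecules arise in
practice — plausible graphs drifting away from real chemistry. The
bundled reference list (`druglike_reference()`, 238 small organic
drug-like molecules validated and kekulized with a standard
cheminformatics toolkit) stands in for the multi-hundred-thousand
compound database a production dictionary would use.

Because the fixture dictionary is small, its key vocabulary is sparse:
foreignness is *more* common than under a database-scale dictionary, and
repairs have fewer familiar alternatives to choose from. Passing tests
therefore demonstrate the mechanics and the policy orderings —
greedy familiarity solving the largest fraction, BFS yielding the
closest outputs, perturbations degrading familiarity monotonically on
average — not absolute solved rates of a production deployment. The
benchmark in the test suite uses 50 molecules, break levels {1, 3, 5},
a 5,000-vertex budget and a radius-1 dictionary, comparing the
exploration-only (`bfs`), exploitation-only (`greedy_f2`) and balanced
(`astar`, `mlr`) policies — the corners of the design space whose
orderings the benchmark asserts; `greedy_ratio` and `uct` run under the
same driver and are exercised at smaller scale in the unit tests. These
sizes keep a full single-core suite run tractable while leaving every
qualitative ordering measurable. Radius-2 dictionaries are fully
supported and used the same way.

## Numerical and degenerate-input choices

* Empty molecules featurize to `n = 0`; familiarity is undefined there
  and errors.
* A unit tree budget returns the root as `budget_exhausted` output.
* `f2` of a correct molecule is exactly 1 in floating point, since
  `n - n_f` is an exact integer.
* Dictionary TSV serialization sorts keys bytewise and stores counts as
  decimal integers, so round trips are lossless and files diff-able.
* Derived seeds (`seed * 48271 + i * 16807 mod 2^31 - 19`) keep every
  per-molecule breaker series independently reproducible from one
  integer seed.

## Known limitations

Stereochemistry, isotopes and ring-membership invariants are not part of
the key definitions (ring membership would be a natural extension of the
Morgan initial invariants). Familiarity is binary per key; a
frequency-continuous notion is deliberately out of scope. The breaker's
uniform edit distribution is a modelling choice, not a claim about any
particular generator's failure modes. Synthesizability scoring and
retrosynthetic validation of corrected molecules are outside the
package's remit.
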