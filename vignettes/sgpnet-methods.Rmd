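---
title: "Models and methods behind sgpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sgpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgpnet)
```

`sgpnet` bundles four analyses that are usually scattered across tools:
interactome queries, disease/pathway projections, SBML model generation,
and synchronous Boolean dynamics. This vignette explains the models each
one implements, the parameters that matter, and the design choices made
where more than one reading was defensible.

## The interactome container

A PPI network is stored as two tibbles: nodes (keyed by a stable `node_id`,
optionally carrying an NCBI-style integer gene id, a display symbol, a
UniProt-style accession, a cellular location and annotation terms) and
undirected edges stored canonically with `a <= b`. Keeping the gene id as a
first-class column makes cross-mapping to other resources trivial, and it
is why identifier collisions are tolerated: two nodes may share a symbol as
long as their `node_id`s differ — symbols are display items, resolution
prefers exact ids and treats an ambiguous symbol as an error rather than
guessing.

Loading deduplicates: `(a, b)` and `(b, a)` are the same edge, and a pair
seen twice merges its provenance tags into one set. This makes loading
idempotent (a file loaded twice equals the file loaded once) and gives the
round-trip guarantee the tests rely on: `read(write(G))` preserves node and
edge sets exactly. Column mappings are explicit configuration, never
sniffed, so loads are byte-reproducible. Self-loops are kept in storage but
excluded from neighborhood expansion unless explicitly requested; curated
PPI data essentially never uses them and silently widening a ball with a
self-loop would distort per-level counts.

Conflicting cellular locations from different sources are not merged; the
container holds a single location string per node and leaves
reconciliation to the data preparer.

## Neighborhood semantics

`expand_neighborhood(seed, k)` returns the subgraph *induced* on all nodes
within shortest-path distance `k` of the seed — including edges between
two nodes at the same level. Published neighborhood counts of the form
"119 proteins possessing 124 edges" are counts of such induced subgraphs,
and the induced reading is the standard one; it is nevertheless a choice
(an alternative counts only tree edges discovered by the BFS), so it is
stated here and pinned by tests against a brute-force BFS oracle rather
than asserted about any external tool. Per-level reporting gives both the
cumulative ball (`n_nodes`, `n_edges` at distance ≤ d) and the incremental
count (`n_new_nodes` at distance exactly d), because both styles appear in
practice. The degree cap defaults to 3 — beyond that a human interactome
ball typically engulfs most of the giant component — and is overridable.

## Disease and pathway projections

The disease–disease projection supports two edge rules because the
literature uses both. In `shared` mode (default) two diseases are linked
when their gene sets intersect, weighted by the intersection size — the
classic bipartite projection of a disease–gene table. In `interacting`
mode they are linked when some gene product of one has a PPI edge to some
gene product of the other, weighted by the number of interacting cross
pairs; this requires an interactome. The mode is recorded in the output so
downstream files are self-describing.

Pathway crosstalk is counted on shared *members* (node identifiers, after
the same resolution as PPI queries, not display names): each catalog
pathway sharing at least one member with the query is reported with the
shared count and the member list, sorted by count descending then name so
output is deterministic. Whether crosstalk should count shared nodes or
shared edges is genuinely ambiguous; shared nodes is the primary statistic
and a `shared_edges` column (same class, endpoints and sign in both
pathways) is emitted alongside so the other reading costs nothing.

Pathways themselves are typed: members are signals, proteins or genes, and
interactions fall into the six class pairs (signal–signal through
gene–gene), each signed activation/inhibition. The constructor enforces
that an edge's class matches its endpoints' species, which catches most
hand-editing mistakes in pathway files.

## SBML export

`build_sbml()` maps a typed pathway to SBML Level 2 Version 4 — the
dialect of the CellDesigner era, still the most widely readable — with one
species per member and one reaction per interaction, assuming first-order
mass-action kinetics. Activation X → Y is encoded as synthesis of Y with X
as modifier and rate k·[X]; inhibition as degradation of Y with X as
modifier and rate k·[X]·[Y]. This particular encoding was chosen because
it yields simulatable dynamics without introducing auxiliary species;
both law templates are overridable. Every rate constant is a local
parameter initialised to `k_default` (1.0) and annotated as
unparameterized, signalling that the value is a placeholder until measured
kinetics are supplied. Species initial amounts default to 1.0 and are
per-member overridable; compartments come from member locations through an
explicit mapping with a `cell` default.

Output is deterministic — members in canonical order, reactions in the
pathway's canonical interaction order, generated ids stable — so identical
input produces byte-identical XML, which is what the round-trip tests
assert. Structural validation (`validate_sbml()`) is implemented in the
package: unique ids, species in declared compartments, every species
referenced by a reaction declared, every kinetic-law symbol resolvable to
a species or local parameter, and every species used in a law declared as
reactant, product or modifier of that reaction.

## Synchronous Boolean dynamics

A Boolean network over nodes `1..N` assigns each node a binary state; all
nodes update simultaneously, so the dynamics is a deterministic map on the
`2^N` global states and every orbit ends in a cycle. Cycles are the
attractors — fixed points (singletons) correspond to resting cellular
phenotypes such as quiescence, longer cycles to sustained oscillations
such as the division cycle — and the set of states draining into a cycle
is its basin. Basins partition the state space, a property the test suite
checks on random networks.

Two update semantics are provided, reflecting the two ways regulatory
logic is usually written down:

* **logic mode** — each node carries an expression over `$node[j]`
  literals with `!`, `&`, `|` and parentheses, precedence NOT > AND > OR,
  parsed by a recursive-descent parser that reports line and column on
  syntax errors and rejects missing, duplicate, or out-of-range
  definitions;
* **threshold mode** — each node carries a signed regulator list and
  switches on exactly when `sum_j a_ij S_j(t) >= 1`. The threshold is
  sharp: a sum of 0 or less gives 0, with no stochastic tie-breaking.
  A node with no regulators holds its state, unless flagged
  *self-degrading*, in which case it decays to 0. Holding is the default
  because constant inputs (a node whose rule is its own literal) are the
  common idiom for external signals; self-degradation is the opt-in for
  species that disappear without active production.

The network's *edge count* is defined as the number of literal occurrences
across rule right-hand sides (threshold mode: regulator entries). A
regulator used in two clauses of one rule counts twice. This is the
definition under which the bundled ten-node cell-cycle rule set has
49 edges, and it is recomputable from the parsed rules. Clamped nodes keep
their full rule in the count — the count describes the model, not the
perturbation.

State strings put node 1 leftmost, and the integer encoding of a state
uses node 1 as the most significant bit, so numeric order equals
lexicographic order of strings and every file the engine writes is sorted
both ways at once. Cycles are reported canonically, rotated to start at
their lexicographically smallest state, which makes attractor sets
comparable across implementations by plain equality.

`find_attractors()` resolves all `2^N` states in one pass: it follows each
unresolved state's path, marking positions on the current path; hitting
the current path closes a new cycle, hitting a resolved state inherits its
attractor, and either way every state on the walked path is assigned in
O(1) amortised per state. An independent oracle used in the tests and in
the acceptance script does it the slow way — following every state's orbit
separately with explicit cycle detection — and the two agree exactly on
hundreds of random networks (N ≤ 4 for the oracle's sake; basin sizes
included).

Exhaustive enumeration is exponential by nature, so `N` is capped at 20
(about a million states, comfortably desk-scale) with an explicit override.
SAT- or BDD-based attractor detection for larger networks and asynchronous
update schemes are out of scope; the engine is synchronous and exact.

Mutant analysis is clamping: `apply_perturbation()` fixes chosen nodes at
0 (knockout) or 1 (constitutive expression), returns a modified copy, and
refuses to re-clamp a node to a conflicting value. In the bundled
cell-cycle model, clamping Rb to 0 removes the quiescent fixed point and
leaves only cyclic attractors — the loss of the restriction point expected
of an Rb knockout.

## Fixtures and generators

The fixture interactome is intentionally minimal: the amyloid trio
(A2M–APOE, APOE–APP), angiogenin with exactly its seven annotated first
neighbours, and nothing else, so worked-example queries have exact
expected answers. The synthetic presenilin pathway exists to exercise the
typed-pathway container and SBML export; it is a structure-only stand-in,
flagged synthetic in name and documentation, not a curated pathway.

Random generators (interactomes, Boolean networks, disease tables, pathway
catalogs) are pure functions of their arguments: seeding uses R's default
Mersenne–Twister stream through `withr::with_seed`, so repeated calls
agree bit for bit and never disturb the caller's RNG. They emulate
*structure* — exact node/edge counts, bounded in-degrees, overlapping gene
sets — not the degree distributions, study bias or noise of real curated
interactomes, so tests passing on generated data demonstrate algorithmic
correctness, not biological fidelity. Problem sizes were chosen
desk-scale: property tests run networks up to N = 10 (1024 states),
oracle-equivalence comparisons use 100 networks with N ≤ 4, and graph
properties use a few hundred nodes.

## Known limitations

* Attractor detection is exhaustive-enumeration only; networks beyond ~20
  nodes need symbolic methods this package does not provide.
* The SBML validator checks structural consistency, not the full SBML
  specification; models destined for strict consumers should additionally
  pass a reference validator.
* Disease projections implement both published edge rules but no
  significance testing of overlap weights.
* Annotation categories are fixed to function/phenotype/pathway.
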