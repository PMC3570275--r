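# sgpnet

Network analysis around disease genes: protein–protein interaction (PPI)
neighborhoods, disease–disease and pathway-crosstalk projections, SBML export
of typed signal–gene–protein pathways, and a synchronous Boolean network
engine with exhaustive attractor analysis.

## What it does

Neurodegenerative disorders, like most complex diseases, are network
phenomena: mutations perturb the interactions of signalling molecules, genes
and proteins rather than any single component. `sgpnet` provides the
computational pieces such an analysis needs, in a tidy interface (tibbles in,
tibbles out):

* **interactome handling** — read tab-separated interaction tables into a
  deduplicated undirected graph with identifier maps (gene id, symbol,
  protein accession), attach function/phenotype/pathway annotations, and
  write Cytoscape SIF files with a node-attribute sidecar;
* **PPI queries** — induce the subnetwork on a gene list (its pairwise
  "binary associations"), expand the degree-*k* neighborhood of a seed
  protein (induced subgraph on the shortest-path ball, per-level counts
  reported, *k* ≤ 3 by default), and filter or group networks by annotation;
* **projection networks** — weighted disease–disease graphs from shared (or
  PPI-interacting) disease genes, and pathway–pathway crosstalk ranked by
  shared components over six typed interaction classes (signal–signal,
  signal–protein, signal–gene, protein–protein, protein–gene, gene–gene);
* **SBML export** — convert a typed pathway into an SBML Level 2 Version 4
  model with first-order mass-action rates: an activation edge X → Y becomes
  synthesis of Y at rate k·[X] with X as modifier, an inhibition edge becomes
  degradation of Y at rate k·[X]·[Y];
* **Boolean dynamics** — parse rule files in the `$node[i] = expr;` syntax
  (`!`, `&`, `|`, parentheses; NOT > AND > OR), or build threshold networks
  from signed regulator lists where node *i* obeys

  S_i(t+1) = 1 ⇔ Σ_j a_ij · S_j(t) ≥ 1,  a_ij ∈ {+1, −1},

  update all nodes synchronously, enumerate the full 2^N state space, find
  every singleton (fixed-point) and cyclic attractor with exact basin sizes,
  follow trajectories, and run clamping-based mutant analyses.

The bundled fixtures include the ten-node mammalian cell-cycle logical model
(CycD, Rb, E2F, CycE, CycA, p27, CDC20, CDH1, UbcH10, CycB; 49 regulatory
edges) and a small annotated PPI example around angiogenin (ANG) and the
amyloid trio A2M/APOE/APP, so everything below runs offline.

## Worked example: cell-cycle attractors

```r
library(sgpnet)

net <- cellcycle_network()
glance(net)
#> # A tibble: 1 × 5
#>   n_nodes n_edges mode  n_clamped n_self_degrading
#>     <int>   <int> <chr>     <int>            <int>
#> 1      10      49 logic         0                0

atts <- find_attractors(enumerate_state_space(net))
atts
#> <attractor_set> 2 attractor(s) over 1024 states
#>   [1] singleton, length 1, basin 512: 0100010100
#>   [2] cyclic, length 7, basin 512: 1000001110 -> 1010000110 -> 1011000100 ->
#>       1011100100 -> 1001100000 -> 1000100011 -> 1000101011
```

State strings list node 1 (CycD) leftmost. The singleton attractor
`0100010100` — Rb, p27 and CDH1 on, all cyclins off — is the quiescent G0
state of the cell; half of the 1024 initial states drain into it. The other
half enter a seven-state cycle that traces the synchronous progression of
the division cycle. Knocking out the tumour suppressor Rb (clamping node 2
to 0) removes the restriction point:

```r
mutant <- apply_perturbation(net, c(Rb = 0))
glance(find_attractors(enumerate_state_space(mutant)))
#> # A tibble: 1 × 5
#>   n_states n_attractors n_singleton n_cyclic largest_basin
#>      <dbl>        <int>       <int>    <int>         <int>
#> 1     1024            2           0        2           512
```

the quiescent fixed point is lost and only cyclic attractors remain — the
mutant cell cannot stop dividing.

PPI queries work the same way:

```r
g <- toy_interactome()
tidy(induce_subnetwork(c("A2M", "APP", "APOE"), g))[, 1:2]
#> # A tibble: 2 × 2
#>   a     b
#>   <chr> <chr>
#> 1 A2M   APOE
#> 2 APOE  APP

nb <- expand_neighborhood("ANG", 1, g)
sort(filter_network(nb, "function", "apoptosis")$nodes$node_id)
#> [1] "ACTN2"   "ATP6AP1" "PTEN"    "TDGF1"   "TNFSF8"
```

A command-line wrapper covering all features ships at
`system.file("cli", "sgpnet", package = "sgpnet")`, e.g.
`sgpnet boolean attractors --rules cellcycle.bool --out transitions.txt`.

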