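---
title: "Duplication-loss reconciliation with species networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplication-loss reconciliation with species networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlrecon)
```

## The model

A rooted binary phylogenetic *species network* is a rooted DAG whose leaves
are extant species, whose internal nodes are speciations (one parent, two
children) or hybridizations (two parents, one child), and whose root has two
children.  A *gene tree* is a rooted binary tree whose leaves are gene
copies labelled by the species that carry them; a species may carry several
copies.

A *reconciliation* maps every gene-tree node to a network node together with
an event: contemporary (a leaf mapped to its species), speciation, or
duplication.  A speciation at node `u` must sit at a network node with two
*separated paths* — paths leaving through different children — down to the
images of `u`'s children; a duplication only requires that evolution never
runs upwards.  Losses are counted along shortest paths: the distance from a
node `x` down to a node `y` is the smallest number of speciation (or root)
nodes `z` with `y < z <= x` over all directed paths, so hybridization nodes
never cost anything, and the top endpoint counts while the bottom one does
not.  With positive event costs `dup_cost` (per duplication) and `loss_cost`
(per loss), the cost of a reconciliation is
`dup_cost * duplications + loss_cost * losses`.

Two optimisation problems are solved:

1. **Best switching.**  A *switching* keeps one incoming edge per
   hybridization node (edges starved by this choice are switched off too)
   and thereby displays a tree inside the network.  The task is to find the
   switching whose displayed tree minimises the classic duplication-loss
   reconciliation cost.  On a switching, losses only count nodes untouched
   by switched-off edges (`V_on`): a gene absent from the unused parent of a
   hybrid is not a loss, because each gene of a hybrid species is inherited
   from one parent only.  This models *ancient* hybridization, where
   polyploidy has been resolved.
2. **Minimum reconciliation on the network.**  Here the gene tree is mapped
   to the network itself, losses being counted with the network distance
   above.  This is the undated analogue of cophylogeny mapping, restricted
   to duplication and loss.

Deciding whether the best-switching cost is zero is exactly the
tree-containment problem, which is NP-hard, so no algorithm polynomial in
the total number of hybridizations `h` is expected for problem 1.

## Algorithms

**Per-component search (problem 1).**  The network decomposes into
biconnected components; contracting them yields a tree whose nodes we call
components and whose edges are the cut-edges.  Every gene-tree node is
labelled by the lowest component whose subnetwork spans its species
(`augment_gene_tree`), artificial pass-through nodes are inserted for
skipped components, and the augmented tree splits, per component, into a
small forest of subgraphs (`component_forest`).  The key identity — tested
on two hundred random instances in `test-acceptance.R` — is that for any
global switching the total cost is the sum over components of the costs of
these subgraphs against the component's own switching, where a subgraph
tree pays its internal reconciliation plus the path from the component root
down to its image, and a pass-through edge pays just that path.  Cost
decomposability makes the minimisations independent: each elementary
network with `k` hybridizations has at most `2^k` switchings, so the work
is `sum(2^k_i)` component evaluations instead of `2^h` global ones
(level-2, `h = 6` instance: 12 vs 64, asserted by a counter).

**Candidate-set dynamic programme (problem 2).**  In gene-tree post-order,
`reconcile_network` stores for every node the pairs (network node, minimal
cost of reconciling the subtree there).  For two child candidates `y`, `z`,
speciation placements range over the *minimal meeting set* — the lowest
nodes with separated paths to `y` and `z`, none of which dominates another
member's paths — and a duplication placement at the higher image is added
when `y` and `z` are comparable.  A merge keeps one cheapest pair per
network node.  The minimal meeting set is computed by an upward sweep over
the ancestors of `y` and `z` that propagates, for every node, the lowest
node all of its paths to `y` and `z` must pass (`meeting_sweep`); a direct
reachability-with-deletion check (`min_meeting_set(..., "enumerate")`)
serves as its oracle.  Backtracking through the stored predecessor pairs
yields an explicit reconciliation, which is re-checked clause by clause by
`validate_reconciliation`.

## Parameters that matter

* `dup_cost`, `loss_cost` (default 1 and 1): positive reals, in cost units
  per event.  Unit costs are the conventional neutral choice; only their
  ratio affects which reconciliation wins.  Zero or negative costs are
  rejected — with a free event the zero-cost characterisation of tree
  containment breaks down.
* `n_leaves`, `n_hybridizations` in `random_network`: the generator grows a
  random tree by sequential edge subdivision, then adds one reticulation at
  a time between two random edges, rejecting cycles.  This yields networks
  whose realized level varies between 1 and `h`, which is what the
  per-component machinery needs exercised.
* `dup_rate`, `loss_rate` in `simulate_gene_tree` (defaults 0.1/0.1, test
  batches use 0.2/0.15): per-speciation-node event probabilities in
  `[0, 1)`.  These rates keep simulated families small (a handful of
  copies) with visible events, matching what a curated gene family in a
  hybridisation study looks like; extinct histories are resampled (the
  retry cap fails loudly).

## What the simulator does and does not emulate

The simulator draws a uniform switching, evolves one lineage down its
displayed tree with duplications and losses at `V_on` speciation nodes, and
prunes extinct branches.  The recorded counts `d_true`, `l_true` are the
events *visible in the surviving history*; they certify an upper bound
(`lca_reconcile` on the true switching can only be cheaper — parsimony may
undercut the true history, so they are a bound, not ground truth).  The
generator does not model incomplete lineage sorting, gene transfer,
population processes, or rate heterogeneity across branches; passing tests
therefore show algorithmic correctness under the duplication-loss model,
not robustness of the model on real data.

## Numerical and design choices

* **Path lengths.**  The loss count of a path depends on the path (a
  minimum over paths is taken), with the top endpoint counted when it is a
  speciation or the root, and the bottom endpoint never counted.  The root
  counts as a speciation for losses (it has two children).  Distances are
  computed once per network by a reverse-topological sweep; infeasible
  pairs are `Inf` (R's native saturating sentinel), never a large integer.
* **Component switchings.**  Distances inside an elementary network count
  only nodes in its `V_on` that are not its leaves — cut-edge targets are
  priced by the component below them, which is exactly what makes the
  per-component sums close (the decomposition-identity test arbitrates this
  reading).
* **Meeting sets of a node with itself.**  The separated-paths definition
  admits a node with two disjoint routes to the same leaf (possible above a
  hybridization); we implement exactly that.  This is not an idle corner:
  it is why a same-species cherry can be explained by a *speciation* whose
  two copies merge back into one hybrid species.  Consequently collapsing
  single-species subtrees — exact on trees and switchings, where such
  double routes cannot exist — is *unsound* against a network, and
  `reconcile_network` deliberately runs on the uncollapsed gene tree, while
  `best_switching` collapses first (and re-expands the solution with one
  zero-loss duplication per removed node).  The candidate-set size bound
  `h + 2` is asserted for gene nodes spanning at least two species, the
  regime in which it is derived; the sharper `h + 1` variant has not been
  violated in any test batch, but only `h + 2` is asserted.
* **Determinism.**  Node ids are stable integers in parse order; every tie
  (co-optimal component switchings, equal-cost merge entries, the root
  candidate) is broken by lexicographically smallest on-edge set or
  smallest node id, and all randomness flows through one explicit seed via
  `withr::with_seed`.  Duplicate post-propagation switchings are
  de-duplicated by their off-edge set.
* **Problem sizes in the test batches.**  Oracle-equivalence batches use
  networks of up to 10 species with up to 6 hybridizations (global
  switching enumeration) and up to 25 network nodes with up to 4
  hybridizations (exhaustive reconciliation search), 300 instances each;
  these are the sizes at which the brute-force oracles remain exact
  references while still covering every code path (levels 0 through the
  full hybridization count).

## Known limitations

Non-binary gene trees or networks are rejected rather than resolved; edge
lengths, dates and transfer/host-switch events are out of scope; and
`all_optimal_switchings` enumerates per-component co-optima, whose product
can be capped (`max_results`) on highly symmetric instances.  The
exhaustive oracles guard their input sizes and fail loudly rather than
truncate.
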