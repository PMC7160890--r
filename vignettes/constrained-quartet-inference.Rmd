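---
title: "Constrained quartet-score species-tree inference: models, algorithms and design choices"
author: "conquart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained quartet-score species-tree inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

Gene trees estimated from different loci routinely disagree with each
other and with the species phylogeny, most prominently because of
incomplete lineage sorting (ILS) under the multispecies coalescent.
Summary methods sidestep per-locus modeling by scoring candidate species
trees against the gene-tree collection; `conquart` uses the quartet
score, the number of induced four-taxon topologies shared between a
candidate tree and the gene trees, summed over genes. The quartet score
is attractive because for any four taxa the most probable quartet
topology among true gene trees under ILS agrees with the species tree,
so its maximizer is a consistent estimator given enough error-free
genes. Gene trees may be incomplete (quartets over absent taxa simply
never form) and multifurcating (unresolved quartets count for nothing).

`conquart` adds the ability to restrict the optimization to trees
compatible with a user-supplied constraint tree T̄ — itself possibly
incomplete and unresolved. A tree T is *compatible* with T̄ when T
restricted to T̄'s leaves is a resolution of T̄.

## The dynamic program

Fix an outgroup leaf `o` (by default the lexicographically smallest
label shared by the inputs; any choice yields the same optima, the
outgroup only orients clusters). With L′ = L ∖ {o}, the optimal score of
a subtree on a cluster A ⊆ L′ satisfies

S(A) = max over A′ ∈ X with A∖A′ ∈ X of S(A′) + S(A∖A′) + w(A′ | A∖A′ | L∖A)

with S({x}) = 0. The weight of a tripartition counts gene-tree quartets
`ab|cd` whose sibling pair falls inside one part while the remaining two
leaves land in the two other parts; both sibling pairs of each quartet
are counted, so the node weights of any binary tree sum to exactly twice
its quartet score. We keep this *doubled* convention internally (it
keeps all weights integral) and halve the value at the API boundary.
Implementation notes:

* clusters are bit masks over the ordered leaf set (at most 31 taxa for
  the restricted DP — a deliberate desk-scale bound);
* the recursion runs bottom-up over clusters in increasing cardinality,
  so no recursion-depth issues arise;
* split enumeration is canonical (A′ contains the smallest element of
  A), halving the work;
* ties in the maximization are broken toward the split whose smaller
  side is lexicographically least, making runs bit-reproducible;
* weights are computed by brute-force enumeration over the aggregated
  multiset of resolved gene-tree quartets. Quartet topologies are read
  off the four-point condition applied to unit-branch-length path
  distances, which is exact and flags unresolved quartets as three-way
  ties. Asymptotically faster weight computations exist but are not the
  point at this scale.

With X equal to the powerset of L′ (`exact_solve()`, capped at 10 taxa)
the DP provably returns the global optimum; the test suite checks this
against independent enumeration of all unrooted topologies.

## Building a valid, constraint-respecting search space

A restricted X must satisfy two properties. **P1**: every cluster of X
belongs to a complete binary tree all of whose clusters are in X —
otherwise the cluster can never participate in a full decomposition and
Eq.-style recursions can dead-end. **P2**: every cluster is compatible
with T̄ — then any tree assembled by the DP is compatible with T̄, and
no change to the DP itself is needed. Simply filtering a standard X by
P2 can break P1, which is why the constructor works with whole trees:

1. every gene tree t is replaced by `comp(T̄, t)` — the constraint
   completed and resolved using the gene tree (see below); outputs are
   compatible with T̄ by construction;
2. the results are completed onto the full leaf set, reference-free:
   incomplete trees are completed against a guide tree built by
   average-linkage agglomeration of the quartet-similarity matrix (the
   fraction of resolved gene-tree quartets in which two leaves are
   siblings; unobserved pairs are imputed with row means and flagged).
   Completion of a compatible tree preserves compatibility because the
   output restricted to the input's leaves resolves the input;
3. greedy consensus trees of these completed trees are formed at
   thresholds {0, 0.2, 0.5} (configurable; the greedy consensus adds
   bipartitions in decreasing frequency order when compatible with those
   already accepted);
4. each consensus tree is in turn forced through `comp(T̄, ·)`;
5. every tree from steps 2 and 4 is resolved into binary *witness*
   trees: one deterministic average-linkage resolution of each polytomy
   under the similarity matrix plus seeded noise-perturbed variants
   (default 2 rounds). X is the union of all witness clusters plus the
   singletons and L′.

P1 holds because every cluster comes from a recorded witness; P2 holds
because witnesses are resolutions of compatible trees. Both properties
are nevertheless re-checked explicitly (`verify_p1()`, `verify_p2()`),
and the test suite exercises them on hundreds of randomized instances
together with negative controls (injected crossing or orphan clusters).
No cap is placed on |X| beyond a soft warning (default 25000): the
polynomial-growth capping policies of large-scale implementations are
out of scope at desk scale.

## RF-minimizing tree completion with multifurcations

`comp(T_b, T_r)` adds to a backbone T_b the leaves of a reference T_r
that it lacks, minimizing the RF distance to T_r among all trees
compatible with T_b. Both trees are rooted at a shared leaf. The binary
ancestor of the algorithm (`brf_plus()`) grafts every fully-missing
reference subtree, in pre-order, as the sister of the LCA (in the
growing backbone) of its sister leaves; it is optimal among *binary*
completions but can be forced to add arbitrary branches. The
multifurcating variant (`brf_star()`) decides per graft:

* **case 1** — the sibling set of the grafted group is a single
  reference subtree whose backbone image is exactly the attachment node:
  a new node is created (recovering a reference branch);
* **case 2** — otherwise any binary attachment would add a
  false-positive branch, so the subtree becomes an extra child of the
  attachment node, forming a polytomy.

Fully-missing subtrees hanging from one reference polytomy are grafted
as a group at the same position. The output is a contraction of the
binary completion, preserves its false negatives, adds no false
positives beyond those already present between T_b and T_r restricted to
shared leaves, and attains the global RF minimum over all trees
compatible with T_b — properties verified instance-by-instance against
an oracle that enumerates every binary completion and every contraction
thereof.

Multifurcating backbones are first *expanded*: at each backbone
polytomy, the children carrying a reference cluster are grouped under a
new node exactly when their shared leaves equal that cluster. The
equality guard is both necessary and sufficient for the added branch to
be a restricted reference bipartition compatible with the backbone. (A
per-child ancestor-mapping formulation we first implemented can miss
compatible splits when one reference child spans several polytomy
children; the enumeration oracle produced a counterexample, so the
constructor now implements the contract directly.)

When backbone and reference share fewer than three leaves the task
degenerates gracefully: the reference is grafted beside the backbone
root, which is the only position the shared rooting determines.

## Synthetic data and the evaluation harness

The generator emulates the study conditions of coalescent simulations
without external simulators: a uniformly random species-tree topology; a
per-gene Poisson number of random NNI moves, with the rate calibrated by
bisection so the expected normalized RF between gene trees and the
species tree hits the configured discordance level (the emulated
ILS-severity targets are 0.15 / 0.34 / 0.69, spanning moderate to very
high discordance); and a second calibrated NNI pass emulating gene-tree
estimation error (targets around 0.25–0.47). Constraints are derived
from a source tree by pruning random leaves, collapsing random internal
branches, or pruning random clades. Everything is reproducible
byte-for-byte from the configuration seed.

What the emulation does *not* capture: coalescent branch lengths and the
correlation structure of real ILS discordance (NNI perturbation spreads
error uniformly over the tree), alignment-driven estimation error that
concentrates on short branches, and missing-data patterns driven by
taxon sampling. Passing the directional experiments therefore shows that
the machinery behaves as designed under controlled discordance — not
that real-data error rates would match any particular figure. A proper
multispecies-coalescent generator can be plugged in behind the same
contract.

The harness (`evaluate_constraints()`) runs matched constrained and
unconstrained searches per replicate and reports normalized RF to the
truth (whole tree, and restricted to the leaves *absent* from the
constraint), the quartet score and |X|. The default validation scale is
20 taxa, 50 genes and 20 replicates at the very-high-discordance level
(0.69/0.47) — the regime where unconstrained searches still make
errors, hence where constraint effects are visible; pruning half the
taxa gives the remaining-leaf comparison a usable denominator, and
pruning a quarter provides the large-constraint condition for the
search-space-size comparison. Expected directions: a self-constraint
(the unconstrained optimum fed back as constraint) changes neither the
tree nor the score; true-tree constraints never hurt, and typically
help, the placement of unconstrained leaves; large correct constraints
shrink |X| in nearly all replicates.

## Numerical and degenerate-input choices

* Newick support values are read from numeric internal-node labels in
  [0, 1]; the branch-annotation dialect (`[&support=…]` comments and
  kin) is not interpreted. `contract_by_support()` requires labels and
  errors otherwise; thresholds are inclusive (support ≤ t collapses).
* Similarity ties during polytomy resolution resolve by canonical child
  order (children sorted by smallest descendant label), and randomized
  rounds draw symmetric Gaussian noise at 0.1 of the similarity spread,
  re-seeded per round so that enlarging `rounds` never changes earlier
  rounds (hence X grows monotonically in `rounds`).
* RF normalization divides by the total number of *internal* branches in
  the two compared trees (so two maximally conflicting binary trees have
  normalized RF 1, and a 201-taxon binary pair has denominator 396).
  Comparisons between trees on different leaf sets restrict both to the
  shared leaves first and require at least four of them.
* Gene trees with duplicate labels are rejected at load time; a
  constraint sharing no leaf with some gene tree leaves that gene tree
  unforced (with a message) rather than failing the run.

## Validation scales

Exhaustive oracles drive the correctness tests at sizes where full
enumeration is feasible: completion optimality on random 5–7-leaf
instances (the oracle enumerates up to 945 topologies times all
contraction subsets) plus invariant checks on 10-leaf instances where
only the proof's sub-properties (contraction, FN preservation, FP
invariance, backbone preservation) are enumerable; DP exactness on
5–8 taxa against all-topology enumeration; certificate checks on
randomized 8–14-taxon search spaces; and the directional experiments at
20 taxa / 50 genes / 20 replicates. These sizes are the package's own
validation design and keep the full suite comfortably reproducible on a
single CPU.

## Known limitations

* The restricted DP is bounded at 31 taxa and weights are computed by
  quartet enumeration; this is a validation-scale implementation of the
  method, not a large-scale production engine.
* |X| enrichment uses similarity-guided resolutions only; the richer
  sampling heuristics of large-scale quartet methods (and their |X|
  size caps) are intentionally not reproduced.
* Support annotation of output branches (e.g. local posterior
  probabilities) and multi-individual taxon mappings are out of scope.
* The completion criterion is RF; other completion criteria could slot
  behind the same `comp()` contract.
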