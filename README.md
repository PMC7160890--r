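# conquart

Constrained species-tree inference by quartet-score maximization.

`conquart` estimates an unrooted species tree from a collection of
(possibly incomplete, possibly multifurcating) gene trees by maximizing
the **quartet score** — the number of four-leaf induced topologies the
species tree shares with the gene trees, summed over genes. Under the
multispecies coalescent, the most frequent quartet topology of the true
gene trees matches the species tree, which is why quartet-score
maximization is the workhorse of summary methods for genome-scale data
affected by incomplete lineage sorting.

The package's distinctive feature is support for **user-provided
constraint trees**: an incomplete and/or unresolved tree T̄ that the
inferred species tree must be compatible with. Constrained searches
enable hypothesis-driven analyses (is there hidden support for a clade
the optimal tree does not recover?), monophyly tests, and growing an
existing tree with new taxa without starting over.

## The method

Let L be the taxon set, o ∈ L a fixed outgroup leaf and L′ = L ∖ {o}.
A *cluster* A ⊂ L′ is the o-free side of a bipartition. The optimal tree
is found with the cluster dynamic program

    S(A) = max over A′ ∈ X, A∖A′ ∈ X of
           S(A′) + S(A∖A′) + w(A′ | A∖A′ | L∖A),      S({x}) = 0

where the tripartition weight `w` counts, over all gene trees, the
quartets `ab|cd` with the sibling pair inside one part and the other two
leaves split across the remaining parts; summed over the nodes of any
binary tree these weights give exactly twice its quartet score. With X
equal to the full powerset the DP is exact (and exponential); with a
restricted X it is fast but only as good as X.

Two properties make a restricted X valid and constraint-aware:

* **P1 (decomposability):** every cluster of X lies in a complete binary
  *witness* tree all of whose clusters are in X;
* **P2 (constraint compatibility):** every cluster of X is compatible
  with T̄ — then *any* tree the DP assembles is compatible with T̄.

X is built by turning tree completion on its head: instead of completing
gene trees with a species tree, the *constraint* is completed with each
*gene tree* using an RF-minimizing completion `comp(T_b, T_r)` that (i)
refines the backbone's polytomies with every compatible reference
bipartition and (ii) grafts missing subtrees at the LCA of their sister
leaves, either as a new sister node (when this recovers a reference
branch) or into a polytomy (when a binary attachment would only add a
false-positive branch). The resulting completion is optimal: its RF
distance to the reference is the minimum over **all** trees — binary or
multifurcating — compatible with the backbone, which the package
verifies against an exhaustive enumeration oracle.

## Worked example

```r
library(conquart)

## 15 taxa, 30 genes, heavy gene-tree discordance plus estimation error
sim <- simulate_genetrees(sim_config(n = 15, k = 30,
                                     discordance = 0.69, error = 0.47,
                                     seed = 4))

## unconstrained search
free <- constrained_infer(sim$genes, seed = 4)
free$score                      # quartet score of the optimum
#> [1] 26968
free$X_size                     # clusters explored by the DP
#> [1] 212
fn_fp(free$tree, sim$species)$nrf
#> [1] 0.08333333

## constrain the search with a correct subtree on 8 of the 15 taxa
cons  <- derive_constraint(sim$species, "prune", 7, seed = 104)
fixed <- constrained_infer(sim$genes, constraint = cons, seed = 4)
fixed$X_size                    # the constraint shrinks the search space
#> [1] 135
resolves(fixed$tree, cons)      # the output honors the constraint
#> [1] TRUE
fn_fp(fixed$tree, sim$species)$nrf
#> [1] 0
```

The quartet score counts shared induced quartets (here out of
30·C(15,4) = 40950 possible); `nrf` is the RF distance normalized by the
total internal branches of the two trees, so 0.083 means one conflicting
branch pair in a 15-taxon tree. Constraining the search with a correct
subtree removes the remaining error here and shrinks |X| by a third.

A command-line wrapper with `infer`, `score`, `complete`, `build-x`,
`simulate` and `evaluate` subcommands is installed at
`inst/scripts/conquart`.

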