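## shared fixture builders (all trees generated in code, seeded per test)

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

random_topology <- function(n, labels = letters[seq_len(n)]) {
  ape::rtopology(n, rooted = FALSE, tip.label = labels)
}

## collapse each internal non-root node independently with probability p
collapse_random <- function(tree, p = 0.4) {
  nt <- length(tree$tip.label)
  cand <- setdiff((nt + 1L):(nt + tree$Nnode), nt + 1L)
  pick <- cand[stats::runif(length(cand)) < p]
  if (length(pick)) collapse_internal_nodes(tree, pick) else tree
}

## a gene-tree set around a random species tree: NNI-perturbed, optionally
## incomplete and multifurcating
random_gene_set <- function(n, k, nni = 2, p_incomplete = 0.3,
                            p_collapse = 0.3,
                            labels = sprintf("s%02d", seq_len(n))) {
  species <- random_topology(n, labels)
  genes <- lapply(seq_len(k), function(i) {
    g <- phangorn::rNNI(species, stats::rpois(1L, nni))
    if (stats::runif(1L) < p_incomplete && n >= 6L) {
      keep <- sample(labels, n - sample1(1:2))
      g <- restrict(g, keep)
    }
    if (stats::runif(1L) < p_collapse) g <- collapse_random(g, 0.3)
    g
  })
  list(species = species, genes = genes, labels = labels)
}

## does the tree contain the (unrooted) split separating `side` from the
## remaining leaves? (orientation-insensitive)
has_split <- function(tree, side) {
  other <- setdiff(tree$tip.label, side)
  any(vapply(bipartitions(tree), function(A)
    setequal(A, side) || setequal(A, other), logical(1L)))
}

is_binary_tree <- function(tree) {
  length(bipartitions(tree)) == length(tree$tip.label) - 3L
}

split_keys_of <- function(tree) {
  vapply(bipartitions(tree), paste, character(1L), collapse = "|")
}
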