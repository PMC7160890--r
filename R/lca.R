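#' Least-common-ancestor index for a rooted tree
#'
#' Preprocesses a rooted `phylo` object into a binary-lifting (jump
#' pointer) table so that subsequent [lca()] queries take logarithmic time
#' each. Any correct index meeting this contract is acceptable for the
#' algorithms in this package; queries must agree with naive ancestor-path
#' intersection.
#'
#' @param tree A rooted `phylo` object (the stored root is used).
#' @return An object of class `conquart_lca`.
#' @export
build_lca_index <- function(tree) {
  nt <- length(tree$tip.label)
  n <- nt + tree$Nnode
  parent <- integer(n)
  parent[] <- 0L
  e <- tree$edge
  parent[e[, 2L]] <- e[, 1L]
  root <- nt + 1L
  ## depths via repeated relaxation over edges in cladewise order
  depth <- integer(n)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(ord)))
    depth[ord[i, 2L]] <- depth[ord[i, 1L]] + 1L
  K <- max(1L, ceiling(log2(max(2L, max(depth) + 1L))))
  up <- matrix(0L, n, K)
  up[, 1L] <- parent
  if (K > 1L) for (j in 2L:K) {
    prev <- up[, j - 1L]
    up[, j] <- ifelse(prev > 0L, up[pmax(prev, 1L), j - 1L], 0L)
  }
  structure(list(tree = tree, n = n, ntip = nt, root = root,
                 parent = parent, depth = depth, up = up),
            class = "conquart_lca")
}

#' Least common ancestor of a set of nodes
#'
#' @param index An index from [build_lca_index()].
#' @param nodes Node ids (integers in ape numbering) and/or tip labels.
#' @return The node id of the deepest common ancestor.
#' @export
lca <- function(index, nodes) {
  tree <- index$tree
  ids <- vapply(nodes, function(x) {
    if (is.character(x)) {
      i <- match(x, tree$tip.label)
      if (is.na(i)) stop("node not in tree: ", x)
      i
    } else {
      xi <- as.integer(x)
      if (is.na(xi) || xi < 1L || xi > index$n)
        stop("node not in tree: ", x)
      xi
    }
  }, integer(1L))
  Reduce(function(a, b) .lca2(index, a, b), ids)
}

.lca2 <- function(index, a, b) {
  depth <- index$depth; up <- index$up
  K <- ncol(up)
  if (depth[a] < depth[b]) { tmp <- a; a <- b; b <- tmp }
  d <- depth[a] - depth[b]
  j <- 1L
  while (d > 0L) {
    if (d %% 2L == 1L) a <- up[a, j]
    d <- d %/% 2L
    j <- j + 1L
  }
  if (a == b) return(a)
  for (j in K:1L) {
    if (up[a, j] != up[b, j] && up[a, j] > 0L && up[b, j] > 0L) {
      a <- up[a, j]; b <- up[b, j]
    }
  }
  index$parent[a]
}
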