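## Internal mutable rooted-tree structure used for tree surgery
## (completion, consensus assembly, polytomy resolution).
##
## A tree is rooted at the designated leaf o; o itself is kept implicit: the
## structure's root is the node adjacent to o, so the leaf set below any
## node is a cluster (never containing o). Fields live in an environment:
##   par  - parent id (0 for root)
##   kids - list of integer child-id vectors (empty for leaves)
##   lab  - leaf label (NA for internal nodes)
##   root - id of the root node

rt_new <- function() {
  e <- new.env(parent = emptyenv())
  e$par <- integer(0L)
  e$kids <- list()
  e$lab <- character(0L)
  e$root <- 0L
  e
}

rt_add <- function(rt, parent, label = NA_character_) {
  id <- length(rt$par) + 1L
  rt$par[id] <- parent
  rt$kids[[id]] <- integer(0L)
  rt$lab[id] <- label
  if (parent > 0L) rt$kids[[parent]] <- c(rt$kids[[parent]], id)
  id
}

## Build from an unrooted phylo, rooting at leaf `o` (which is removed and
## kept implicit). Degree-two nodes are suppressed; children are ordered
## canonically by their smallest descendant label.
rt_from_phylo <- function(phy, o) {
  nt <- length(phy$tip.label)
  oi <- match(o, phy$tip.label)
  if (is.na(oi)) stop("outgroup leaf not in tree: ", o)
  nn <- nt + phy$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rt <- rt_new()
  build <- function(v, from, parent) {
    nb <- setdiff(adj[[v]], from)
    if (v <= nt) {
      return(rt_add(rt, parent, phy$tip.label[v]))
    }
    if (length(nb) == 1L) return(build(nb, v, parent))  # suppress degree-2
    id <- rt_add(rt, parent)
    for (c in nb) build(c, v, id)
    id
  }
  start <- adj[[oi]]
  if (length(start) != 1L) stop("outgroup leaf is not a pendant leaf")
  rt$root <- build(start, oi, 0L)
  rt_sort_children(rt)
  rt
}

## leaf labels below each node (list indexed by id)
rt_leafsets <- function(rt) {
  n <- length(rt$par)
  ls <- vector("list", n)
  rec <- function(v) {
    if (!length(rt$kids[[v]])) {
      ls[[v]] <<- rt$lab[v]
    } else {
      for (c in rt$kids[[v]]) rec(c)
      ls[[v]] <<- unlist(ls[rt$kids[[v]]], use.names = FALSE)
    }
  }
  rec(rt$root)
  ls
}

rt_leaves_below <- function(rt, v) {
  if (!length(rt$kids[[v]])) return(rt$lab[v])
  unlist(lapply(rt$kids[[v]], function(c) rt_leaves_below(rt, c)),
         use.names = FALSE)
}

## canonical ordering: children sorted by smallest descendant label
rt_sort_children <- function(rt) {
  ls <- rt_leafsets(rt)
  mins <- vapply(ls, function(x) min(x), character(1L))
  rec <- function(v) {
    k <- rt$kids[[v]]
    if (length(k) > 1L) rt$kids[[v]] <- k[order(mins[k])]
    for (c in rt$kids[[v]]) rec(c)
  }
  rec(rt$root)
  invisible(rt)
}

## map leaf label -> node id
rt_leafmap <- function(rt) {
  ids <- which(!is.na(rt$lab) & !lengths(rt$kids))
  stats::setNames(ids, rt$lab[ids])
}

rt_lca_ids <- function(rt, ids) {
  if (!length(ids)) stop("LCA of an empty node set")
  path <- integer(0L)
  v <- ids[1L]
  while (v > 0L) { path <- c(path, v); v <- rt$par[v] }
  for (x in ids[-1L]) {
    v <- x
    while (!(v %in% path)) v <- rt$par[v]
    path <- path[which(path == v):length(path)]
  }
  path[1L]
}

## deep-copy the subtree of `src` rooted at v into `dst`, attached under
## `parent` (0 = detached); returns the new root id
rt_copy_subtree <- function(dst, src, v, parent) {
  id <- rt_add(dst, parent, src$lab[v])
  for (c in src$kids[[v]]) rt_copy_subtree(dst, src, c, id)
  id
}

## splice node w above existing node v (w becomes v's parent in place)
rt_insert_above <- function(rt, v) {
  p <- rt$par[v]
  w <- length(rt$par) + 1L
  rt$par[w] <- p
  rt$kids[[w]] <- integer(0L)
  rt$lab[w] <- NA_character_
  if (p > 0L) {
    k <- rt$kids[[p]]
    rt$kids[[p]] <- replace(k, k == v, w)
  } else {
    rt$root <- w
  }
  rt$par[v] <- w
  rt$kids[[w]] <- v
  w
}

## attach an already-created (detached) node as a child of parent
rt_attach <- function(rt, node, parent) {
  rt$par[node] <- parent
  rt$kids[[parent]] <- c(rt$kids[[parent]], node)
  invisible(rt)
}

## number of children
rt_nkids <- function(rt, v) length(rt$kids[[v]])

rt_is_binary <- function(rt) {
  all(lengths(rt$kids) %in% c(0L, 2L))
}

## serialize back to an unrooted newick / phylo with o re-attached
rt_newick <- function(rt, o) {
  rec <- function(v) {
    if (!length(rt$kids[[v]])) return(rt$lab[v])
    paste0("(", paste(vapply(rt$kids[[v]], rec, character(1L)),
                      collapse = ","), ")")
  }
  if (!length(rt$kids[[rt$root]])) {
    return(paste0("(", rt$lab[rt$root], ",", o, ");"))
  }
  inner <- vapply(rt$kids[[rt$root]], rec, character(1L))
  paste0("(", paste(c(inner, o), collapse = ","), ");")
}

rt_to_phylo <- function(rt, o) {
  rt_sort_children(rt)
  parse_newick(rt_newick(rt, o))
}

## clusters (leaf-label sets below each non-root internal node, plus the
## root cluster and singletons if requested)
rt_clusters <- function(rt) {
  ls <- rt_leafsets(rt)
  ids <- seq_along(rt$par)
  lapply(ids, function(v) ls[[v]])
}
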