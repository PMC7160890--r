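## Construction of the restricted DP search space X: the set of clusters
## explored by the dynamic program, built so that (P1) every cluster lies
## in at least one complete binary witness tree whose clusters are all in
## X, and (P2) every cluster is compatible with the user's constraint tree.

## all cluster masks of a tree rooted at o, over bit positions given by
## `labels` (singletons and the full cluster included; o's bit never set)
.all_cluster_masks <- function(tree, labels, o) {
  rt <- rt_from_phylo(tree, o)
  ls <- rt_leafsets(rt)
  unique(vapply(ls, function(ll)
    as.integer(sum(2^(match(ll, labels) - 1L))), integer(1L)))
}

.mask_to_labels <- function(mask, labels) {
  bits <- as.integer(2^(seq_along(labels) - 1L))
  labels[bitwAnd(mask, bits) != 0L]
}

.labels_to_mask <- function(x, labels) {
  as.integer(sum(2^(match(x, labels) - 1L)))
}

## assemble a phylo from a laminar family of cluster masks (o implicit)
.clusters_to_phylo <- function(labels, o, masks) {
  bits <- as.integer(2^(seq_along(labels) - 1L))
  obit <- bits[match(o, labels)]
  full <- as.integer(sum(bits)) - obit
  masks <- setdiff(unique(masks), c(full, 0L))
  sz <- .popcount(masks)
  masks <- masks[sz >= 2L]
  nodes <- c(full, masks)
  nsz <- .popcount(nodes)
  parent_of <- function(m) {
    sup <- nodes[bitwAnd(nodes, m) == m & nodes != m]
    if (!length(sup)) return(full)
    sup[which.min(.popcount(sup))]
  }
  kids <- lapply(nodes, function(x) integer(0L))
  for (i in seq_along(nodes)[-1L]) {
    p <- parent_of(nodes[i])
    pi <- match(p, nodes)
    kids[[pi]] <- c(kids[[pi]], i)
  }
  singles <- setdiff(which(bitwAnd(full, bits) != 0L), integer(0L))
  leaf_parent <- vapply(bits[singles], parent_of, integer(1L))
  rec <- function(i) {
    subs <- c(vapply(kids[[i]], rec, character(1L)),
              sort(labels[singles[leaf_parent == nodes[i]]]))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  inner <- c(vapply(kids[[1L]], rec, character(1L)),
             sort(labels[singles[leaf_parent == full]]))
  parse_newick(paste0("(", paste(c(inner, o), collapse = ","), ");"))
}

#' Greedy consensus trees at a set of frequency thresholds
#'
#' Bipartitions of the input trees are ranked by frequency and added
#' greedily when compatible with those already accepted; for each
#' threshold only bipartitions with frequency at or above it are kept
#' (threshold 1 gives the strict consensus, 0 the full greedy consensus).
#'
#' @param trees A list of `phylo` objects sharing one leaf set.
#' @param thresholds Numeric vector of frequency thresholds in \[0, 1\].
#' @return A list of `phylo` consensus trees, one per threshold.
#' @export
greedy_consensus <- function(trees, thresholds = 0) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  labels <- sort(trees[[1L]]$tip.label)
  same <- vapply(trees, function(t) setequal(t$tip.label, labels),
                 logical(1L))
  if (!all(same)) stop("greedy consensus requires trees on one leaf set")
  o <- min(labels)
  k <- length(trees)
  allm <- unlist(lapply(trees, function(t) {
    m <- .all_cluster_masks(t, labels, o)
    m[.popcount(m) >= 2L & .popcount(m) < length(labels) - 1L]
  }))
  if (!length(allm)) {
    star <- star_tree(labels)
    return(stats::setNames(rep(list(star), length(thresholds)), thresholds))
  }
  u <- sort(unique(allm))
  freq <- tabulate(match(allm, u)) / k
  ord <- order(-freq, u)
  u <- u[ord]; freq <- freq[ord]
  out <- lapply(thresholds, function(thr) {
    acc <- integer(0L)
    for (i in seq_along(u)) {
      if (freq[i] < thr && !isTRUE(all.equal(freq[i], thr))) next
      m <- u[i]
      iw <- bitwAnd(acc, m)
      if (all(iw == 0L | iw == m | iw == acc)) acc <- c(acc, m)
    }
    .clusters_to_phylo(labels, o, acc)
  })
  stats::setNames(out, thresholds)
}

#' Resolve polytomies guided by a quartet-similarity matrix
#'
#' Each polytomy is resolved by average-linkage agglomeration of its child
#' subtrees under the similarity matrix (one deterministic resolution);
#' additional rounds perturb the similarities with seeded Gaussian noise to
#' produce alternative resolutions. Every output is a full binary
#' resolution of the input, so resolutions of a constraint-compatible tree
#' remain constraint-compatible.
#'
#' @param tree A `phylo` tree complete on the matrix's leaf set.
#' @param matrix A similarity matrix from [quartet_similarity_matrix()].
#' @param rounds Number of resolutions to produce (first is deterministic).
#' @param seed Integer seed for the randomized rounds.
#' @return A list of binary `phylo` trees (a single element when the input
#'   is already binary).
#' @export
resolve_polytomies <- function(tree, matrix, rounds = 2L, seed = 1L) {
  labels <- rownames(matrix)
  if (!setequal(tree$tip.label, labels))
    stop("tree must be complete on the similarity matrix's leaf set")
  o <- min(labels)
  rt0 <- rt_from_phylo(tree, o)
  if (rt_is_binary(rt0)) return(list(tree))
  spread <- max(matrix) - min(matrix)
  if (!is.finite(spread) || spread <= 0) spread <- 1
  out <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    sim <- matrix
    if (r > 1L) {
      set.seed(as.integer((seed + 7919 * r) %% .Machine$integer.max))
      noise <- matrix(stats::rnorm(length(sim), sd = 0.1 * spread),
                      nrow(sim))
      noise <- (noise + t(noise)) / 2
      sim <- sim + noise
    }
    rt <- rt_from_phylo(tree, o)
    .resolve_rt(rt, sim, labels)
    out[[r]] <- rt_to_phylo(rt, o)
  }
  out
}

## resolve all polytomies of rt in place by average-linkage agglomeration
.resolve_rt <- function(rt, sim, labels) {
  nodes <- seq_along(rt$par)
  internal <- nodes[lengths(rt$kids) > 2L]
  for (v in internal) .resolve_node(rt, v, sim, labels)
  ## new polytomies are never created; but nodes added after the scan are
  ## binary by construction
  invisible(rt)
}

.resolve_node <- function(rt, v, sim, labels) {
  items <- rt$kids[[v]]
  lsets <- lapply(items, function(c) rt_leaves_below(rt, c))
  m <- length(items)
  S <- matrix(-Inf, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    S[i, j] <- mean(sim[lsets[[i]], lsets[[j]]])
  alive <- rep(TRUE, m)
  node_of <- items
  while (sum(alive) > 2L) {
    ii <- which(alive)
    sub <- S[ii, ii, drop = FALSE]
    best <- which(sub == max(sub[upper.tri(sub)]), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    a <- ii[best[1L, 1L]]; b <- ii[best[1L, 2L]]
    ## merge b into a: new internal node adopting both subtrees
    nv <- rt_add(rt, 0L)
    for (x in c(node_of[a], node_of[b])) {
      rt$kids[[v]] <- setdiff(rt$kids[[v]], x)
      rt$par[x] <- nv
      rt$kids[[nv]] <- c(rt$kids[[nv]], x)
    }
    rt_attach(rt, nv, v)
    na <- length(lsets[[a]]); nb <- length(lsets[[b]])
    for (x in which(alive)) {
      if (x == a || x == b) next
      w <- (na * .simget(S, x, a) + nb * .simget(S, x, b)) / (na + nb)
      S[min(x, a), max(x, a)] <- w
    }
    lsets[[a]] <- c(lsets[[a]], lsets[[b]])
    node_of[a] <- nv
    alive[b] <- FALSE
  }
  invisible(rt)
}

.simget <- function(S, i, j) S[min(i, j), max(i, j)]

#' Complete a set of trees onto the full leaf set, reference-free
#'
#' Trees already complete are returned unchanged. Incomplete trees are
#' completed with [comp()] against a complete binary guide tree obtained
#' by average-linkage agglomeration of the quartet-similarity matrix
#' (any completion method is admissible here; the matrix summarizes the
#' joint quartet signal of all inputs, so the step needs no designated
#' reference tree).
#'
#' @param trees A list of `phylo` objects on subsets of the matrix's
#'   leaf set.
#' @param matrix A similarity matrix from [quartet_similarity_matrix()].
#' @return A list of `phylo` trees, each complete on the full leaf set,
#'   whose restriction to the corresponding input's leaves resolves it.
#' @export
reference_free_complete <- function(trees, matrix) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  labels <- rownames(matrix)
  complete <- vapply(trees, function(t) setequal(t$tip.label, labels),
                     logical(1L))
  if (all(complete)) return(trees)
  guide <- resolve_polytomies(star_tree(labels), matrix,
                              rounds = 1L, seed = 0L)[[1L]]
  lapply(seq_along(trees), function(i) {
    if (complete[i]) trees[[i]] else comp(trees[[i]], guide)
  })
}

#' Build the restricted search space X under an optional constraint
#'
#' The pipeline: (1) each gene tree is made compatible with the constraint
#' by completing the constraint with it ([comp()]); (2) the results are
#' completed onto the full leaf set reference-free; (3) greedy consensus
#' trees are formed at the configured thresholds; (4) each consensus tree
#' is in turn forced to be compatible with the constraint; (5) every tree
#' from steps 2 and 4 is resolved into binary witness trees whose clusters
#' -- together with all singletons and the full cluster -- form X. By
#' construction every cluster lies in a complete binary witness (P1) and is
#' compatible with the constraint (P2); both properties are re-checkable
#' with [verify_p1()] and [verify_p2()].
#'
#' @param genetrees A list of `phylo` gene trees (possibly incomplete and
#'   multifurcating).
#' @param constraint Optional `phylo` constraint tree.
#' @param seed Integer seed driving the randomized resolution rounds.
#' @param thresholds Consensus frequency thresholds.
#' @param rounds Resolution rounds per multifurcating tree.
#' @param outgroup Designated outgroup leaf; defaults to the
#'   lexicographically smallest label shared by all inputs (or of the
#'   union when none is shared).
#' @param budget Soft cap on |X|; a warning is raised above it.
#' @return An object of class `conquart_space` with fields `labels`,
#'   `outgroup`, `masks` (cluster bit masks over `labels`), `witnesses`
#'   (complete binary trees certifying P1) and `constraint`.
#' @export
build_search_space <- function(genetrees, constraint = NULL, seed = 1L,
                               thresholds = c(0, 0.2, 0.5), rounds = 2L,
                               outgroup = NULL, budget = 25000L) {
  if (inherits(genetrees, "phylo")) genetrees <- list(genetrees)
  if (!length(genetrees)) stop("at least one gene tree is required")
  labs <- lapply(genetrees, `[[`, "tip.label")
  dups <- vapply(labs, anyDuplicated, integer(1L))
  if (any(dups > 0L)) stop("gene tree ", which(dups > 0L)[1L],
                           " has duplicate leaf labels")
  labels <- sort(unique(c(unlist(labs),
                          if (!is.null(constraint)) constraint$tip.label)))
  if (length(labels) > 31L)
    stop("the restricted DP supports at most 31 taxa (got ",
         length(labels), ")")
  o <- if (is.null(outgroup)) choose_outgroup(c(genetrees,
                                                if (!is.null(constraint))
                                                  list(constraint)))
       else outgroup
  if (!o %in% labels) stop("outgroup not among the input leaves: ", o)
  unforced <- character(0L)
  step1 <- genetrees
  if (!is.null(constraint)) {
    step1 <- lapply(seq_along(genetrees), function(i) {
      t <- genetrees[[i]]
      if (!length(intersect(t$tip.label, constraint$tip.label))) {
        unforced <<- c(unforced, paste0("gene tree ", i))
        return(t)
      }
      comp(constraint, t)
    })
    if (length(unforced))
      message("constraint shares no leaf with: ",
              paste(unforced, collapse = ", "),
              "; these trees contribute without constraint forcing")
  }
  mat <- quartet_similarity_matrix(genetrees, labels)
  step2 <- reference_free_complete(step1, mat)
  cons <- greedy_consensus(step2, thresholds)
  step4 <- if (is.null(constraint)) cons
           else lapply(cons, function(c) comp(constraint, c))
  pool <- c(step2, unname(step4))
  witnesses <- list()
  for (i in seq_along(pool)) {
    res <- resolve_polytomies(pool[[i]], mat, rounds = rounds,
                              seed = as.integer((seed + 131L * i) %%
                                                  .Machine$integer.max))
    witnesses <- c(witnesses, res)
  }
  bits <- as.integer(2^(seq_along(labels) - 1L))
  obit <- bits[match(o, labels)]
  full <- as.integer(sum(bits)) - obit
  masks <- unique(c(unlist(lapply(witnesses, .all_cluster_masks,
                                  labels = labels, o = o)),
                    setdiff(bits, obit), full))
  masks <- sort(masks)
  if (length(masks) > budget)
    warning("search space size |X| = ", length(masks),
            " exceeds the configured budget (", budget, ")")
  structure(list(labels = labels, outgroup = o, masks = masks,
                 witnesses = witnesses, constraint = constraint,
                 unforced = unforced,
                 meta = list(seed = seed, thresholds = thresholds,
                             rounds = rounds)),
            class = "conquart_space")
}

#' @export
print.conquart_space <- function(x, ...) {
  cat("Search space X over", length(x$labels), "taxa (outgroup",
      x$outgroup, "):", length(x$masks), "clusters,",
      length(x$witnesses), "witness trees,",
      if (is.null(x$constraint)) "unconstrained" else "constrained", "\n")
  invisible(x)
}

#' Clusters of a search space as label sets
#' @param space A `conquart_space` object.
#' @return A list of character vectors.
#' @export
space_clusters <- function(space) {
  lapply(space$masks, .mask_to_labels, labels = space$labels)
}

#' Verify the decomposability certificate (P1)
#'
#' Checks that every cluster of the space occurs in at least one recorded
#' complete binary witness tree (whose clusters are, by construction, all
#' members of the space), which guarantees the dynamic program can always
#' decompose it.
#'
#' @param space A `conquart_space` object.
#' @return `TRUE` or `FALSE`.
#' @export
verify_p1 <- function(space) {
  wm <- unique(unlist(lapply(space$witnesses, .all_cluster_masks,
                             labels = space$labels, o = space$outgroup)))
  ## witnesses must be binary and complete, and cover every cluster
  ok_shape <- all(vapply(space$witnesses, function(w) {
    setequal(w$tip.label, space$labels) &&
      rt_is_binary(rt_from_phylo(w, space$outgroup))
  }, logical(1L)))
  ok_shape && all(space$masks %in% wm)
}

#' Verify constraint compatibility of every cluster (P2)
#'
#' @param space A `conquart_space` object.
#' @return `TRUE` (vacuously for unconstrained spaces) or `FALSE`.
#' @export
verify_p2 <- function(space) {
  if (is.null(space$constraint)) return(TRUE)
  for (m in space$masks) {
    A <- .mask_to_labels(m, space$labels)
    if (!is_compatible(A, space$constraint)) return(FALSE)
  }
  TRUE
}
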