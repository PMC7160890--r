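#' Set up a tree-completion task
#'
#' A completion task adds to a backbone tree `T_b` the leaves present in a
#' reference tree `T_r` but absent from `T_b`, keeping the output compatible
#' with `T_b` while minimizing the RF distance to `T_r`. Both trees are
#' rooted at a shared leaf (the lexicographically smallest) for processing.
#'
#' @param backbone,reference `phylo` objects with at least one shared leaf.
#' @return A list with elements `backbone`, `reference`, `outgroup`,
#'   `shared` (shared leaves) and `missing` (reference leaves absent from
#'   the backbone).
#' @export
completion_task <- function(backbone, reference) {
  shared <- intersect(backbone$tip.label, reference$tip.label)
  if (!length(shared))
    stop("backbone and reference share no leaf to root on")
  list(backbone = backbone, reference = reference,
       outgroup = min(shared), shared = sort(shared),
       missing = sort(setdiff(reference$tip.label, backbone$tip.label)))
}

#' RF-minimizing binary tree completion
#'
#' Re-implementation of the linear-time RF(+) completion: every
#' fully-missing subtree of the reference is grafted, in a pre-order
#' traversal, as the sister of the LCA (in the growing backbone) of its
#' sister leaves. The output is binary, complete on the reference leaf set,
#' and its restriction to the backbone leaves equals the backbone; among
#' binary completions the RF distance to the reference is minimal.
#'
#' @param backbone A binary `phylo` tree.
#' @param reference A binary `phylo` tree whose leaves contain the
#'   backbone's.
#' @return A binary `phylo` tree on the reference leaf set.
#' @export
brf_plus <- function(backbone, reference) {
  task <- completion_task(backbone, reference)
  if (!all(backbone$tip.label %in% reference$tip.label))
    stop("brf_plus requires a complete reference: ",
         "every backbone leaf must occur in the reference")
  if (!.is_binary_unrooted(backbone))
    stop("brf_plus requires a binary backbone")
  if (!.is_binary_unrooted(reference))
    stop("brf_plus requires a binary reference")
  .brf_run(task, mode = "plus")
}

#' RF-minimizing tree completion with multifurcating output
#'
#' Extension of [brf_plus()] in which each grafted subtree either gains a
#' new attachment node (when this recovers a reference bipartition, case 1)
#' or is added as an extra child of its attachment node, creating a
#' polytomy (case 2, avoiding a false-positive branch). Among all trees --
#' binary or multifurcating -- compatible with the backbone, the output
#' minimizes the RF distance to the reference; it is a contraction of the
#' [brf_plus()] output on the same task. Multifurcating references are
#' handled by grafting all fully-missing children of a reference polytomy
#' as a group at the same position; a multifurcating backbone should first
#' be refined with [expand_backbone()] (done automatically by [comp()]).
#'
#' @inheritParams brf_plus
#' @return A (possibly multifurcating) `phylo` tree on the union leaf set.
#' @export
brf_star <- function(backbone, reference) {
  task <- completion_task(backbone, reference)
  .brf_run(task, mode = "star")
}

.is_binary_unrooted <- function(phy) {
  o <- min(phy$tip.label)
  rt <- rt_from_phylo(phy, o)
  rt_is_binary(rt)
}

.brf_run <- function(task, mode = c("star", "plus")) {
  mode <- match.arg(mode)
  o <- task$outgroup
  Tb <- rt_from_phylo(task$backbone, o)
  Tr <- rt_from_phylo(task$reference, o)
  shared <- setdiff(task$shared, o)
  tr_leafset <- task$reference$tip.label
  ltr <- rt_leafsets(Tr)
  fully_missing <- vapply(seq_along(Tr$par),
                          function(v) !any(ltr[[v]] %in% task$backbone$tip.label),
                          logical(1L))
  bbmap <- as.list(rt_leafmap(Tb))

  graft <- function(p) {
    kids <- Tr$kids[[p]]
    U <- kids[fully_missing[kids]]
    if (length(U)) {
      anchor <- intersect(ltr[[p]], names(bbmap))
      if (!length(anchor)) {
        s_b <- Tb$root
        case1 <- (mode == "plus")
      } else {
        s_b <- rt_lca_ids(Tb, unlist(bbmap[anchor], use.names = FALSE))
        if (mode == "plus") {
          case1 <- TRUE
        } else {
          ## case 1 needs the grafted edge below the new node to recover a
          ## reference bipartition: the sibling set of the grafted group
          ## must be a single reference subtree (otherwise the reference
          ## has no edge above it) whose backbone image is exactly s_b
          lb <- rt_leaves_below(Tb, s_b)
          case1 <- length(setdiff(kids, U)) == 1L &&
            setequal(intersect(lb, tr_leafset), anchor)
        }
      }
      roots <- vapply(U, function(u) rt_copy_subtree(Tb, Tr, u, 0L),
                      integer(1L))
      if (case1) {
        w <- rt_insert_above(Tb, s_b)
        for (r in roots) rt_attach(Tb, r, w)
      } else {
        for (r in roots) rt_attach(Tb, r, s_b)
      }
      for (r in roots) {
        for (leaf in which(!is.na(Tb$lab) & !lengths(Tb$kids)))
          if (is.null(bbmap[[Tb$lab[leaf]]])) bbmap[[Tb$lab[leaf]]] <<- leaf
      }
    }
    for (c in kids) {
      if (!fully_missing[c] && length(Tr$kids[[c]])) graft(c)
    }
  }
  if (fully_missing[Tr$root]) {
    ## degenerate task: only o is shared; graft the whole reference beside
    ## the backbone root
    r <- rt_copy_subtree(Tb, Tr, Tr$root, 0L)
    if (mode == "plus" || !length(Tb$kids[[Tb$root]])) {
      w <- rt_insert_above(Tb, Tb$root)
      rt_attach(Tb, r, w)
    } else {
      rt_attach(Tb, r, Tb$root)
    }
  } else {
    graft(Tr$root)
  }
  rt_to_phylo(Tb, o)
}

#' Refine a multifurcating backbone with compatible reference bipartitions
#'
#' Adds to the backbone every bipartition of the reference that (restricted
#' to the backbone's leaves) is compatible with it, by grouping, at each
#' backbone polytomy, the children covered by a reference node whose own
#' children all map inside distinct child subtrees. The output is a
#' resolution of the backbone and contains no bipartition absent from both
#' input trees.
#'
#' @param backbone A `phylo` tree (possibly multifurcating).
#' @param reference A `phylo` tree sharing at least one leaf with the
#'   backbone.
#' @return A `phylo` tree on the backbone leaf set.
#' @export
expand_backbone <- function(backbone, reference) {
  shared <- intersect(backbone$tip.label, reference$tip.label)
  if (!length(shared))
    stop("backbone and reference share no leaf to root on")
  o <- min(shared)
  Tb <- rt_from_phylo(backbone, o)
  if (rt_is_binary(Tb)) return(backbone)
  Tr <- rt_from_phylo(reference, o)
  shared_p <- setdiff(shared, o)
  ltr <- rt_leafsets(Tr)
  bbmap <- rt_leafmap(Tb)

  ## postorder list of internal nodes of Tr
  post <- integer(0L)
  walk <- function(v) {
    for (c in Tr$kids[[v]]) walk(c)
    if (length(Tr$kids[[v]])) post <<- c(post, v)
  }
  walk(Tr$root)

  for (u in post) {
    su <- intersect(ltr[[u]], shared_p)
    if (length(su) < 2L || length(su) >= length(shared_p)) next
    v <- rt_lca_ids(Tb, unname(bbmap[su]))
    if (rt_nkids(Tb, v) <= 2L) next
    ## group the children of the polytomy v that carry the reference
    ## cluster; the grouping realizes the restricted reference split
    ## exactly when the grouped subtrees' shared leaves equal the cluster
    ## (otherwise the split crosses an existing backbone branch)
    W <- Filter(function(w) any(rt_leaves_below(Tb, w) %in% su),
                Tb$kids[[v]])
    if (length(W) < 2L || length(W) >= rt_nkids(Tb, v)) next
    covered <- unlist(lapply(W, function(w) rt_leaves_below(Tb, w)),
                      use.names = FALSE)
    if (!setequal(intersect(covered, shared_p), su)) next
    nv <- rt_add(Tb, v)
    for (w in W) {
      Tb$kids[[v]] <- setdiff(Tb$kids[[v]], w)
      Tb$par[w] <- nv
      Tb$kids[[nv]] <- c(Tb$kids[[nv]], w)
    }
  }
  rt_to_phylo(Tb, o)
}

#' Complete a backbone tree with the leaves of a reference tree
#'
#' The completion pipeline: the backbone's polytomies are first refined
#' with every compatible reference bipartition ([expand_backbone()]), then
#' missing leaves are grafted by the multifurcating-output completion
#' ([brf_star()]), grouping fully-missing subtrees that hang from the same
#' reference polytomy. The output contains all leaves of both trees and its
#' restriction to the backbone leaves is a resolution of the backbone, so
#' the output is always compatible with the backbone.
#'
#' @param backbone A `phylo` tree (possibly incomplete and multifurcating);
#'   typically a constraint tree.
#' @param reference A `phylo` tree supplying missing leaves; typically a
#'   gene tree.
#' @return A `phylo` tree on the union of the two leaf sets.
#' @export
comp <- function(backbone, reference) {
  shared <- intersect(backbone$tip.label, reference$tip.label)
  if (!length(shared))
    stop("backbone and reference share no leaf to root on")
  expanded <- expand_backbone(backbone, reference)
  brf_star(expanded, reference)
}
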