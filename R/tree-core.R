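#' @importFrom ape read.tree write.tree keep.tip collapse.singles
#' @importFrom stats cophenetic rnorm runif rpois
#' @importFrom utils combn
NULL

#' Parse a newick string into a phylo object
#'
#' Trees are handled with unrooted semantics throughout the package:
#' polytomies are preserved and a stored root of degree two is treated as an
#' artifact of the newick notation. Support values are read from internal
#' node labels when these are numeric and fall in \[0, 1\] (the convention
#' used by most maximum-likelihood and summary tools); other label dialects
#' are not interpreted.
#'
#' @param text A single newick string (terminated by `;`).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("`text` must be a single newick string")
  .check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("newick parse error: unparsable string")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(phy$tip.label))) stop("empty leaf label")
  phy
}

## locate unbalanced parentheses / missing terminator with a 1-based offset
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at offset ", i, ": unmatched ')'")
    }
  }
  if (depth > 0L)
    stop("newick parse error at offset ", length(chars),
         ": ", depth, " unclosed '('")
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error at offset ", length(chars),
         ": missing ';' terminator")
  invisible(TRUE)
}

#' Serialize a tree (or list of trees) to newick
#'
#' @param tree A `phylo` object or a list of them.
#' @param path Optional file path; when `NULL` the newick string(s) are
#'   returned invisibly as a character vector.
#' @return Character vector of newick strings (invisibly when writing).
#' @export
write_newick <- function(tree, path = NULL) {
  trees <- if (inherits(tree, "phylo")) list(tree) else tree
  txt <- vapply(trees, function(t) ape::write.tree(t), character(1L))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read newick trees from a file
#'
#' @param path Path to a file with one newick tree per line.
#' @return A list of `phylo` objects.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("cannot open file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in file: ", path)
  lapply(lines, parse_newick)
}

#' Restrict a tree to a subset of its leaves
#'
#' Returns the induced topology on `keep` intersected with the tree's
#' leaves, with all degree-two nodes suppressed.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain.
#' @return A `phylo` object on the retained leaves.
#' @export
restrict <- function(tree, keep) {
  shared <- intersect(tree$tip.label, keep)
  if (!length(shared)) stop("restriction to an empty leaf set")
  if (length(shared) < 2L)
    stop("cannot represent a tree with fewer than 2 leaves")
  if (length(shared) == length(tree$tip.label)) return(tree)
  out <- ape::keep.tip(tree, shared)
  ape::collapse.singles(out)
}

## ---- split machinery -------------------------------------------------------
## A split is stored as the sorted character vector of labels on the side not
## containing the reference leaf (the lexicographically smallest leaf unless
## an outgroup is supplied). Keys are collapse-joined strings for set algebra
## on trees of any size.

## logical descendant matrix: rows = internal edges (child node ids), cols =
## tips in tree order
.descendant_sets <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  m <- matrix(FALSE, nt + nn, nt)
  m[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  ## edges in postorder: children before parents
  e <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(e))) {
    m[e[i, 1L], ] <- m[e[i, 1L], ] | m[e[i, 2L], ]
  }
  m
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' One bipartition per internal edge; pendant (leaf) edges are excluded.
#' Each bipartition is reported as the sorted label vector of the side not
#' containing the reference leaf.
#'
#' @param tree A `phylo` object.
#' @param ref Reference leaf used to orient the splits; defaults to the
#'   lexicographically smallest leaf label.
#' @return A list of character vectors (possibly empty for a star tree).
#' @export
bipartitions <- function(tree, ref = NULL) {
  nt <- length(tree$tip.label)
  if (nt < 4L) return(list())
  if (is.null(ref)) ref <- min(tree$tip.label)
  if (!ref %in% tree$tip.label) stop("`ref` is not a leaf of the tree")
  m <- .descendant_sets(tree)
  e <- tree$edge
  internal <- e[, 2L] > nt
  kids <- e[internal, 2L]
  ri <- match(ref, tree$tip.label)
  out <- list()
  seen <- character(0L)
  for (v in kids) {
    side <- m[v, ]
    if (side[ri]) side <- !side
    sz <- sum(side)
    if (sz < 2L || sz > nt - 2L) next
    lab <- sort(tree$tip.label[side])
    key <- paste(lab, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- lab
  }
  out
}

## split keys for a tree restricted to `labels` (labels must include ref);
## returns character keys of nontrivial splits of restrict(tree, labels)
.split_keys <- function(tree, labels = tree$tip.label, ref = NULL) {
  shared <- intersect(tree$tip.label, labels)
  if (is.null(ref)) ref <- min(shared)
  nt <- length(tree$tip.label)
  m <- .descendant_sets(tree)
  e <- tree$edge
  kids <- e[e[, 2L] > nt, 2L]
  keep <- tree$tip.label %in% shared
  ri <- match(ref, tree$tip.label)
  ns <- length(shared)
  keys <- character(0L)
  for (v in kids) {
    side <- m[v, ] & keep
    if (side[ri]) side <- keep & !side
    sz <- sum(side)
    if (sz < 2L || sz > ns - 2L) next
    keys <- c(keys, paste(sort(tree$tip.label[side]), collapse = "\r"))
  }
  unique(keys)
}

#' Compatibility of a cluster with a tree
#'
#' A cluster `A` (one side of the bipartition `A | L \ A`) is compatible
#' with a tree `T` when some tree containing that bipartition induces a
#' resolution of `T` on `T`'s leaves. This is decided by restricting the
#' bipartition to `T`'s leaf set and testing pairwise split compatibility
#' (one empty pairwise intersection) against every split of `T`; a
#' restriction that becomes trivial is always compatible.
#'
#' @param A Character vector of leaf labels (the cluster).
#' @param tree A `phylo` object.
#' @return `TRUE` or `FALSE`.
#' @export
is_compatible <- function(A, tree) {
  lt <- tree$tip.label
  At <- lt %in% A
  na <- sum(At)
  if (na <= 1L || na >= length(lt) - 1L) return(TRUE)
  nt <- length(lt)
  if (nt < 4L) return(TRUE)
  m <- .descendant_sets(tree)
  e <- tree$edge
  kids <- e[e[, 2L] > nt, 2L]
  for (v in kids) {
    s <- m[v, ]
    sz <- sum(s)
    if (sz < 2L || sz > nt - 2L) next
    ## one of the four pairwise intersections must be empty
    if (!(!any(At & s) || !any(At & !s) || !any(!At & s) || !any(!At & !s)))
      return(FALSE)
  }
  TRUE
}

#' Is one tree compatible with (a resolution-extension of) another?
#'
#' `TRUE` when `tree` restricted to the leaves of `backbone` induces a
#' resolution of `backbone`, i.e. every split of `backbone` appears among
#' the restricted splits of `tree`.
#'
#' @param tree,backbone `phylo` objects; `backbone`'s leaves need not all be
#'   present in `tree` (splits are compared on the shared leaf set).
#' @return `TRUE` or `FALSE`.
#' @export
resolves <- function(tree, backbone) {
  shared <- intersect(tree$tip.label, backbone$tip.label)
  if (length(shared) < 4L) return(TRUE)
  ref <- min(shared)
  kb <- .split_keys(backbone, shared, ref)
  kt <- .split_keys(tree, shared, ref)
  all(kb %in% kt)
}

#' False-negative / false-positive branch counts and RF distance
#'
#' Both trees are restricted to their shared leaves. FN counts bipartitions
#' of the reference absent from the estimate, FP the reverse; RF is their
#' sum and the normalized RF divides by the total number of internal
#' branches in the two (restricted) trees.
#'
#' @param estimated,reference `phylo` objects.
#' @return A list with elements `fn`, `fp`, `rf`, `nrf`.
#' @export
fn_fp <- function(estimated, reference) {
  shared <- intersect(estimated$tip.label, reference$tip.label)
  if (length(shared) < 4L)
    stop("fewer than 4 shared leaves between the two trees")
  ref <- min(shared)
  ke <- .split_keys(estimated, shared, ref)
  kr <- .split_keys(reference, shared, ref)
  fn <- sum(!kr %in% ke)
  fp <- sum(!ke %in% kr)
  denom <- length(ke) + length(kr)
  list(fn = fn, fp = fp, rf = fn + fp,
       nrf = if (denom > 0L) (fn + fp) / denom else 0)
}

#' Collapse weakly supported branches into polytomies
#'
#' Every internal edge whose support value is less than or equal to
#' `threshold` is contracted. Supports are taken from internal node labels
#' (see [parse_newick()]).
#'
#' @param tree A `phylo` object carrying numeric internal node labels.
#' @param threshold Support threshold in \[0, 1\]; edges with support
#'   `<= threshold` are removed.
#' @return A `phylo` object, possibly with polytomies. Surviving supports
#'   are retained.
#' @export
contract_by_support <- function(tree, threshold) {
  if (is.null(tree$node.label))
    stop("tree carries no support values (internal node labels)")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  nt <- length(tree$tip.label)
  root <- nt + 1L
  ## internal nodes other than the root whose support is missing -> error
  ids <- (nt + 1L):(nt + tree$Nnode)
  nonroot <- ids[ids != root]
  if (any(is.na(sup[nonroot - nt])))
    stop("tree carries no support values (non-numeric internal node labels)")
  drop <- nonroot[sup[nonroot - nt] <= threshold]
  collapse_internal_nodes(tree, drop)
}

#' Contract a set of internal edges of a tree
#'
#' Each listed internal node is spliced out: its children become children of
#' its parent, removing the corresponding internal edge. The stored root
#' cannot be contracted.
#'
#' @param tree A `phylo` object.
#' @param nodes Integer vector of internal node ids (in ape numbering,
#'   `> Ntip(tree)`), excluding the root.
#' @return A `phylo` object.
#' @export
collapse_internal_nodes <- function(tree, nodes) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  if (any(nodes <= nt)) stop("only internal nodes can be contracted")
  if (root %in% nodes) stop("the stored root cannot be contracted")
  if (!length(nodes)) return(tree)
  kids <- .children_list(tree)
  labels <- tree$node.label
  has_lab <- !is.null(labels)
  drop <- rep(FALSE, nt + tree$Nnode)
  drop[nodes] <- TRUE
  build <- function(v) {
    ## returns the newick fragment(s) contributed by v: a single node
    ## string normally, or the spliced child fragments when v is dropped
    if (v <= nt) return(tree$tip.label[v])
    parts <- unlist(lapply(kids[[v]], build))
    if (v != root && drop[v]) return(parts)
    lab <- if (has_lab) labels[v - nt] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  txt <- paste0(build(root), ";")
  parse_newick(txt)
}

## children-of-node list indexed by node id
.children_list <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1L]]] <- c(kids[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  kids
}

#' Choose the designated outgroup leaf
#'
#' The lexicographically smallest label shared by all supplied trees; when
#' no label is common to all, the smallest label of the union. Used to give
#' clusters a canonical orientation.
#'
#' @param trees A list of `phylo` objects.
#' @return A single leaf label.
#' @export
choose_outgroup <- function(trees) {
  labs <- lapply(trees, function(t) t$tip.label)
  shared <- Reduce(intersect, labs)
  if (length(shared)) return(min(shared))
  min(unlist(labs))
}

#' Are two trees topologically identical?
#'
#' Same leaf set and identical split sets (an isomorphism test for
#' unrooted, possibly multifurcating trees).
#'
#' @param a,b `phylo` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_topology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  if (length(a$tip.label) < 4L) return(TRUE)
  r <- min(a$tip.label)
  setequal(.split_keys(a, ref = r), .split_keys(b, ref = r))
}

#' Leaves of a tree
#' @param tree A `phylo` object.
#' @return Sorted character vector of leaf labels.
#' @export
leaves <- function(tree) sort(tree$tip.label)

#' Build a star (fully unresolved) tree
#' @param labels Leaf labels.
#' @return A `phylo` object with a single internal node.
#' @export
star_tree <- function(labels) {
  parse_newick(paste0("(", paste(labels, collapse = ","), ");"))
}
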