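## Exact small-instance oracles: exhaustive enumeration over all unrooted
## binary topologies, used to validate the completion algorithm (global
## RF minimum over all trees compatible with a backbone) and the dynamic
## program (global quartet-score maximum, optionally constraint-filtered).
## Enumerations are cached per leaf count within the session.

.oracle_cache <- new.env(parent = emptyenv())

.pc16 <- local({
  v <- integer(65536L)
  for (i in 1L:65535L) v[i + 1L] <- v[i %/% 2L + 1L] + i %% 2L
  v
})

.popcount <- function(x) {
  .pc16[bitwAnd(x, 65535L) + 1L] + .pc16[bitwShiftR(x, 16L) + 1L]
}

.generic_labels <- function(n) sprintf("@%02d", seq_len(n))

## cluster masks (side not containing leaf index 1) for a phylo whose tips
## are a subset of `labels`; nontrivial splits only
.cluster_masks <- function(phy, labels, ref = NULL) {
  lt <- phy$tip.label
  if (is.null(ref)) ref <- min(lt)
  rt <- rt_from_phylo(phy, ref)
  ls <- rt_leafsets(rt)
  nt <- length(lt)
  masks <- vapply(ls, function(ll)
    as.integer(sum(2^(match(ll, labels) - 1L))), integer(1L))
  sizes <- lengths(ls)
  unique(masks[sizes >= 2L & sizes <= nt - 2L])
}

## restrict cluster masks to subset mask S, canonicalizing on refbit
## (the bit of the chosen reference leaf inside S); returns unique
## nontrivial split masks
.restrict_masks <- function(masks, S, refbit) {
  if (!length(masks)) return(integer(0L))
  m <- bitwAnd(masks, S)
  flip <- bitwAnd(m, refbit) != 0L
  m[flip] <- bitwAnd(S, bitwNot(m[flip]))
  sz <- .popcount(m)
  ns <- .popcount(S)
  unique(m[sz >= 2L & sz <= ns - 2L])
}

.topo_cache_get <- function(n) {
  key <- sprintf("n%d", n)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  if (n < 4L || n > 10L)
    stop("topology enumeration supports 4 to 10 leaves (got ", n, ")")
  glab <- .generic_labels(n)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = glab)
  ## expand the compressed multiPhylo container into plain phylo objects
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  CM <- lapply(trees, .cluster_masks, labels = glab, ref = glab[1L])
  ## quartet pairings per topology (binary trees: always resolved)
  qc <- utils::combn(n, 4L)
  nq <- ncol(qc)
  pairQ <- matrix(0L, nq, length(trees))
  i <- qc[1L, ]; j <- qc[2L, ]; k <- qc[3L, ]; l <- qc[4L, ]
  for (t in seq_along(trees)) {
    phy <- trees[[t]]
    phy$edge.length <- rep(1, nrow(phy$edge))
    D <- stats::cophenetic(phy)
    D <- D[glab, glab]
    s1 <- D[cbind(i, j)] + D[cbind(k, l)]
    s2 <- D[cbind(i, k)] + D[cbind(j, l)]
    s3 <- D[cbind(i, l)] + D[cbind(j, k)]
    p <- integer(nq)
    p[s1 < s2 & s1 < s3] <- 1L
    p[s2 < s1 & s2 < s3] <- 2L
    p[s3 < s1 & s3 < s2] <- 3L
    pairQ[, t] <- p
  }
  qkeys <- ((i * 1024 + j) * 1024 + k) * 1024 + l
  val <- list(trees = trees, CM = CM, pairQ = pairQ, qkeys = qkeys, nq = nq,
              glab = glab)
  assign(key, val, envir = .oracle_cache)
  val
}

#' All unrooted binary topologies on a leaf set
#'
#' @param labels Character vector of 4 to 10 leaf labels.
#' @return A list of `phylo` objects ((2n-5)!! trees).
#' @export
all_binary_topologies <- function(labels) {
  labels <- sort(labels)
  cache <- .topo_cache_get(length(labels))
  lapply(cache$trees, function(t) {
    t$tip.label <- labels[match(t$tip.label, cache$glab)]
    t
  })
}

#' Exhaustive minimum-RF completion oracle
#'
#' Enumerates every binary tree on the union leaf set whose restriction to
#' the backbone resolves it, together with every contraction of each, and
#' returns the minimum RF distance to the reference over this set -- the
#' global optimum over all (binary or multifurcating) trees compatible
#' with the backbone. Intended for validation at 7 or fewer union leaves.
#'
#' @param backbone,reference `phylo` objects.
#' @return A list with `min_rf` (global optimum over all compatible trees)
#'   and `min_rf_binary` (optimum over binary completions only).
#' @export
oracle_min_rf_completion <- function(backbone, reference) {
  labels <- sort(union(backbone$tip.label, reference$tip.label))
  n <- length(labels)
  cache <- .topo_cache_get(n)
  bmask <- as.integer(sum(2^(match(backbone$tip.label, labels) - 1L)))
  rmask <- as.integer(sum(2^(match(reference$tip.label, labels) - 1L)))
  bref <- as.integer(2^(match(min(backbone$tip.label), labels) - 1L))
  rref <- as.integer(2^(match(min(reference$tip.label), labels) - 1L))
  bsplits <- .restrict_masks(.cluster_masks(backbone, labels), bmask, bref)
  rsplits <- .restrict_masks(.cluster_masks(reference, labels), rmask, rref)
  best <- Inf
  best_bin <- Inf
  for (t in seq_along(cache$CM)) {
    ## cached masks are canonical on generic index 1 == labels[1]
    E <- cache$CM[[t]]
    rb <- .restrict_masks(E, bmask, bref)
    if (!all(bsplits %in% rb)) next
    rk_full <- .restrict_masks(E, rmask, rref)
    rf_bin <- sum(!rsplits %in% rk_full) + sum(!rk_full %in% rsplits)
    best_bin <- min(best_bin, rf_bin)
    ne <- length(E)
    for (d in 0:(2^ne - 1L)) {
      keep <- E[bitwAnd(d, bitwShiftL(1L, seq_len(ne) - 1L)) == 0L]
      kb <- .restrict_masks(keep, bmask, bref)
      if (!all(bsplits %in% kb)) next
      rk <- .restrict_masks(keep, rmask, rref)
      rf <- sum(!rsplits %in% rk) + sum(!rk %in% rsplits)
      if (rf < best) best <- rf
    }
  }
  list(min_rf = best, min_rf_binary = best_bin)
}

#' Exhaustive quartet-score maximization oracle
#'
#' Enumerates all unrooted binary topologies on `labels` (optionally only
#' those compatible with a constraint tree) and returns the maximum quartet
#' score against the gene trees along with one maximizing topology.
#'
#' @param genetrees A list of `phylo` objects on subsets of `labels`.
#' @param labels Leaf set of the candidate trees (4 to 10 labels).
#' @param constraint Optional `phylo` constraint tree on a subset of
#'   `labels`; candidates must resolve it.
#' @return A list with `score` (the maximal quartet score), `tree` (a
#'   maximizing `phylo`), and `n_candidates`.
#' @export
oracle_best_tree <- function(genetrees, labels, constraint = NULL) {
  if (inherits(genetrees, "phylo")) genetrees <- list(genetrees)
  labels <- sort(labels)
  n <- length(labels)
  cache <- .topo_cache_get(n)
  keep <- rep(TRUE, length(cache$CM))
  if (!is.null(constraint)) {
    cmask <- as.integer(sum(2^(match(constraint$tip.label, labels) - 1L)))
    cref <- as.integer(2^(match(min(constraint$tip.label), labels) - 1L))
    csplits <- .restrict_masks(.cluster_masks(constraint, labels),
                               cmask, cref)
    for (t in seq_along(cache$CM)) {
      rc <- .restrict_masks(cache$CM[[t]], cmask, cref)
      keep[t] <- all(csplits %in% rc)
    }
  }
  if (!any(keep)) stop("no binary topology is compatible with the constraint")
  ## per-quartet pairing counts from the gene trees
  agg <- .qt_aggregate(genetrees, labels)
  nq <- cache$nq
  cnt3 <- matrix(0, nq, 3L)
  if (agg$n) {
    ## reconstruct (a<b<c<d, pairing) per aggregated record
    abcd <- cbind(agg$x1, agg$x2, agg$y1, agg$y2)
    srt <- t(apply(abcd, 1L, sort))
    key <- ((srt[, 1L] * 1024 + srt[, 2L]) * 1024 + srt[, 3L]) * 1024 +
      srt[, 4L]
    row <- match(key, cache$qkeys)
    a <- srt[, 1L]; b <- srt[, 2L]; c <- srt[, 3L]; d <- srt[, 4L]
    pr <- ifelse((agg$x1 == a & agg$x2 == b) | (agg$y1 == a & agg$y2 == b),
                 1L,
                 ifelse((agg$x1 == a & agg$x2 == c) |
                          (agg$y1 == a & agg$y2 == c), 2L, 3L))
    for (r in seq_along(row))
      cnt3[row[r], pr[r]] <- cnt3[row[r], pr[r]] + agg$cnt[r]
  }
  cand <- which(keep)
  PQ <- cache$pairQ[, cand, drop = FALSE]
  cntvec <- as.vector(cnt3)
  lin <- matrix(seq_len(nq), nq, length(cand)) + (PQ - 1L) * nq
  vals <- matrix(cntvec[lin], nq, length(cand))
  scores <- colSums(vals)
  bi <- cand[which.max(scores)]
  tree <- cache$trees[[bi]]
  tree$tip.label <- labels[match(tree$tip.label, cache$glab)]
  list(score = max(scores), tree = tree, n_candidates = length(cand))
}
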