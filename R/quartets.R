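## Quartet topology machinery.
##
## Induced quartet topologies are read off the four-point condition applied
## to path (topological) distances: with unit branch lengths, for leaves
## a<b<c<d the pair sums d(a,b)+d(c,d), d(a,c)+d(b,d), d(a,d)+d(b,c)
## identify the induced split as the strictly smallest sum; a three-way tie
## means the quartet is unresolved (passes through a polytomy).
## A "record" is (a,b,c,d, pairing) with global leaf indices a<b<c<d and
## pairing 1 = ab|cd, 2 = ac|bd, 3 = ad|bc.

## quartet records of one tree, with leaf indices relative to `labels`
.qt_records <- function(tree, labels) {
  lt <- tree$tip.label
  gl <- match(lt, labels)
  if (anyNA(gl)) stop("tree contains leaves outside the global leaf set: ",
                      paste(lt[is.na(gl)], collapse = ", "))
  m <- length(lt)
  if (m < 4L) return(.qt_empty())
  phy <- tree
  phy$edge.length <- rep(1, nrow(phy$edge))
  D <- stats::cophenetic(phy)
  perm <- order(gl)
  D <- D[lt[perm], lt[perm], drop = FALSE]
  g <- gl[perm]
  q <- utils::combn(m, 4L)
  i <- q[1L, ]; j <- q[2L, ]; k <- q[3L, ]; l <- q[4L, ]
  s1 <- D[cbind(i, j)] + D[cbind(k, l)]
  s2 <- D[cbind(i, k)] + D[cbind(j, l)]
  s3 <- D[cbind(i, l)] + D[cbind(j, k)]
  pair <- integer(length(s1))
  pair[s1 < s2 & s1 < s3] <- 1L
  pair[s2 < s1 & s2 < s3] <- 2L
  pair[s3 < s1 & s3 < s2] <- 3L
  keep <- pair > 0L
  list(a = g[i[keep]], b = g[j[keep]], c = g[k[keep]], d = g[l[keep]],
       pair = pair[keep])
}

.qt_empty <- function()
  list(a = integer(0L), b = integer(0L), c = integer(0L), d = integer(0L),
       pair = integer(0L))

## encode records as exact doubles (labels indices < 2^10, fine up to n=1024)
.qt_keys <- function(r) {
  (((r$a * 1024 + r$b) * 1024 + r$c) * 1024 + r$d) * 4 + r$pair
}

## aggregate records over a set of gene trees into unique records + counts,
## plus the sibling-pair layout used by the weight function:
## (x1,x2) and (y1,y2) are the two sibling pairs of each resolved quartet
.qt_aggregate <- function(genetrees, labels) {
  recs <- lapply(genetrees, .qt_records, labels = labels)
  a <- unlist(lapply(recs, `[[`, "a"))
  b <- unlist(lapply(recs, `[[`, "b"))
  c <- unlist(lapply(recs, `[[`, "c"))
  d <- unlist(lapply(recs, `[[`, "d"))
  p <- unlist(lapply(recs, `[[`, "pair"))
  if (!length(a))
    return(list(x1 = integer(0L), x2 = integer(0L), y1 = integer(0L),
                y2 = integer(0L), cnt = numeric(0L), n = 0L))
  key <- (((a * 1024 + b) * 1024 + c) * 1024 + d) * 4 + p
  u <- unique(key)
  cnt <- tabulate(match(key, u))
  first <- match(u, key)
  a <- a[first]; b <- b[first]; c <- c[first]; d <- d[first]; p <- p[first]
  x1 <- ifelse(p == 1L, a, ifelse(p == 2L, a, a))
  x2 <- ifelse(p == 1L, b, ifelse(p == 2L, c, d))
  y1 <- ifelse(p == 1L, c, ifelse(p == 2L, b, b))
  y2 <- ifelse(p == 1L, d, ifelse(p == 2L, d, c))
  list(x1 = as.integer(x1), x2 = as.integer(x2),
       y1 = as.integer(y1), y2 = as.integer(y2),
       cnt = as.numeric(cnt), n = length(u))
}

#' Quartet score of a tree against a set of gene trees
#'
#' The number of four-leaf induced topologies shared between `tree` and
#' each gene tree, summed over the gene trees. Gene trees may be incomplete
#' (quartets over absent leaves never form) and multifurcating (unresolved
#' quartets contribute nothing). Exact enumeration over all four-subsets;
#' intended for desk-scale trees (roughly up to 25 leaves).
#'
#' @param tree A `phylo` object.
#' @param genetrees A list of `phylo` objects.
#' @return The quartet score (a non-negative number).
#' @export
quartet_score <- function(tree, genetrees) {
  if (inherits(genetrees, "phylo")) genetrees <- list(genetrees)
  labels <- sort(unique(c(tree$tip.label,
                          unlist(lapply(genetrees, `[[`, "tip.label")))))
  keysT <- .qt_keys(.qt_records(tree, labels))
  total <- 0
  for (g in genetrees) {
    keysG <- .qt_keys(.qt_records(g, labels))
    total <- total + sum(keysG %in% keysT)
  }
  total
}

#' Weight of a tripartition under a set of gene trees
#'
#' The tripartition `A' | A \ A' | L \ A` around an internal node of a tree
#' rooted at the outgroup is weighted by the number of gene-tree quartets
#' `ab|cd` whose sibling pair `{a, b}` lies inside one part while `c` and
#' `d` fall in the two remaining parts (counted for both sibling pairs of
#' each resolved quartet). Summing these weights over the internal nodes of
#' any binary tree yields twice its quartet score, which is the doubled
#' convention used by the dynamic program.
#'
#' @param parts A list of three disjoint character vectors jointly
#'   partitioning the full leaf set.
#' @param genetrees A list of `phylo` objects.
#' @return A non-negative number.
#' @export
tripartition_weight <- function(parts, genetrees) {
  if (inherits(genetrees, "phylo")) genetrees <- list(genetrees)
  if (!is.list(parts) || length(parts) != 3L)
    stop("`parts` must be a list of three leaf-label vectors")
  labels <- sort(unlist(parts))
  if (anyDuplicated(labels) || !all(lengths(parts) >= 0L))
    stop("the three parts must be disjoint")
  glabs <- sort(unique(unlist(lapply(genetrees, `[[`, "tip.label"))))
  if (!all(glabs %in% labels))
    stop("the three parts must jointly cover the gene-tree leaf set")
  agg <- .qt_aggregate(genetrees, labels)
  p <- integer(length(labels))
  p[match(parts[[1L]], labels)] <- 1L
  p[match(parts[[2L]], labels)] <- 2L
  p[match(parts[[3L]], labels)] <- 3L
  .weight_eval(agg, p)
}

## evaluate the tripartition weight for a part-assignment vector p over the
## aggregated records
.weight_eval <- function(agg, p) {
  if (!agg$n) return(0)
  px1 <- p[agg$x1]; px2 <- p[agg$x2]; py1 <- p[agg$y1]; py2 <- p[agg$y2]
  c1 <- px1 == px2 & py1 != py2 & py1 != px1 & py2 != px1
  c2 <- py1 == py2 & px1 != px2 & px1 != py1 & px2 != py1
  sum(agg$cnt * (c1 + c2))
}

#' Pairwise similarity matrix from gene-tree quartet frequencies
#'
#' Entry (i, j) is the fraction, over all resolved gene-tree quartets that
#' contain both leaves, in which the two leaves are siblings (paired on the
#' same side of the induced split). Pairs that never co-occur in a resolved
#' quartet are imputed with the mean of the observed entries in their rows
#' and recorded in the `imputed_pairs` attribute. The diagonal is set to
#' the maximal value.
#'
#' @param genetrees A list of `phylo` objects.
#' @param labels Optional ordered leaf set; defaults to the union of the
#'   gene-tree leaves.
#' @return A symmetric numeric matrix with leaf labels as dimnames.
#' @export
quartet_similarity_matrix <- function(genetrees, labels = NULL) {
  if (inherits(genetrees, "phylo")) genetrees <- list(genetrees)
  if (!length(genetrees)) stop("at least one gene tree is required")
  if (is.null(labels))
    labels <- sort(unique(unlist(lapply(genetrees, `[[`, "tip.label"))))
  n <- length(labels)
  agg <- .qt_aggregate(genetrees, labels)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  if (agg$n) {
    combos <- list(c("x1", "x2"), c("y1", "y2"),
                   c("x1", "y1"), c("x1", "y2"),
                   c("x2", "y1"), c("x2", "y2"))
    for (cb in combos) {
      i <- agg[[cb[1L]]]; j <- agg[[cb[2L]]]
      idx <- (pmin(i, j) - 1L) * n + pmax(i, j)
      s <- rowsum(agg$cnt, idx)
      den[as.integer(rownames(s))] <- den[as.integer(rownames(s))] + s[, 1L]
    }
    for (cb in combos[1:2]) {
      i <- agg[[cb[1L]]]; j <- agg[[cb[2L]]]
      idx <- (pmin(i, j) - 1L) * n + pmax(i, j)
      s <- rowsum(agg$cnt, idx)
      num[as.integer(rownames(s))] <- num[as.integer(rownames(s))] + s[, 1L]
    }
  }
  sim <- matrix(NA_real_, n, n)
  obs <- den > 0
  sim[obs] <- num[obs] / den[obs]
  ## counts were accumulated in the lower triangle; mirror upward
  sim[upper.tri(sim)] <- t(sim)[upper.tri(sim)]
  diag(sim) <- NA
  imputed <- which(is.na(sim) & upper.tri(sim), arr.ind = TRUE)
  if (nrow(imputed)) {
    rowmean <- rowMeans(sim, na.rm = TRUE)
    rowmean[is.nan(rowmean)] <- 0
    for (r in seq_len(nrow(imputed))) {
      i <- imputed[r, 1L]; j <- imputed[r, 2L]
      v <- mean(c(rowmean[i], rowmean[j]))
      sim[i, j] <- sim[j, i] <- v
    }
  }
  mx <- suppressWarnings(max(sim[upper.tri(sim)], 0))
  diag(sim) <- max(1, mx)
  dimnames(sim) <- list(labels, labels)
  attr(sim, "imputed_pairs") <-
    if (nrow(imputed)) cbind(labels[imputed[, 1L]], labels[imputed[, 2L]])
    else matrix(character(0L), 0L, 2L)
  sim
}
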