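## The cluster dynamic program: S(A) = max over splits (A', A \ A') with
## both halves in X of S(A') + S(A \ A') + w(A' | A \ A' | L \ A), with
## S({x}) = 0. Weights follow the doubled convention (the weight counts
## each quartet's two sibling pairs), so the summed weights of any binary
## tree equal twice its quartet score; reported scores are halved at the
## boundary.

## lexicographic order on label sets encoded as masks: the smaller set is
## the one containing the smallest differing label
.lex_less <- function(m1, m2) {
  d <- bitwXor(m1, m2)
  if (d == 0L) return(FALSE)
  lb <- bitwAnd(d, -d)
  bitwAnd(m1, lb) != 0L
}

## deterministic tie key: the smaller side of the split (by size, then
## lexicographically); candidates compare by lex order of that side
.split_key <- function(a, b) {
  pa <- .popcount(a); pb <- .popcount(b)
  if (pa < pb) return(a)
  if (pb < pa) return(b)
  if (.lex_less(a, b)) a else b
}

#' Solve the cluster dynamic program over a search space
#'
#' Memoized bottom-up maximization of the doubled quartet score over all
#' ordered splits of each cluster into two members of X, followed by
#' backtracking into a binary species tree (the outgroup is re-attached at
#' the top). Weights are always computed against the supplied gene trees.
#' Ties are broken toward the split whose smaller side is
#' lexicographically least, making results run-to-run deterministic.
#'
#' @param space A `conquart_space` from [build_search_space()] (or a
#'   compatible list with `labels`, `outgroup`, `masks`, and optionally
#'   `witnesses`).
#' @param genetrees A list of `phylo` gene trees.
#' @return An object of class `conquart_dp`: a list with `score` (quartet
#'   score of the optimal tree), `score2` (the doubled DP value), `tree`
#'   (a `phylo`), and `table` (per-cluster DP scores).
#' @export
dp_solve <- function(space, genetrees) {
  if (inherits(genetrees, "phylo")) genetrees <- list(genetrees)
  labels <- space$labels
  o <- space$outgroup
  nl <- length(labels)
  if (nl > 31L) stop("the dynamic program supports at most 31 taxa")
  glabs <- unique(unlist(lapply(genetrees, `[[`, "tip.label")))
  if (!all(glabs %in% labels))
    stop("gene trees contain leaves outside the search space: ",
         paste(setdiff(glabs, labels), collapse = ", "))
  bits <- as.integer(2^(seq_len(nl) - 1L))
  obit <- bits[match(o, labels)]
  full <- as.integer(sum(bits)) - obit
  X <- sort(unique(c(space$masks, setdiff(bits, obit), full)))
  if (any(bitwAnd(X, obit) != 0L))
    stop("clusters must not contain the outgroup leaf")
  agg <- .qt_aggregate(genetrees, labels)
  sz <- .popcount(X)
  ord <- order(sz, X)
  X <- X[ord]; sz <- sz[ord]
  np <- length(X)
  S <- rep(-Inf, np)
  S[sz == 1L] <- 0
  choice <- integer(np)
  p0 <- rep(3L, nl)
  has_witnesses <- length(space$witnesses) > 0L
  for (i in which(sz >= 2L)) {
    A <- X[i]
    lb <- bitwAnd(A, -A)
    cand <- which(sz < sz[i] & bitwAnd(X, A) == X & bitwAnd(X, lb) != 0L)
    if (!length(cand)) next
    compm <- bitwXor(A, X[cand])
    ci <- match(compm, X)
    ok <- !is.na(ci)
    ok[ok] <- is.finite(S[cand[ok]]) & is.finite(S[ci[ok]])
    cand <- cand[ok]; ci <- ci[ok]
    if (!length(cand)) next
    best <- -Inf
    bestj <- 0L
    bestkey <- NA_integer_
    for (j in seq_along(cand)) {
      a1 <- X[cand[j]]
      a2 <- bitwXor(A, a1)
      p <- p0
      p[bitwAnd(a1, bits) != 0L] <- 1L
      p[bitwAnd(a2, bits) != 0L] <- 2L
      w <- .weight_eval(agg, p)
      val <- S[cand[j]] + S[ci[j]] + w
      if (val > best) {
        best <- val; bestj <- j; bestkey <- .split_key(a1, a2)
      } else if (val == best && bestj > 0L) {
        key <- .split_key(a1, a2)
        if (.lex_less(key, bestkey)) { bestj <- j; bestkey <- key }
      }
    }
    if (bestj > 0L) {
      S[i] <- best
      choice[i] <- X[cand[bestj]]
    }
  }
  fi <- match(full, X)
  if (!is.finite(S[fi])) {
    if (has_witnesses) {
      bad <- X[sz >= 2L & !is.finite(S)][1L]
      stop("cluster {", paste(.mask_to_labels(bad, labels),
                              collapse = ","),
           "} admits no split within X: P1 is violated")
    }
    stop("the search space admits no complete decomposition")
  }
  if (has_witnesses) {
    reach <- !is.finite(S) & sz >= 2L
    if (any(reach)) {
      ## clusters without any decomposition violate P1 for witness-backed
      ## spaces (every witness cluster decomposes along its witness tree)
      bad <- X[reach][1L]
      stop("cluster {", paste(.mask_to_labels(bad, labels),
                              collapse = ","),
           "} admits no split within X: P1 is violated")
    }
  }
  rec <- function(m) {
    if (.popcount(m) == 1L) return(.mask_to_labels(m, labels))
    a1 <- choice[match(m, X)]
    a2 <- bitwXor(m, a1)
    paste0("(", rec(a1), ",", rec(a2), ")")
  }
  a1 <- choice[fi]; a2 <- bitwXor(full, a1)
  txt <- paste0("(", rec(a1), ",", rec(a2), ",", o, ");")
  tree <- parse_newick(txt)
  structure(list(score2 = S[fi], score = S[fi] / 2, tree = tree,
                 labels = labels, outgroup = o,
                 table = data.frame(mask = X, size = sz, score = S)),
            class = "conquart_dp")
}

#' @export
print.conquart_dp <- function(x, ...) {
  cat("Quartet-score DP solution: score =", x$score,
      "(doubled:", x$score2, ")\n")
  cat(write_newick(x$tree), "\n")
  invisible(x)
}

#' Exact dynamic program over the full powerset
#'
#' Runs the cluster DP with X set to every subset of the leaf set minus
#' the outgroup, optionally filtered to clusters compatible with a
#' constraint tree; the result is the global quartet-score optimum over
#' all binary trees (over all constraint-compatible binary trees when a
#' constraint is given). Exponential in the leaf count, hence capped.
#'
#' @param genetrees A list of `phylo` gene trees.
#' @param outgroup Optional designated outgroup leaf.
#' @param constraint Optional `phylo` constraint tree.
#' @param cap Maximum allowed number of taxa (default 10).
#' @return A `conquart_dp` object (see [dp_solve()]).
#' @export
exact_solve <- function(genetrees, outgroup = NULL, constraint = NULL,
                        cap = 10L) {
  if (inherits(genetrees, "phylo")) genetrees <- list(genetrees)
  labels <- sort(unique(c(unlist(lapply(genetrees, `[[`, "tip.label")),
                          if (!is.null(constraint)) constraint$tip.label)))
  n <- length(labels)
  if (n > cap)
    stop("exact mode supports at most ", cap, " taxa (got ", n,
         "); use the restricted search space instead")
  o <- if (is.null(outgroup))
    choose_outgroup(c(genetrees, if (!is.null(constraint)) list(constraint)))
  else outgroup
  bits <- as.integer(2^(seq_len(n) - 1L))
  obit <- bits[match(o, labels)]
  allm <- seq_len(as.integer(2^n - 1L))
  masks <- allm[bitwAnd(allm, obit) == 0L]
  if (!is.null(constraint)) {
    keep <- vapply(masks, function(m)
      is_compatible(.mask_to_labels(m, labels), constraint), logical(1L))
    masks <- masks[keep]
  }
  space <- list(labels = labels, outgroup = o, masks = masks,
                witnesses = NULL, constraint = constraint)
  dp_solve(space, genetrees)
}

#' Constrained species-tree inference
#'
#' The full pipeline: build the constraint-respecting search space X from
#' the gene trees ([build_search_space()]), then maximize the quartet
#' score over it with the cluster DP ([dp_solve()]). Tripartition weights
#' are always computed against the original gene trees, never the
#' completed ones; the returned tree is compatible with the constraint
#' because every cluster of X is.
#'
#' @inheritParams build_search_space
#' @param ... Further arguments passed to [build_search_space()].
#' @return A `conquart_dp` object with two extra fields: `space` (the
#'   search space used) and `X_size`.
#' @export
constrained_infer <- function(genetrees, constraint = NULL, seed = 1L,
                              ...) {
  space <- build_search_space(genetrees, constraint = constraint,
                              seed = seed, ...)
  sol <- dp_solve(space, genetrees)
  sol$space <- space
  sol$X_size <- length(space$masks)
  sol
}
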