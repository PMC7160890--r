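## Synthetic-data generation: a random species tree, coalescent-style
## gene-tree discordance emulated by Poisson-distributed random NNI moves
## calibrated to a target mean normalized RF between species tree and true
## gene trees, and gene-tree estimation error as further NNI perturbation.
## A proper multispecies-coalescent simulator can be substituted behind
## the same contract (any generator returning a species tree and gene
## trees on the same labels).

#' Simulation configuration
#'
#' @param n Number of taxa (at least 5).
#' @param k Number of gene trees.
#' @param discordance Target mean normalized RF between the species tree
#'   and the true gene trees (0 = no discordance; the study conditions
#'   emulate moderate/high/very-high incomplete lineage sorting with
#'   targets around 0.15, 0.34 and 0.69).
#' @param error Target mean normalized RF added by gene-tree estimation
#'   error (applied on top of discordance).
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical trees.
#' @return A list of class `conquart_sim_config`.
#' @export
sim_config <- function(n, k, discordance = 0.34, error = 0.3, seed = 1L) {
  if (n < 5L) stop("at least 5 taxa are required")
  if (k < 1L) stop("at least one gene tree is required")
  structure(list(n = as.integer(n), k = as.integer(k),
                 discordance = discordance, error = error,
                 seed = as.integer(seed)),
            class = "conquart_sim_config")
}

## mean normalized RF produced by Poisson(lambda) NNI moves on `tree`,
## estimated with m draws (uses the current RNG stream)
.mean_nrf_at <- function(tree, lambda, m = 24L) {
  vals <- vapply(seq_len(m), function(i) {
    mv <- stats::rpois(1L, lambda)
    t2 <- if (mv > 0L) phangorn::rNNI(tree, mv) else tree
    fn_fp(t2, tree)$nrf
  }, numeric(1L))
  mean(vals)
}

## calibrate the Poisson NNI rate to hit a target mean normalized RF
.calibrate_nni <- function(tree, target, m = 24L) {
  if (target <= 0) return(0)
  lo <- 0; hi <- 0.5
  while (.mean_nrf_at(tree, hi, m) < target && hi < 16 * length(tree$tip.label))
    hi <- hi * 2
  for (it in seq_len(10L)) {
    mid <- (lo + hi) / 2
    if (.mean_nrf_at(tree, mid, m) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a species tree and discordant gene trees
#'
#' The species tree is a uniformly random binary topology; each gene tree
#' is the species tree perturbed by a Poisson number of random NNI moves
#' (rate calibrated so the mean normalized RF matches the configured
#' discordance), then perturbed again to emulate gene-tree estimation
#' error. Fully reproducible from the configuration.
#'
#' @param config A [sim_config()] object.
#' @return A list with `species` (`phylo`), `genes` (list of `phylo`),
#'   `config`, and the calibrated rates `lambda_discord`, `lambda_error`.
#' @export
simulate_genetrees <- function(config) {
  stopifnot(inherits(config, "conquart_sim_config"))
  set.seed(config$seed)
  labels <- sprintf("s%02d", seq_len(config$n))
  species <- ape::rtopology(config$n, rooted = FALSE, tip.label = labels)
  species$edge.length <- NULL
  lam_d <- .calibrate_nni(species, config$discordance)
  lam_e <- .calibrate_nni(species, config$error)
  genes <- vector("list", config$k)
  for (i in seq_len(config$k)) {
    mv <- stats::rpois(1L, lam_d)
    g <- if (mv > 0L) phangorn::rNNI(species, mv) else species
    me <- stats::rpois(1L, lam_e)
    if (me > 0L) g <- phangorn::rNNI(g, me)
    g$edge.length <- NULL
    genes[[i]] <- g
  }
  list(species = species, genes = genes, config = config,
       lambda_discord = lam_d, lambda_error = lam_e)
}

#' Derive a constraint tree from a source tree
#'
#' `prune` removes `count` uniformly chosen leaves (an induced subtree of
#' the source); `collapse` contracts `count` uniformly chosen internal
#' branches (a contraction of the source); `clade` repeatedly prunes the
#' clade below a random internal node until at least `count` leaves are
#' gone, emulating missing taxa that form clades. Every result is
#' compatible with the source tree.
#'
#' @param tree A `phylo` source tree (typically the true species tree or
#'   an unconstrained estimate).
#' @param mode One of `"prune"`, `"collapse"`, `"clade"`.
#' @param count Number of leaves to remove / branches to collapse.
#' @param seed Integer seed.
#' @return A `phylo` constraint tree.
#' @export
derive_constraint <- function(tree, mode = c("prune", "collapse", "clade"),
                              count, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  nt <- length(tree$tip.label)
  if (mode == "prune") {
    if (count > nt - 4L)
      stop("cannot prune ", count, " of ", nt,
           " leaves and keep an informative tree")
    if (count == 0L) return(tree)
    drop <- sample(tree$tip.label, count)
    return(restrict(tree, setdiff(tree$tip.label, drop)))
  }
  if (mode == "collapse") {
    root <- nt + 1L
    internal <- setdiff((nt + 1L):(nt + tree$Nnode), root)
    if (count > length(internal))
      stop("only ", length(internal), " internal branches are available")
    if (count == 0L) return(tree)
    pick <- sample(internal, count)
    return(collapse_internal_nodes(tree, pick))
  }
  ## clade mode: prune whole clades until enough leaves are gone
  cur <- tree
  removed <- 0L
  while (removed < count) {
    ntc <- length(cur$tip.label)
    if (ntc <= 4L) break
    kids <- .children_list(cur)
    root <- ntc + 1L
    cand <- setdiff((ntc + 1L):(ntc + cur$Nnode), root)
    sizes <- vapply(cand, function(v) {
      length(ape::extract.clade(cur, v)$tip.label)
    }, integer(1L))
    ok <- cand[sizes <= ntc - 4L & sizes <= (count - removed) + 2L]
    if (!length(ok)) ok <- cand[sizes <= ntc - 4L]
    if (!length(ok)) break
    v <- if (length(ok) == 1L) ok else sample(ok, 1L)
    cl <- ape::extract.clade(cur, v)$tip.label
    cur <- restrict(cur, setdiff(cur$tip.label, cl))
    removed <- removed + length(cl)
  }
  cur
}

#' Build hybrid gene trees from a collapsed species tree
#'
#' The species tree's weakly supported branches (support at or below
#' `threshold`) are contracted, and the collapsed tree is completed with
#' respect to each gene tree via [comp()] -- mixing the reliable species
#' tree backbone with per-gene signal. When the species tree carries no
#' support values the tree is used as-is with a warning.
#'
#' @param genetrees A list of `phylo` gene trees.
#' @param species A `phylo` species tree, ideally with support values.
#' @param threshold Support threshold for collapsing.
#' @return A list of hybrid `phylo` trees, one per gene tree.
#' @export
hybridize <- function(genetrees, species, threshold = 0.99) {
  backbone <- if (is.null(species$node.label)) {
    warning("species tree carries no support values; using it uncollapsed")
    species
  } else {
    contract_by_support(species, threshold)
  }
  lapply(genetrees, function(g) comp(backbone, g))
}

#' Run the constrained-vs-unconstrained evaluation harness
#'
#' For each replicate: simulate a species tree and gene trees, run the
#' unconstrained search, derive constraint trees from the true species
#' tree, run the constrained searches, and record the normalized RF to the
#' truth (full tree, and restricted to the leaves absent from the
#' constraint for prune-mode constraints), the quartet score, and the
#' search-space size.
#'
#' @param n,k Taxa and genes per replicate.
#' @param replicates Number of replicates.
#' @param discordance,error Simulation levels (see [sim_config()]).
#' @param modes Constraint modes to evaluate (subset of
#'   `c("none", "prune", "collapse")`; `"none"` is always run).
#' @param count Leaves to prune / branches to collapse per constraint.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param ... Passed to [build_search_space()] via [constrained_infer()].
#' @return A data frame with one row per (replicate, mode).
#' @export
evaluate_constraints <- function(n, k, replicates = 20L,
                                 discordance = 0.34, error = 0.3,
                                 modes = c("none", "prune", "collapse"),
                                 count = NULL, seed = 1L, ...) {
  modes <- union("none", modes)
  if (is.null(count)) count <- floor(n / 2)
  rows <- list()
  for (r in seq_len(replicates)) {
    sim <- simulate_genetrees(sim_config(n, k, discordance, error,
                                         seed = seed + r))
    truth <- sim$species
    for (mode in modes) {
      constraint <- switch(
        mode,
        none = NULL,
        prune = derive_constraint(truth, "prune", count,
                                  seed = seed + 1000L + r),
        collapse = derive_constraint(truth, "collapse",
                                     min(count, truth$Nnode - 1L),
                                     seed = seed + 2000L + r))
      sol <- constrained_infer(sim$genes, constraint = constraint,
                               seed = seed + r, ...)
      if (!is.null(constraint) && !resolves(sol$tree, constraint))
        stop("constraint-compatibility audit failed in replicate ", r)
      nrf <- fn_fp(sol$tree, truth)$nrf
      rem <- NA_real_
      if (mode == "prune") {
        remaining <- setdiff(truth$tip.label, constraint$tip.label)
        if (length(remaining) >= 4L)
          rem <- fn_fp(restrict(sol$tree, remaining),
                       restrict(truth, remaining))$nrf
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, mode = mode,
        constraint_size = if (is.null(constraint)) NA_integer_
                          else length(constraint$tip.label),
        nrf = nrf, nrf_remaining = rem,
        qscore = sol$score, X_size = sol$X_size)
    }
  }
  do.call(rbind, rows)
}
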