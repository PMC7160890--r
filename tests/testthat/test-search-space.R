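test_that("quartet similarity reflects sibling frequencies", {
  g <- parse_newick("((a,b),(c,d));")
  m1 <- quartet_similarity_matrix(list(g))
  expect_gt(m1["a", "b"], m1["a", "c"])
  expect_equal(m1["a", "b"], 1)
  expect_equal(m1["a", "c"], 0)

  mk <- quartet_similarity_matrix(list(g, g, g))
  expect_equal(unclass(mk), unclass(m1), ignore_attr = TRUE)

  ms <- quartet_similarity_matrix(list(star_tree(letters[1:4])))
  off <- ms[upper.tri(ms)]
  expect_true(all(off == off[1]))  # nothing resolved: uniform after imputation
  expect_gt(nrow(attr(ms, "imputed_pairs")), 0)
})

test_that("greedy consensus keeps splits by frequency and compatibility", {
  set.seed(47)
  t <- random_topology(7)
  cons <- greedy_consensus(list(t, t, t), thresholds = c(0, 0.5, 1))
  for (cc in cons) expect_true(same_topology(cc, t))

  t2 <- parse_newick("((a,b),(c,d),e);")
  t3 <- parse_newick("((a,b),(c,e),d);")
  out <- greedy_consensus(list(t2, t2, t3), thresholds = c(0.5, 0.9))
  expect_true(has_split(out[[1]], c("c", "d")))
  expect_false(has_split(out[[2]], c("c", "d")))
  expect_true(has_split(out[[2]], c("a", "b")))

  expect_error(greedy_consensus(list(t2, parse_newick("((a,b),(c,f));"))),
               "one leaf set")
})

test_that("reference-free completion yields complete trees resolving the inputs", {
  set.seed(53)
  labs <- sprintf("s%02d", 1:8)
  full <- random_topology(8, labs)
  genes <- list(full, restrict(full, labs[1:7]), restrict(full, labs[2:8]))
  mat <- quartet_similarity_matrix(genes, labs)
  out <- reference_free_complete(genes, mat)
  expect_true(same_topology(out[[1]], full))  # complete input untouched
  for (i in 2:3) {
    expect_setequal(out[[i]]$tip.label, labs)
    expect_true(resolves(out[[i]], genes[[i]]))
  }
  ## completeness audit on random instances
  for (i in 1:25) {
    gs <- random_gene_set(sample1(6:10), 4, p_incomplete = 0.8)
    m <- quartet_similarity_matrix(gs$genes, gs$labels)
    o <- reference_free_complete(gs$genes, m)
    for (j in seq_along(o)) {
      expect_setequal(o[[j]]$tip.label, gs$labels)
      expect_true(resolves(o[[j]], gs$genes[[j]]))
    }
  }
})

test_that("polytomy resolution returns binary resolutions of the input", {
  set.seed(59)
  labs <- letters[1:6]
  mat <- quartet_similarity_matrix(list(random_topology(6, labs)), labs)
  bin <- random_topology(6, labs)
  expect_identical(resolve_polytomies(bin, mat, rounds = 3), list(bin))

  g <- parse_newick("((a,b),(c,d));")
  m <- quartet_similarity_matrix(list(g))
  res <- resolve_polytomies(star_tree(letters[1:4]), m, rounds = 1)[[1]]
  expect_true(any(vapply(bipartitions(res), setequal, logical(1),
                         c("c", "d"))))

  for (i in 1:25) {
    n <- sample1(6:10)
    labs <- sprintf("s%02d", 1:n)
    gs <- lapply(1:3, function(j) random_topology(n, labs))
    m <- quartet_similarity_matrix(gs, labs)
    base <- collapse_random(random_topology(n, labs), 0.6)
    outs <- resolve_polytomies(base, m, rounds = 3, seed = i)
    for (o in outs) {
      expect_true(is_binary_tree(o))
      expect_true(resolves(o, base))  # contracting new edges recovers input
    }
  }
})

test_that("the search space from identical binary gene trees recovers them", {
  set.seed(61)
  t <- random_topology(8, sprintf("s%02d", 1:8))
  genes <- list(t, t, t, t)
  sp <- build_search_space(genes, seed = 1)
  tm <- conquart:::.all_cluster_masks(t, sp$labels, sp$outgroup)
  expect_true(all(tm %in% sp$masks))
  sol <- dp_solve(sp, genes)
  expect_true(same_topology(sol$tree, t))
})

test_that("built spaces satisfy P1 and P2 on random constrained instances", {
  set.seed(67)
  for (i in 1:30) {
    n <- sample1(8:13)
    gs <- random_gene_set(n, sample1(4:7))
    mode <- sample(c("prune", "collapse", "none"), 1)
    constraint <- if (mode == "none") NULL
      else derive_constraint(gs$species, mode, sample1(2:4), seed = i)
    sp <- build_search_space(gs$genes, constraint = constraint, seed = i)
    expect_true(verify_p1(sp))
    expect_true(verify_p2(sp))
  }
})

test_that("negative controls are caught by the certificates", {
  set.seed(71)
  gs <- random_gene_set(8, 4, p_incomplete = 0)
  constraint <- derive_constraint(gs$species, "prune", 3, seed = 1)
  sp <- build_search_space(gs$genes, constraint = constraint, seed = 1)
  expect_true(verify_p1(sp) && verify_p2(sp))

  ## inject a cluster crossing a constraint split
  spl <- bipartitions(constraint)[[1]]
  crossing <- c(spl[1], setdiff(constraint$tip.label, spl)[1])
  bad2 <- sp
  bad2$masks <- union(bad2$masks,
                      conquart:::.labels_to_mask(crossing, sp$labels))
  expect_false(verify_p2(bad2))

  ## inject an orphan cluster present in no witness tree
  wm <- unique(unlist(lapply(sp$witnesses, conquart:::.all_cluster_masks,
                             labels = sp$labels, o = sp$outgroup)))
  nl <- length(sp$labels)
  orphan <- NULL
  for (m in 3:(2^nl - 1)) {
    if (bitwAnd(m, conquart:::.labels_to_mask(sp$outgroup, sp$labels)) == 0L &&
        conquart:::.popcount(m) >= 2L && !(m %in% wm)) { orphan <- m; break }
  }
  expect_false(is.null(orphan))
  bad1 <- sp
  bad1$masks <- union(bad1$masks, orphan)
  expect_false(verify_p1(bad1))
})

test_that("extra resolution rounds only grow the search space", {
  set.seed(73)
  for (i in 1:5) {
    gs <- random_gene_set(9, 4)
    constraint <- derive_constraint(gs$species, "collapse", 3, seed = i)
    sp2 <- build_search_space(gs$genes, constraint, seed = 5, rounds = 2)
    sp3 <- build_search_space(gs$genes, constraint, seed = 5, rounds = 3)
    expect_true(all(sp2$masks %in% sp3$masks))
  }
})
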