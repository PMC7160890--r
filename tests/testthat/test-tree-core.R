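test_that("newick parsing reflects the written structure", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_s3_class(t1, "phylo")
  expect_setequal(t1$tip.label, c("a", "b", "c", "d"))
  expect_length(bipartitions(t1), 1L)
  expect_equal(bipartitions(t1)[[1]], c("c", "d"))

  t2 <- parse_newick("((a,b,c),d);")
  expect_length(bipartitions(t2), 0L)  # degree-3 polytomy, no internal split

  expect_error(parse_newick("((a,b),(c,d);"), "offset")
  expect_error(parse_newick("((a,b),(a,d));"), "duplicate")
})

test_that("newick round-trip preserves topology and supports", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample1(4:12)
    t <- random_topology(n)
    if (runif(1) < 0.5) t <- collapse_random(t)
    s <- write_newick(t)
    expect_true(same_topology(parse_newick(s), t))
  }
  ts <- parse_newick("((a,b)0.8,((c,d)0.4,e)0.9);")
  rt <- parse_newick(write_newick(ts))
  expect_setequal(stats::na.omit(as.numeric(rt$node.label)),
                  c(0.8, 0.4, 0.9))
})

test_that("restriction induces the subtree and suppresses degree-2 nodes", {
  t <- parse_newick("((a,b),(c,d));")
  r <- restrict(t, c("a", "b", "c"))
  expect_setequal(r$tip.label, c("a", "b", "c"))
  expect_length(bipartitions(r), 0L)

  expect_true(same_topology(restrict(t, t$tip.label), t))

  t2 <- parse_newick("((a,(b,e)),(c,d));")
  r2 <- restrict(t2, c("a", "c", "d"))
  expect_true(same_topology(r2, parse_newick("(a,(c,d));")))

  expect_error(restrict(t, c("x", "y")), "empty")
})

test_that("bipartition counts follow n - 3 for binary trees", {
  expect_length(bipartitions(star_tree(letters[1:4])), 0L)
  cat5 <- parse_newick("(a,(b,(c,(d,e))));")
  expect_length(bipartitions(cat5), 2L)
  set.seed(7)
  for (n in 5:10) {
    t <- random_topology(n)
    expect_length(bipartitions(t), n - 3L)
    tc <- collapse_random(t, 0.5)
    expect_lte(length(bipartitions(tc)), n - 3L)
  }
})

test_that("cluster-tree compatibility follows the one-empty-intersection rule", {
  t <- parse_newick("((a,b),(c,d));")
  expect_true(is_compatible(c("a", "b"), t))
  expect_false(is_compatible(c("a", "c"), t))
  expect_true(is_compatible(c("a", "c"), star_tree(letters[1:4])))

  ## every cluster read off a tree's own bipartitions is compatible with it
  set.seed(11)
  for (i in 1:10) {
    t <- collapse_random(random_topology(sample1(6:10)), 0.3)
    for (A in bipartitions(t)) expect_true(is_compatible(A, t))
  }
})

test_that("fn_fp counts missing and extra branches and is antisymmetric", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")
  expect_equal(fn_fp(t1, t1)[c("fn", "fp")], list(fn = 0L, fp = 0L))
  r <- fn_fp(t1, t2)
  expect_equal(r$fn, 1L); expect_equal(r$fp, 1L); expect_equal(r$nrf, 1)

  set.seed(13)
  t <- random_topology(8)
  expect_equal(fn_fp(star_tree(t$tip.label), t)[c("fn", "fp")],
               list(fn = 5L, fp = 0L))
  for (i in 1:8) {
    a <- collapse_random(random_topology(7), 0.3)
    b <- collapse_random(random_topology(7), 0.3)
    ab <- fn_fp(a, b); ba <- fn_fp(b, a)
    expect_equal(ab$fn, ba$fp)
    expect_equal(ab$fp, ba$fn)
  }
  expect_error(fn_fp(parse_newick("((a,b),x);"), parse_newick("((a,b),y);")),
               "shared leaves")
})

test_that("support-based contraction collapses exactly the weak edges", {
  t <- parse_newick("((a,b)1.0,((c,d)1.0,e)1.0);")
  expect_true(same_topology(contract_by_support(t, 0.99), t))
  t2 <- parse_newick("((a,b)0.5,((c,d)0.5,e)0.5);")
  expect_true(same_topology(contract_by_support(t2, 0.99),
                            star_tree(letters[1:5])))
  t3 <- parse_newick("((a,b)0.3,((c,d)1.0,e)0.95);")
  out <- contract_by_support(t3, 0.95)
  expect_length(bipartitions(out),
                sum(c(0.3, 1.0, 0.95) > 0.95))
  expect_error(contract_by_support(parse_newick("((a,b),(c,d));"), 0.5),
               "support")
})

test_that("quartet score counts shared induced quartets exactly", {
  t <- parse_newick("((a,b),(c,d));")
  expect_equal(quartet_score(t, list(t)), 1)
  expect_equal(quartet_score(t, list(parse_newick("((a,c),(b,d));"))), 0)
  t6 <- parse_newick("(((a,b),c),((d,e),f));")
  expect_equal(quartet_score(t6, list(t6, t6, t6)), 3 * choose(6, 4))
  set.seed(17)
  for (n in 5:9) {
    t <- random_topology(n)
    expect_equal(quartet_score(t, list(t)), choose(n, 4))
  }
  ## unresolved gene-tree quartets contribute nothing
  expect_equal(quartet_score(t, list(star_tree(letters[1:4]))), 0)
})

test_that("LCA index agrees with naive ancestor-set intersection", {
  t <- parse_newick("((a,b),(c,(d,e)));")
  idx <- build_lca_index(t)
  expect_equal(lca(idx, c("a", "a")), match("a", t$tip.label))
  expect_equal(lca(idx, c("a", "d")), length(t$tip.label) + 1L)

  set.seed(19)
  big <- random_topology(50, sprintf("t%02d", 1:50))
  idx <- build_lca_index(big)
  parent <- integer(50 + big$Nnode)
  parent[big$edge[, 2]] <- big$edge[, 1]
  anc <- function(v) { out <- v; while (parent[v] > 0) { v <- parent[v]; out <- c(out, v) }; out }
  for (i in 1:200) {
    ab <- sample(50 + big$Nnode, 2)
    naive <- intersect(anc(ab[1]), anc(ab[2]))[1]
    expect_equal(lca(idx, ab), naive)
  }
  expect_error(lca(idx, c("t01", "zz")), "not in tree")
})
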