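test_that("binary completion recovers the reference when the backbone is induced", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample1(6:8)
    tr <- random_topology(n)
    tb <- restrict(tr, sample(tr$tip.label, sample1(4:(n - 1))))
    out <- brf_plus(tb, tr)
    expect_equal(fn_fp(out, tr)$rf, 0)
    expect_true(resolves(out, tb))
    expect_setequal(out$tip.label, tr$tip.label)
  }
  ## nothing to add: output equals the backbone
  t <- random_topology(6)
  expect_true(same_topology(brf_plus(t, t), t))
  expect_error(brf_plus(parse_newick("((a,b),(c,x));"),
                        parse_newick("((a,b),(c,d));")),
               "complete reference")
})

test_that("binary completion attains the exhaustive binary optimum", {
  set.seed(29)
  for (i in 1:12) {
    n <- sample1(5:7)
    tr <- random_topology(n)
    nb <- sample1(4:(n - 1))
    tb <- random_topology(nb, labels = sample(tr$tip.label, nb))
    o <- oracle_min_rf_completion(tb, tr)
    out <- brf_plus(tb, tr)
    expect_equal(fn_fp(out, tr)$rf, o$min_rf_binary)
    expect_true(resolves(out, tb))
  }
})

test_that("case 1 grafts as a sister, case 2 forms a polytomy", {
  ## case 1: the sibling leaves of the missing subtree are exactly a
  ## backbone cluster, so a new node recovers the reference bipartition
  tb <- parse_newick("((a,b),(c,o));")
  tr <- parse_newick("(((a,b),(x,y)),(c,o));")
  out <- brf_star(tb, tr)
  expect_equal(fn_fp(out, tr)$rf, 0)
  expect_true(same_topology(out, tr))
  expect_true(has_split(out, c("a", "b", "x", "y")))
  expect_true(has_split(out, c("a", "b")))

  ## case 2: no placement can recover the bipartition above the missing
  ## subtree; a sister insertion would add a false-positive branch
  tb2 <- parse_newick("((a,(b,c)),(d,o));")
  tr2 <- parse_newick("(((a,b),(x,y)),(c,(d,o)));")
  out2 <- brf_star(tb2, tr2)
  o2 <- oracle_min_rf_completion(tb2, tr2)
  expect_equal(fn_fp(out2, tr2)$rf, o2$min_rf)
  ## the grafted pair creates a polytomy instead of a new branch
  expect_false(is_binary_tree(out2))
  expect_true(resolves(out2, tb2))
})

test_that("multifurcating-output completion attains the global optimum", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample1(5:7)
    tr <- random_topology(n)
    if (runif(1) < 0.5) tr <- collapse_random(tr, 0.5)
    nb <- sample1(3:(n - 1))
    tb <- random_topology(max(nb, 3), labels = sample(tr$tip.label, max(nb, 3)))
    if (runif(1) < 0.5 && length(tb$tip.label) >= 4)
      tb <- collapse_random(tb, 0.5)
    o <- oracle_min_rf_completion(tb, tr)
    out <- comp(tb, tr)
    expect_equal(fn_fp(out, tr)$rf, o$min_rf)
    expect_true(resolves(out, tb))
  }
})

test_that("the multifurcating output is a contraction preserving FN and FP", {
  set.seed(37)
  for (i in 1:15) {
    n <- sample1(5:8)
    tr <- random_topology(n)
    nb <- sample1(4:(n - 1))
    tb <- random_topology(nb, labels = sample(tr$tip.label, nb))
    plus <- brf_plus(tb, tr)
    star <- brf_star(tb, tr)
    expect_true(all(split_keys_of(star) %in% split_keys_of(plus)))
    pf <- fn_fp(plus, tr); sf <- fn_fp(star, tr)
    expect_equal(sf$fn, pf$fn)
    expect_equal(sf$fp, fn_fp(tb, restrict(tr, tb$tip.label))$fp)
    expect_true(resolves(star, tb))
  }
})

test_that("backbone expansion adds exactly the compatible reference splits", {
  tb <- parse_newick("((a,b),(c,d));")
  expect_true(same_topology(expand_backbone(tb, parse_newick("((a,c),(b,d));")),
                            tb))
  s <- star_tree(letters[1:4])
  r <- parse_newick("((a,b),(c,d));")
  expect_true(same_topology(expand_backbone(s, r), r))
  ## a polytomy whose reference resolution conflicts with an existing
  ## backbone split stays unresolved
  tb2 <- parse_newick("((a,b),c,d,e);")
  r2 <- parse_newick("(((a,c),b),(d,e));")  # {a,c} crosses {a,b}
  out2 <- expand_backbone(tb2, r2)
  expect_true(resolves(out2, tb2))
  expect_false(has_split(out2, c("a", "c")))
  expect_true(has_split(out2, c("d", "e")))
})

test_that("comp is an identity on itself and groups reference polytomies", {
  set.seed(41)
  t <- random_topology(7)
  expect_true(same_topology(comp(t, t), t))
  tc <- collapse_random(t, 0.5)
  expect_true(same_topology(comp(tc, tc), tc))

  ## two fully-missing subtrees under one reference polytomy attach as a
  ## single polytomy at the same backbone position
  tb <- parse_newick("((a,b),(c,o));")
  tr <- parse_newick("((x,y,(w,z),(a,b)),(c,o));")
  out <- comp(tb, tr)
  o <- oracle_min_rf_completion(tb, tr)
  expect_equal(fn_fp(out, tr)$rf, o$min_rf)
  expect_true(has_split(out, c("a", "b", "w", "x", "y", "z")))
})

test_that("comp stays compatible with the backbone on random pairs", {
  set.seed(43)
  for (i in 1:40) {
    n <- sample1(6:12)
    labs <- sprintf("s%02d", seq_len(n))
    tr <- collapse_random(random_topology(n, labs), 0.3)
    nb <- sample1(4:(n - 1))
    tb <- collapse_random(random_topology(nb, sample(labs, nb)), 0.3)
    out <- comp(tb, tr)
    expect_true(resolves(out, tb))
    expect_setequal(out$tip.label, union(tb$tip.label, tr$tip.label))
  }
})

test_that("completion degenerates gracefully with under 3 shared leaves", {
  tb <- parse_newick("((a,b),(c,o));")
  tr <- parse_newick("((x,y),(z,o));")
  out <- comp(tb, tr)
  expect_setequal(out$tip.label, c("a", "b", "c", "o", "x", "y", "z"))
  expect_true(resolves(out, tb))
  expect_true(resolves(out, tr))
  expect_error(comp(parse_newick("((a,b),c);"), parse_newick("((x,y),z);")),
               "no leaf")
})
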