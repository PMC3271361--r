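test_that("node matching: exact clades and MRCAs", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  q_ab <- node_query("ab", c("A", "B"))
  v <- match_node(tr, q_ab)
  expect_setequal(ape::extract.clade(tr, v)$tip.label, c("A", "B"))

  q_ac <- node_query("ac", c("A", "C"))
  expect_true(is.na(match_node(tr, q_ac)))
  expect_equal(
    match_node(tr, node_query("ac", c("A", "C"), mode = "mrca")),
    ape::Ntip(tr) + 1L
  )
  expect_error(match_node(tr, node_query("z", c("A", "Z"))), "missing")
  expect_error(match_node(tr, node_query("all", c("A", "B", "C", "D"))), "strict subset")
})

test_that("matching is invariant to internal-label noise and edge order", {
  a <- parse_newick("((A:1,B:1)0.93:1,(C:1,D:1)0.99:1);")
  b <- parse_newick("((D:1,C:1):1,(B:1,A:1):1);")
  q <- node_query("ab", c("A", "B"))
  va <- match_node(a, q)
  vb <- match_node(b, q)
  expect_setequal(ape::extract.clade(a, va)$tip.label, c("A", "B"))
  expect_setequal(ape::extract.clade(b, vb)$tip.label, c("A", "B"))
})

test_that("absent fraction reflects constructed clade frequencies exactly", {
  with_clade <- parse_newick("(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  without <- parse_newick("(((A:1,D:1):1,(B:1,C:1):1):1,E:1);")
  trees <- structure(
    c(rep(list(with_clade), 6), rep(list(without), 4)),
    class = "multiPhylo"
  )
  st <- tibble::tibble(taxon = LETTERS[1:5], state = c(1, 1, 1, 0, 0))
  q <- node_query("abc", c("A", "B", "C"))
  mp <- summarize_mp(trees, st, q)
  expect_equal(mp$absent_frac, 0.4)
  expect_equal(mp$n_matched, 6L)
  ml <- summarize_ml(trees, st, q, rates = rate_model(1, 1))
  expect_equal(ml$absent_frac, 0.4)
  # absent + matched fractions account for every tree
  expect_equal(ml$n_matched + 0.4 * 10, 10)
})

test_that("ML summary over identical trees equals the single-tree reconstruction", {
  set.seed(31)
  tr <- simulate_yule(12, depth = 0.8)
  st <- simulate_character(tr, rate_model(1.5, 1.5))$states
  q <- node_query("root2", ape::extract.clade(tr, 15)$tip.label)
  trees <- structure(rep(list(tr), 5), class = "multiPhylo")
  fixed <- rate_model(1.2, 0.6)
  s <- summarize_ml(trees, st, q, rates = fixed)
  rec <- marginal_asr(tr, st, fixed)
  v <- match_node(tr, q)
  expect_equal(s$mean_p1, rec$nodes$p1[v])
  expect_equal(s$absent_frac, 0)
  # estimate-per-tree over identical trees equals the fixed single-tree fit
  est <- summarize_ml(trees, st, q, rates = "estimate")
  fit <- fit_mk(tr, st, kind = "AsymmMk")
  rec_fit <- marginal_asr(tr, st, fit$model)
  expect_equal(est$mean_p1, rec_fit$nodes$p1[v], tolerance = 1e-6)
})

test_that("two-tree means are arithmetic averages of per-tree marginals", {
  set.seed(32)
  t1 <- simulate_yule(8, depth = 0.8)
  t2 <- prune_taxa(simulate_yule(9, depth = 0.8), "t9")
  t2$tip.label <- t1$tip.label
  st <- tibble::tibble(
    taxon = t1$tip.label, state = sample(c(0L, 1L), 8, replace = TRUE)
  )
  q <- node_query("deep", t1$tip.label[1:3], mode = "mrca")
  m <- rate_model(0.9, 1.7)
  trees <- structure(list(t1, t2), class = "multiPhylo")
  s <- summarize_ml(trees, st, q, rates = m)
  p1 <- vapply(list(t1, t2), function(tr) {
    marginal_asr(tr, st, m)$nodes$p1[match_node(tr, q)]
  }, numeric(1))
  expect_equal(s$mean_p1, mean(p1))
})

test_that("swapping the rates and relabeling the states are equivalent", {
  # under (fw, bw) with states s, state-1 probabilities equal the state-0
  # probabilities under (bw, fw) with the states flipped -- an exact
  # symmetry of the model, checked on the fixed rate grid F1 vs F2
  ds <- simulate_study(seed = 13, k_trees = 30)
  flipped <- ds$states
  flipped$state <- 1L - flipped$state
  s1 <- summarize_ml(ds$trees, ds$states, ds$queries, rates = "F1")
  s2 <- summarize_ml(ds$trees, flipped, ds$queries, rates = "F2")
  expect_equal(s1$mean_p1, s2$mean_p0, tolerance = 1e-9)
  expect_equal(s1$absent_frac, s2$absent_frac)
})

test_that("MP fractions partition the sample", {
  # equivocal cherry in every tree
  cherry <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  st <- tibble::tibble(taxon = c("A", "B", "C", "D"), state = c(0, 1, 0, 1))
  trees <- structure(rep(list(cherry), 10), class = "multiPhylo")
  q <- node_query("ab", c("A", "B"))
  mp <- summarize_mp(trees, st, q)
  expect_equal(mp$equivocal_frac, 1)

  # uniquely-best node in every tree
  st2 <- tibble::tibble(taxon = c("A", "B", "C", "D"), state = c(1, 1, 0, 0))
  mpA <- summarize_mp(trees, st2, q)
  expect_equal(mpA$unique1_frac, 1)

  # 30/70 mixture of trees where the query clade is equivocal vs absent
  noclade <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  mix <- structure(
    c(rep(list(cherry), 3), rep(list(noclade), 7)),
    class = "multiPhylo"
  )
  mpB <- summarize_mp(mix, st, q)
  expect_equal(mpB$equivocal_frac, 0.3)
  expect_equal(mpB$absent_frac, 0.7)
  for (s in list(mp, mpA, mpB)) {
    expect_equal(
      s$absent_frac + s$unique0_frac + s$unique1_frac + s$equivocal_frac, 1
    )
  }
})
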