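test_that("transition probabilities: identity at t = 0, stationary limit, stochastic rows", {
  m <- rate_model(1.3, 0.4)
  expect_equal(transition_prob(m, 0), diag(2), ignore_attr = TRUE)
  sym <- rate_model(2, 2)
  expect_equal(
    unname(transition_prob(sym, 1e6)),
    matrix(0.5, 2, 2),
    tolerance = 1e-12
  )
  asym <- rate_model(3, 1)
  limit <- transition_prob(asym, 1e6)
  expect_equal(unname(limit[1, ]), unname(stationary_dist(asym)), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:200) {
    mm <- rate_model(runif(1, 1e-3, 50), runif(1, 1e-3, 50))
    expect_equal(rowSums(transition_prob(mm, runif(1, 0, 10))), c("0" = 1, "1" = 1))
  }
  expect_error(transition_prob(m, -0.1), "non-negative")
})

test_that("transition probabilities match the matrix-exponential oracle", {
  m <- rate_model(1.62, 2.99)
  Q <- matrix(c(-1.62, 1.62, 2.99, -2.99), 2, 2, byrow = TRUE)
  expect_lt(
    max(abs(transition_prob(m, 0.1) - as.matrix(Matrix::expm(Q * 0.1)))),
    1e-10
  )
})

test_that("single-tip and two-tip likelihoods match closed forms", {
  tip1 <- structure(
    list(
      edge = matrix(c(2L, 1L), 1, 2), edge.length = 0.7,
      tip.label = "A", Nnode = 1L
    ),
    class = "phylo"
  )
  m <- rate_model(1.5, 0.8)
  expect_equal(
    mk_loglik(tip1, tibble::tibble(taxon = "A", state = 1), m),
    log(1.5 / (1.5 + 0.8))
  )
  # two tips: ln sum_s pi_s P_s0(t1) P_s1(t2)
  t1 <- 0.3
  t2 <- 0.9
  tr <- parse_newick(sprintf("(A:%f,B:%f);", t1, t2))
  pi <- stationary_dist(m)
  P1 <- transition_prob(m, t1)
  P2 <- transition_prob(m, t2)
  expect_equal(
    mk_loglik(tr, tibble::tibble(taxon = c("A", "B"), state = c(0, 1)), m),
    log(pi[1] * P1[1, 1] * P2[1, 2] + pi[2] * P1[2, 1] * P2[2, 2]),
    ignore_attr = TRUE
  )
})

test_that("likelihood input contracts are enforced", {
  tr <- parse_newick("((A,B),C);")
  st <- tibble::tibble(taxon = c("A", "B", "C"), state = c(0, 1, 1))
  expect_error(mk_loglik(tr, st, rate_model(1, 1)), "branch length")
  tr2 <- parse_newick("((A:1,B:1):1,C:1);")
  expect_error(
    mk_loglik(tr2, tibble::tibble(taxon = c("A", "B", "C"), state = NA), rate_model(1, 1)),
    "no non-missing"
  )
  # zero-length branches are legal (identity transition)
  tr0 <- parse_newick("((A:0,B:1):1,C:1);")
  expect_true(is.finite(mk_loglik(tr0, st, rate_model(1, 2))))
})

test_that("marginal reconstruction: observed tips, symmetry, Bayes at the root", {
  m <- rate_model(1, 1, kind = "MK1")
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  st <- tibble::tibble(taxon = c("A", "B", "C", "D"), state = c(0, 1, 1, 0))
  rec <- marginal_asr(tr, st, m)
  tips <- rec$nodes[rec$nodes$type == "tip", ]
  expect_equal(tips$p1, c(0, 1, 1, 0))
  # mirror-symmetric data under MK1: central node equivocal
  root <- ape::Ntip(tr) + 1L
  expect_equal(rec$nodes$p1[root], 0.5, tolerance = 1e-12)
  expect_equal(rec$nodes$p0 + rec$nodes$p1, rep(1, nrow(rec$nodes)))
})

test_that("likelihood and marginals match exhaustive enumeration", {
  set.seed(404)
  for (i in 1:30) {
    inst <- rand_instance(sample(4:7, 1), p_missing = 0.1, p_polytomy = 0.2)
    fw <- runif(1, 0.2, 4)
    bw <- runif(1, 0.2, 4)
    m <- rate_model(fw, bw)
    expect_equal(
      mk_loglik(inst$tree, inst$states, m),
      brute_loglik(inst$tree, inst$sv, fw, bw),
      tolerance = 1e-9
    )
    rec <- marginal_asr(inst$tree, inst$states, m)
    node <- sample((ape::Ntip(inst$tree) + 1L):nrow(rec$nodes), 1)
    expect_equal(
      rec$nodes$p1[node],
      brute_marginal_p1(inst$tree, inst$sv, fw, bw, node),
      tolerance = 1e-9
    )
  }
})

test_that("likelihood is invariant to re-rooting with the equilibrium prior", {
  skip_if_not_installed("phytools")
  set.seed(55)
  tr <- simulate_yule(12, depth = 1)
  st <- tibble::tibble(
    taxon = tr$tip.label, state = sample(c(0L, 1L), 12, replace = TRUE)
  )
  m <- rate_model(0.8, 2.1)
  base <- mk_loglik(tr, st, m)
  for (i in 1:8) {
    node <- sample(setdiff(14:(12 + tr$Nnode), 13), 1)
    edge_len <- tr$edge.length[which(tr$edge[, 2] == node)]
    pos <- runif(1, 0, edge_len)
    rr <- phytools::reroot(tr, node, position = pos)
    expect_equal(mk_loglik(rr, st, m), base, tolerance = 1e-9)
  }
})

test_that("root probability responds monotonically to the rate ratio", {
  # balanced star data: as fw/(fw+bw) grows, gains become easy and losses
  # rare, so the root is increasingly inferred unicellular (the observed
  # state-1 tips are cheaply explained by repeated gains, while state-0
  # tips would each require a rare loss from a multicellular root); p1 at
  # the root is therefore strictly decreasing in fw/(fw+bw)
  star <- parse_newick("(A:0.5,B:0.5,C:0.5,D:0.5,E:0.5,F:0.5);")
  st <- tibble::tibble(
    taxon = LETTERS[1:6], state = c(0, 0, 0, 1, 1, 1)
  )
  ratios <- seq(0.1, 0.9, by = 0.1)
  p1 <- vapply(ratios, function(r) {
    m <- rate_model(2 * r, 2 * (1 - r))
    rec <- marginal_asr(star, st, m)
    rec$nodes$p1[rec$nodes$type == "internal"]
  }, numeric(1))
  expect_true(all(diff(p1) < 0))
  # symmetry: at fw = bw the balanced root is exactly equivocal
  expect_equal(p1[5], 0.5, tolerance = 1e-12)
})

test_that("ML fitting: nesting, boundary flags and start tie-breaks", {
  set.seed(606)
  tr <- simulate_yule(24, depth = 1)
  st <- simulate_character(tr, rate_model(1, 2))$states
  f2 <- fit_mk(tr, st, kind = "AsymmMk")
  f1 <- fit_mk(tr, st, kind = "MK1")
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_equal(f1$model$fw, f1$model$bw)

  const <- tibble::tibble(taxon = tr$tip.label, state = 1)
  fc <- fit_mk(tr, const, kind = "MK1")
  expect_true(fc$boundary)
  expect_lt(fc$model$fw, 1e-6)
})

test_that("rate grid and token resolution", {
  g <- rate_grid()
  expect_equal(nrow(g), 6L)
  expect_equal(g$fw, c(0.90, 2.70, 5.40, 0.45, 0.90, 2.70))
  expect_equal(g$bw, c(2.70, 0.90, 0.45, 5.40, 0.90, 2.70))
  f3 <- resolve_rates("F3")
  expect_equal(c(f3$fw, f3$bw), c(5.40, 0.45))
  expect_equal(resolve_rates("F5")$kind, "MK1")
  expect_identical(resolve_rates("estimate"), "estimate")
  lit <- resolve_rates("1.5:0.25")
  expect_equal(c(lit$fw, lit$bw), c(1.5, 0.25))
  expect_error(resolve_rates("F9"), "unknown")
  expect_error(resolve_rates("fast"), "unknown")
})
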