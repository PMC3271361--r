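test_that("Yule trees have the requested size, shape and depth", {
  set.seed(10)
  tr <- simulate_yule(3, birth = 1)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)
  d <- ape::node.depth.edgelength(tr)[1:3]
  expect_lt(diff(range(d)), 1e-9) # ultrametric
  for (i in 1:10) {
    n <- sample(4:50, 1)
    tr <- simulate_yule(n, birth = runif(1, 0.5, 3), depth = 2.5)
    expect_equal(ape::Ntip(tr), n)
    d <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_true(all(abs(d - 2.5) < 1e-9)) # rescale contract
  }
  expect_error(simulate_yule(1), "n_tips")
  expect_error(simulate_yule(5, birth = 0), "birth")
})

test_that("Yule waiting times follow the pure-birth expectation", {
  set.seed(11)
  birth <- 2
  n <- 6
  # time of the first split after the root: Exp(2 * birth)
  first_wait <- replicate(800, {
    tr <- simulate_yule(n, birth = birth)
    depths <- ape::node.depth.edgelength(tr)
    tip_depth <- depths[1]
    # earliest non-root internal node time = waiting time from 2 lineages
    min(depths[(n + 2):(2 * n - 1)])
  })
  expect_equal(mean(first_wait), 1 / (2 * birth), tolerance = 0.1)
})

test_that("character simulation is stationary and counts its events", {
  set.seed(12)
  m <- rate_model(1, 3)
  tr <- simulate_yule(10, depth = 1)
  sims <- replicate(2000, simulate_character(tr, m), simplify = FALSE)
  # marginal frequency of state 1 at a fixed tip ~ pi1
  f1 <- mean(vapply(sims, function(s) s$states$state[1], integer(1)))
  pi1 <- stationary_dist(m)[["pi1"]]
  se <- sqrt(pi1 * (1 - pi1) / 2000)
  expect_lt(abs(f1 - pi1), 3 * se)
  # expected number of realized changes = total length * equilibrium flux
  flux <- sum(tr$edge.length) *
    (stationary_dist(m)[["pi0"]] * m$fw + stationary_dist(m)[["pi1"]] * m$bw)
  mean_changes <- mean(vapply(sims, `[[`, integer(1), "n_changes"))
  expect_equal(mean_changes, flux, tolerance = 0.05)
  # endpoint consistency: parent/child flips never exceed realized events
  flips <- vapply(sims, function(s) {
    sum(s$node_states[tr$edge[, 1]] != s$node_states[tr$edge[, 2]])
  }, integer(1))
  expect_true(all(flips <= vapply(sims, `[[`, integer(1), "n_changes")))
})

test_that("an absorbing forward limit freezes the ancestral state", {
  set.seed(13)
  tr <- simulate_yule(12, depth = 1)
  s <- simulate_character(tr, rate_model(1e-8, 5))
  expect_true(all(s$states$state == 0))
})

test_that("tree-sample perturbation degenerates correctly and reports clade frequencies", {
  set.seed(14)
  tr <- simulate_yule(12, depth = 1)
  same <- perturb_tree_sample(tr, 5, nni_intensity = 0, jitter_sd = 0)
  expect_true(all(vapply(same, function(x) {
    identical(write_newick(x), write_newick(tr))
  }, logical(1))))
  expect_true(all(attr(same, "clade_freq")$freq == 1))

  jit <- perturb_tree_sample(tr, 5, nni_intensity = 0, jitter_sd = 0.2)
  expect_true(all(attr(jit, "clade_freq")$freq == 1)) # topology unchanged
  expect_false(identical(jit[[1]]$edge.length, tr$edge.length))

  moved <- perturb_tree_sample(tr, 60, nni_intensity = 3, jitter_sd = 0.1)
  cf <- attr(moved, "clade_freq")
  expect_true(any(cf$freq < 1)) # some clades disrupted
  # clade frequency agrees with the summarizer's absent fraction
  pick <- cf[cf$n_tips > 2 & cf$freq < 1, ]
  if (nrow(pick)) {
    v <- pick$node[1]
    q <- node_query("probe", ape::extract.clade(tr, v)$tip.label)
    st <- tibble::tibble(
      taxon = tr$tip.label, state = rep_len(c(0L, 1L), 12)
    )
    mp <- summarize_mp(moved, st, q)
    expect_equal(1 - mp$absent_frac, pick$freq[1])
  }
})

test_that("the study generator is deterministic and matches its truth record", {
  a <- simulate_study(seed = 99, k_trees = 15)
  b <- simulate_study(seed = 99, k_trees = 15)
  expect_identical(write_newick(a$consensus), write_newick(b$consensus))
  expect_identical(write_newick(a$trees), write_newick(b$trees))
  expect_identical(a$states$state, b$states$state)

  expect_equal(ape::Ntip(a$consensus), 58L)
  expect_equal(sum(a$states$state == 0), 29L)
  expect_equal(sum(a$states$state == 1), 29L)
  expect_equal(fitch_steps(a$consensus, a$states), a$truth$n_changes)
  # planted reversals bound the MPR loss range from below
  rng <- directional_transitions(a$consensus, a$states, "enumerate")
  expect_gte(rng$min_n_loss, 5L)
  expect_gte(rng$max_n_gain, 2L) # gain + regain representable
  # deep nodes exist and are multicellular under parsimony
  mpr <- mpr_state_sets(a$consensus, a$states)
  for (q in a$queries) {
    v <- match_node(a$consensus, q)
    expect_false(is.na(v))
    expect_true(mpr$nodes$set1[v] && !mpr$nodes$set0[v])
  }
})

test_that("generated tree samples survive an io round-trip", {
  ds <- simulate_study(seed = 15, k_trees = 10)
  tmp <- tempfile(fileext = ".nwk")
  write_newick(ds$trees, tmp)
  back <- read_tree_sample(tmp, quiet = TRUE)
  expect_length(back, 10L)
  expect_setequal(back[[1]]$tip.label, ds$consensus$tip.label)
  stf <- tempfile(fileext = ".tsv")
  write_states(ds$states, stf)
  st2 <- read_states(stf, quiet = TRUE)
  expect_equal(st2$state, ds$states$state)
})
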