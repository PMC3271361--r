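test_that("config validation", {
  expect_error(mcmc_config(iterations = 100, burnin = 100), "burnin")
  expect_error(mcmc_config(hyper_bounds = c(5, 1)), "bounds")
})

test_that("prior-only chain recovers the hyperprior and rate priors", {
  tr <- simulate_yule(6, depth = 0.5)
  st <- tibble::tibble(taxon = tr$tip.label, state = c(0, 1, 0, 1, 0, 1))
  s <- suppressWarnings(run_rjmcmc(
    tr, st,
    config = mcmc_config(
      iterations = 2e5, burnin = 2e4, thin = 40,
      likelihood_on = FALSE, seed = 91
    )
  ))
  d <- s$draws
  # m ~ Uniform(0, 10)
  expect_equal(mean(d$m), 5, tolerance = 0.08) # relative tol: +-0.4 absolute
  expect_gt(mean(d$m > 5), 0.45)
  expect_lt(mean(d$m > 5), 0.55)
  # rates are exponential with mean m: fw/m ~ Exp(1)
  z <- d$fw / d$m
  expect_equal(mean(z), 1, tolerance = 0.1)
  expect_equal(mean(z > 1), exp(-1), tolerance = 0.1)
  # chain never leaves its support; both models visited
  expect_true(all(d$fw > 0 & d$bw > 0))
  expect_true(all(d$m > 0 & d$m < 10))
  expect_setequal(unique(d$model), c("MK1", "AsymmMk"))
})

test_that("fixed-model posterior agrees with the ML fit on informative data", {
  set.seed(92)
  tr <- simulate_yule(32, depth = 1)
  chars <- simulate_characters(tr, rate_model(1, 3), 200)
  fit <- fit_mk(tr, chars, kind = "AsymmMk")
  s <- suppressWarnings(run_rjmcmc(
    tr, chars,
    config = mcmc_config(
      iterations = 2e4, burnin = 4e3, thin = 10,
      rj = FALSE, kind = "AsymmMk", seed = 92
    )
  ))
  d <- s$draws
  expect_true(all(d$model == "AsymmMk"))
  expect_lt(abs(mean(d$fw) - fit$model$fw), 3 * stats::sd(d$fw))
  expect_lt(abs(mean(d$bw) - fit$model$bw), 3 * stats::sd(d$bw))
})

test_that("symmetric data yield near-equal posterior mean rates under rj", {
  set.seed(93)
  tr <- simulate_yule(32, depth = 1)
  chars <- simulate_characters(tr, rate_model(2, 2), 100)
  s <- suppressWarnings(run_rjmcmc(
    tr, chars,
    config = mcmc_config(iterations = 3e4, burnin = 5e3, thin = 10, seed = 93)
  ))
  d <- s$draws
  expect_lt(
    abs(mean(d$fw) - mean(d$bw)),
    0.15 * mean(c(d$fw, d$bw))
  )
  # model-indicator posterior is seed-stable within MC error
  s2 <- suppressWarnings(run_rjmcmc(
    tr, chars,
    config = mcmc_config(iterations = 3e4, burnin = 5e3, thin = 10, seed = 193)
  ))
  expect_lt(
    abs(mean(s$draws$model == "MK1") - mean(s2$draws$model == "MK1")),
    0.2
  )
})

test_that("node posterior summaries and thresholds", {
  fake <- structure(
    list(draws = tibble::tibble(p1_node3 = rep(1, 50))),
    class = "rjmcmc_sample"
  )
  np <- node_posterior(fake, "node3")
  expect_equal(np$mean, 1)
  expect_equal(np$frac_gt_0.9, 1)
  set.seed(9)
  fake <- structure(
    list(draws = tibble::tibble(p1_node3 = runif(4000))),
    class = "rjmcmc_sample"
  )
  np2 <- node_posterior(fake, "node3")
  expect_equal(np2$mean, 0.5, tolerance = 0.05)
  expect_equal(np2$frac_gt_0.75, 0.25, tolerance = 0.1)
  expect_error(node_posterior(fake, "nodeX"), "unknown query")
})

test_that("per-draw node probabilities track the planted deep ancestor", {
  ds <- simulate_study(seed = 21, k_trees = 20)
  q <- list(node_query("node3", ds$queries[[1]]$tips, mode = "mrca"))
  s <- suppressWarnings(run_rjmcmc(
    ds$trees, ds$states, q,
    config = mcmc_config(iterations = 2e4, burnin = 4e3, thin = 20, seed = 7)
  ))
  np <- node_posterior(s, "node3")
  expect_gt(np$frac_gt_0.9, 0.5)
})

test_that("marginal likelihood: analytic single-tip case and BF antisymmetry", {
  tip1 <- structure(
    list(
      edge = matrix(c(2L, 1L), 1, 2), edge.length = 1.0,
      tip.label = "A", Nnode = 1L
    ),
    class = "phylo"
  )
  st <- tibble::tibble(taxon = "A", state = 1)
  # under MK1 the likelihood is the constant 1/2, so lnML = ln 0.5
  m1 <- marginal_likelihood(tip1, st, "MK1", seed = 1, rungs = 8,
                            iters_per_rung = 200, burnin_per_rung = 50)
  expect_equal(m1$lnml, log(0.5), tolerance = 1e-9)
  hm <- marginal_likelihood(tip1, st, "MK1", estimator = "harmonic-mean",
                            seed = 2, iters_per_rung = 200)
  expect_equal(hm$lnml, log(0.5), tolerance = 1e-9)
  expect_false(hm$stable)

  set.seed(3)
  tr <- simulate_yule(6, depth = 0.8)
  sts <- simulate_character(tr, rate_model(1, 1))$states
  a <- marginal_likelihood(tr, sts, "AsymmMk", seed = 4, rungs = 16,
                           iters_per_rung = 500, burnin_per_rung = 100)
  b <- marginal_likelihood(tr, sts, "MK1", seed = 5, rungs = 16,
                           iters_per_rung = 500, burnin_per_rung = 100)
  expect_equal(
    bayes_factor(a, b)$two_ln_bf,
    -bayes_factor(b, a)$two_ln_bf
  )
})
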