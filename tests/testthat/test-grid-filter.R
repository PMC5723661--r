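test_that("grid construction enforces interior, sorted bin centers", {
  g <- make_grid(10, 10, 10)
  expect_equal(g$alpha, (1:10 - 0.5) / 10)
  expect_true(all(g$p > 0 & g$p < 1))
  expect_error(make_grid(m_k = 1), "at least 2")
  expect_error(make_grid(p_values = c(0, 0.5, 1)), "inside")
  expect_error(make_grid(alpha_values = c(0.5, 0.2)), "ascending")
})

test_that("the uniform initial posterior has uniform marginals and unit mass", {
  post <- init_posterior(make_grid(10, 10, 10))
  expect_equal(unname(post$mass[1, 1, 1]), 0.001)
  expect_equal(sum(post$mass), 1, tolerance = 1e-12)
  expect_equal(unname(posterior_marginal(post, "alpha")), rep(0.1, 10))
})

test_that("learning-rate transition mixes a stay kernel with a uniform jump", {
  # k concentrated at 1: pure delta kernel leaves alpha untouched
  g1 <- make_grid(k_values = c(1 - 1e-12, 1 - 1e-13), m_alpha = 5, m_p = 4)
  post <- init_posterior(g1)
  m <- post$mass * 0
  m[, 2, ] <- 1 / (2 * 4)  # alpha point mass at bin 2, uniform over k and p
  post$mass <- m
  out <- transition_alpha(post)
  expect_equal(out$mass, m, tolerance = 1e-10)

  # k concentrated at 0: alpha marginal becomes uniform
  g0 <- make_grid(k_values = c(1e-13, 1e-12), m_alpha = 5, m_p = 4)
  post0 <- init_posterior(g0)
  m0 <- post0$mass * 0
  m0[, 2, ] <- 1 / (2 * 4)
  post0$mass <- m0
  out0 <- transition_alpha(post0)
  expect_equal(unname(posterior_marginal(out0, "alpha")), rep(0.2, 5),
               tolerance = 1e-10)

  # k = 0.5, 5 alpha bins, alpha point mass: stay probability 0.5 + 0.5/5
  gk <- make_grid(k_values = c(0.5, 0.5 + 1e-9), m_alpha = 5, m_p = 4)
  postk <- init_posterior(gk)
  mk <- postk$mass * 0
  mk[, 3, ] <- 1 / (2 * 4)
  postk$mass <- mk
  outk <- transition_alpha(postk)
  expect_equal(unname(posterior_marginal(outk, "alpha"))[3], 0.6,
               tolerance = 1e-9)
  expect_equal(unname(posterior_marginal(outk, "alpha"))[1], 0.1,
               tolerance = 1e-9)
})

test_that("Beta propagation smooths p as the kernel dictates and conserves mass", {
  # alpha = 0.5 gives v = 0, i.e. a uniform Beta(1,1) kernel
  g <- make_grid(m_k = 3, alpha_values = c(0.5, 0.5 + 1e-12), m_p = 8)
  post <- init_posterior(g)
  m <- post$mass * 0
  m[, , 2] <- 1 / (3 * 2)  # point mass in p
  post$mass <- m
  out <- propagate_p(post)
  expect_equal(unname(posterior_marginal(out, "p")), rep(1 / 8, 8),
               tolerance = 1e-10)

  # alpha = 0.25 gives v = 2; from a point mass at p = 0.5 the conditional
  # follows Beta(2, 2) on the grid: symmetric with mode at 0.5
  p_vals <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  g2 <- make_grid(m_k = 2, alpha_values = c(0.25, 0.25 + 1e-12),
                  p_values = p_vals)
  post2 <- init_posterior(g2)
  m2 <- post2$mass * 0
  m2[, , 3] <- 1 / (2 * 2)
  post2$mass <- m2
  out2 <- propagate_p(post2)
  expected <- dbeta(p_vals, 2, 2) / sum(dbeta(p_vals, 2, 2))
  expect_equal(unname(posterior_marginal(out2, "p")), expected,
               tolerance = 1e-10)
  expect_equal(sum(out2$mass), 1, tolerance = 1e-10)
})

test_that("reinforcement-learning drift shifts and re-bins p, conserving mass", {
  p_vals <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  g <- make_grid(m_k = 2, alpha_values = c(0.2, 0.2 + 1e-12),
                 p_values = p_vals)
  post <- init_posterior(g)
  m <- post$mass * 0
  m[, , 3] <- 1 / (2 * 2)  # point mass at p = 0.5
  post$mass <- m
  # alpha = 0.2, o = 1: target 0.5 + 0.2 * 0.5 = 0.6, split between 0.5, 0.7
  out <- rl_drift(post, 1)
  marg <- unname(posterior_marginal(out, "p"))
  expect_equal(marg[3], 0.5, tolerance = 1e-9)
  expect_equal(marg[4], 0.5, tolerance = 1e-9)
  expect_equal(sum(out$mass), 1, tolerance = 1e-10)

  # o equal to p: no shift at all
  g5 <- make_grid(m_k = 2, m_alpha = 3, p_values = p_vals)
  post5 <- init_posterior(g5)
  out5 <- rl_drift(post5, 0)
  # mass can only move toward p = 0 (o = 0 pulls down); smallest alpha ~ small move
  expect_equal(sum(out5$mass), 1, tolerance = 1e-10)

  # alpha -> 0 limit: shift smaller than grid spacing, mass nearly unchanged
  g0 <- make_grid(m_k = 2, alpha_values = c(1e-4, 2e-4), p_values = p_vals)
  post0 <- init_posterior(g0)
  out0 <- rl_drift(post0, 1)
  expect_equal(out0$mass, post0$mass, tolerance = 1e-3)
})

test_that("outcome coding and observation likelihood follow the rule o = 1 iff s = r", {
  expect_identical(outcome_code(1, 1), 1L)
  expect_identical(outcome_code(0, 0), 1L)
  expect_identical(outcome_code(1, 0), 0L)
  expect_identical(outcome_code(0, 1), 0L)
  expect_equal(obs_likelihood(1, 1, 0.7, 0.6), 0.42)
  expect_equal(obs_likelihood(0, 0, 0.7, 0.6), 0.3 * 0.4)
  expect_equal(obs_likelihood(0, 1, 0.7, 0.6), 0.7 * 0.4)
})

test_that("Bayes update sharpens the belief and preserves normalization", {
  g <- test_grid(8)
  post <- init_posterior(g)
  params <- softmax_params(0, 4)
  p_before <- posterior_mean(post, "p")
  for (i in 1:5) {
    post <- bayes_update(post, s = 1, o = 1, params = params)
    p_after <- posterior_mean(post, "p")
    expect_gt(p_after, p_before)
    expect_equal(sum(post$mass), 1, tolerance = 1e-10)
    p_before <- p_after
  }
  # a flat likelihood (s-term constant, o-term injected flat via sp identity
  # and o pattern) cannot change the posterior: check invariance numerically
  # by updating with complementary observations restoring symmetry
  post_u <- init_posterior(g)
  out <- bayes_update(post_u, s = 1, o = 1, sp_identity = TRUE)
  expect_equal(sum(out$mass), 1, tolerance = 1e-10)
})

test_that("prediction error follows the chosen-color convention", {
  expect_equal(prediction_error(1, 1, 0.8), 0.2)
  expect_equal(prediction_error(0, 1, 0.8), 0.8)
  expect_equal(prediction_error(0, 0, 0.5), -0.5)
  expect_equal(prediction_error(c(1, 0), c(1, 0), c(0.8, 0.5)), c(0.2, -0.5))
})

test_that("filter_run matches the brute-force oracle to 1e-12 on a 3x3x3 grid", {
  g <- make_grid(3, 3, 3)
  s <- c(1L, 1L, 0L, 1L, 0L)
  r <- c(1L, 0L, 0L, 1L, 1L)
  for (betas in list(c(-1, 3), NULL)) {
    params <- if (is.null(betas)) NULL else softmax_params(betas[1], betas[2])
    got <- filter_run(toy_run(s, r), params = params, grid = g,
                      sp_identity = is.null(betas))
    want <- oracle_filter(s, r, g$k, g$alpha, g$p,
                          beta1 = betas[1], beta2 = betas[2])
    expect_equal(got$alpha_mean, want$alpha_mean, tolerance = 1e-12)
    expect_equal(got$p_mean, want$p_mean, tolerance = 1e-12)
    expect_equal(got$ps, want$ps, tolerance = 1e-12)
    expect_equal(got$pe, want$pe, tolerance = 1e-12)
    expect_identical(got$o, want$o)
  }
})

test_that("first-trial estimates equal the uniform-prior grid means", {
  g <- test_grid(9)
  tr <- filter_run(toy_run(1, 1), params = softmax_params(0, 1), grid = g)
  expect_equal(tr$alpha_mean[1], mean(g$alpha))
  expect_equal(tr$p_mean[1], mean(g$p))
})

test_that("a consistently confirmed color drives p_mean up monotonically", {
  g <- test_grid(10)
  tr <- filter_run(toy_run(rep(1, 8), rep(1, 8)),
                   params = softmax_params(0, 2), grid = g)
  expect_true(all(diff(tr$p_mean) > 0))
  expect_true(all(tr$p_mean > 0 & tr$p_mean < 1))
  expect_true(all(tr$alpha_mean > 0 & tr$alpha_mean < 1))
  expect_true(all(abs(tr$pe) <= 1))
})

test_that("the learning-rate posterior reacts sharply to an abrupt reversal", {
  # Behaving agents on a 0.8 -> 0.2 reversal schedule: the reversal shows
  # up as an outsized one-step revision of E[alpha] around the change
  # point, well above the typical trial-to-trial movement during the
  # stable stretch. (The direction of the revision is not monotone: the
  # first surprise transiently favors the lagging low-alpha cells before
  # fast-updating cells win again; the vignette discusses this.)
  g <- test_grid(12)
  set.seed(11)
  stats <- replicate(40, {
    sched <- tibble::tibble(
      run = 1, trial = 1:40, condition = "hard",
      p_red_true = rep(c(0.8, 0.2), each = 20),
      s = NA_integer_, r = NA_integer_, o = NA_integer_, responded = NA
    )
    beh <- run_agent(sched, agent_spec("flexible", grid = g))
    a <- filter_run(beh, params = softmax_params(-3.5, 7), grid = g)$alpha_mean
    steps <- abs(diff(a))
    c(shock = max(steps[21:23]), stable = mean(steps[8:19]))
  })
  expect_gt(mean(stats["shock", ]), mean(stats["stable", ]))
})

test_that("posterior stays a probability distribution through a noisy run", {
  g <- test_grid(7)
  set.seed(42)
  post <- init_posterior(g)
  params <- softmax_params(-1, 2)
  for (i in 1:12) {
    post <- transition_alpha(post)
    post <- propagate_p(post)
    post <- rl_drift(post, sample(0:1, 1))
    post <- bayes_update(post, sample(0:1, 1), sample(0:1, 1), params)
    expect_equal(sum(post$mass), 1, tolerance = 1e-10)
    expect_true(all(post$mass >= 0))
  }
})
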