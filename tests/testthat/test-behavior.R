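# Deterministic rule-following agent: repeats after high reward, switches
# after low, on a fabricated trial table with independent random rewards.
rule_agent_table <- function(n, seed, p_repeat_high = 1, p_repeat_low = 0,
                             participant = "x") {
  set.seed(seed)
  r <- stats::rbinom(n, 1, 0.5)
  s <- integer(n)
  s[1] <- 1L
  for (i in 2:n) {
    q <- if (r[i - 1] == 1) p_repeat_high else p_repeat_low
    s[i] <- if (stats::runif(1) < q) s[i - 1] else 1L - s[i - 1]
  }
  tibble::tibble(participant = participant, run = 1L, trial = seq_len(n),
                 condition = rep(c("easy", "hard"), length.out = n),
                 p_red_true = 0.5, s = s, r = r, o = as.integer(s == r),
                 responded = TRUE)
}

test_that("repetition frequencies hit the degenerate extremes correctly", {
  n <- 40
  base <- tibble::tibble(participant = "a", run = 1L, trial = 1:n,
                         condition = rep(c("easy", "hard"), each = n / 2),
                         p_red_true = 0.5,
                         r = rep(c(0L, 1L), n / 2), responded = TRUE)
  alt <- base; alt$s <- rep(c(0L, 1L), n / 2); alt$o <- as.integer(alt$s == alt$r)
  per <- base; per$s <- 1L; per$o <- as.integer(per$s == per$r)

  t_alt <- repetition_table(alt)
  expect_true(all(t_alt$freq[t_alt$prev_reward != "all" & t_alt$n > 0] == 0))
  t_per <- repetition_table(per)
  expect_true(all(t_per$freq[t_per$n > 0] == 1))
  # empty cells flagged as NA with n = 0
  expect_true(all(is.na(t_alt$freq[t_alt$n == 0])))
})

test_that("repetition is computed on within-run consecutive responded pairs only", {
  d <- tibble::tibble(participant = "a", run = c(1L, 1L, 1L, 2L, 2L),
                      trial = c(1L, 2L, 4L, 1L, 2L),  # gap at run 1 trial 3
                      condition = "easy", p_red_true = 0.8,
                      s = c(1L, 1L, 0L, 0L, 0L), r = c(1L, 1L, 0L, 0L, 1L),
                      o = c(1L, 1L, 1L, 1L, 0L), responded = TRUE)
  tab <- repetition_table(d)
  all_row <- tab[tab$prev_reward == "all", ]
  # usable pairs: run1 (1,2) and run2 (1,2); the gapped and cross-run pairs drop
  expect_equal(all_row$n, 2)
  expect_equal(all_row$freq, 1)  # both usable pairs are repeats
})

test_that("a reward-contingent repeater shows the expected repetition split", {
  d <- rule_agent_table(400, seed = 71, p_repeat_high = 0.9, p_repeat_low = 0.1)
  deltas <- repetition_deltas(d)
  expect_gt(deltas$rep_after_high, 0.8)
  expect_lt(deltas$rep_after_low, 0.2)
  expect_gt(deltas$delta_rep, 0.5)
})

test_that("dynamic regression recovers a planted first-order dependence", {
  # +-1 choices with persistence 0.85 have lag-1 autocorrelation 0.7 and no
  # extra lag-2 dependence; both reward sets see the same process
  d <- rule_agent_table(4000, seed = 72, p_repeat_high = 0.85,
                        p_repeat_low = 0.85)
  res <- dynamic_analysis(d)
  expect_equal(nrow(res), 2)
  expect_true(all(abs(res$c_n1 - 0.7) < 0.08))
  expect_true(all(abs(res$c_n2) < 0.08))

  # choices independent of history: both coefficients near zero
  d0 <- rule_agent_table(4000, seed = 73, p_repeat_high = 0.5,
                         p_repeat_low = 0.5)
  res0 <- dynamic_analysis(d0)
  expect_true(all(abs(res0$c_n1) < 0.08))
  expect_true(all(abs(res0$c_n2) < 0.08))

  # repeat-after-high / switch-after-low agent: signed reliance pattern
  d1 <- rule_agent_table(2000, seed = 74, p_repeat_high = 0.9,
                         p_repeat_low = 0.2)
  res1 <- dynamic_analysis(d1)
  expect_gt(res1$c_n1[res1$prev_reward == "high"], 0)
  expect_lt(res1$c_n1[res1$prev_reward == "low"], 0)
})

test_that("dynamic regression OLS matches the normal-equations oracle", {
  d <- rule_agent_table(300, seed = 75, p_repeat_high = 0.8,
                        p_repeat_low = 0.3)
  res <- dynamic_analysis(d)
  # rebuild the design exactly as specified and solve the normal equations
  dd <- d[order(d$run, d$trial), ]
  x <- 2 * dd$s - 1
  idx <- 3:nrow(dd)
  for (lev in c("high", "low")) {
    sel <- idx[(dd$r[idx - 1] == 1) == (lev == "high")]
    zs <- function(v) (v - mean(v)) / stats::sd(v)
    y <- zs(x[sel]); X <- cbind(zs(x[sel - 1]), zs(x[sel - 2]))
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unlist(res[res$prev_reward == lev, c("c_n1", "c_n2")]),
                 c(c_n1 = beta[1], c_n2 = beta[2]), tolerance = 1e-10)
  }
})

test_that("learning-rate/repetition correlation behaves across cohorts", {
  set.seed(76)
  fits <- tibble::tibble(participant = sprintf("p%02d", 1:20),
                         delta_alpha = stats::runif(20, 0, 0.05))
  beh <- tibble::tibble(participant = fits$participant,
                        delta_rep = 5 * fits$delta_alpha +
                          stats::rnorm(20, sd = 0.03))
  res <- alpha_repetition_correlation(fits, beh)
  expect_gt(res$r, 0)
  expect_lt(res$p_value, 0.05)

  # permuted pairing destroys the association
  beh_perm <- beh
  beh_perm$delta_rep <- sample(beh_perm$delta_rep)
  res_p <- alpha_repetition_correlation(fits, beh_perm)
  expect_lt(abs(res_p$r), 0.5)

  # identical agents: zero variance, undefined correlation, flagged
  fits0 <- fits; fits0$delta_alpha <- 0.02
  expect_warning(res0 <- alpha_repetition_correlation(fits0, beh), "variance")
  expect_true(res0$flagged)
  expect_true(is.na(res0$r))

  expect_error(alpha_repetition_correlation(fits[1:2, ], beh[1:2, ]),
               "3 participants")
})

test_that("variance-explained control separates reward-driven from pe-driven repetition", {
  set.seed(77)
  n <- 300
  r <- stats::rbinom(n, 1, 0.5)
  # choices constructed so that repetition is exactly the reward indicator
  s <- integer(n); s[1] <- 1L
  for (i in 2:n) s[i] <- if (r[i - 1] == 1) s[i - 1] else 1L - s[i - 1]
  d <- tibble::tibble(participant = "a", run = 1L, trial = 1:n,
                      condition = "easy", p_red_true = 0.5,
                      s = s, r = r, o = as.integer(s == r), responded = TRUE)
  trace <- tibble::tibble(run = 1L, trial = 1:n,
                          pe = stats::runif(n, -1, 1))
  res <- reward_vs_pe_variance(d, trace)
  expect_gt(res$delta_r2, 0)
  expect_equal(res$r2_reward, 1, tolerance = 1e-10)

  # and the mirror image: repetition driven by the sign of pe
  pe <- stats::runif(n, -1, 1)
  s2 <- integer(n); s2[1] <- 1L
  for (i in 2:n) s2[i] <- if (pe[i - 1] > 0) s2[i - 1] else 1L - s2[i - 1]
  d2 <- d; d2$s <- s2; d2$r <- stats::rbinom(n, 1, 0.5)
  d2$o <- as.integer(d2$s == d2$r)
  trace2 <- tibble::tibble(run = 1L, trial = 1:n, pe = pe)
  res2 <- reward_vs_pe_variance(d2, trace2)
  expect_lt(res2$delta_r2, 0)
})

test_that("accuracy summaries hit the oracle and chance benchmarks", {
  sess <- make_session("p01", seed = 81)
  omni <- sess
  omni$s <- as.integer(omni$p_red_true > 0.5)
  omni$r <- sample_reward(omni$s, omni$p_red_true)
  omni$o <- outcome_code(omni$s, omni$r)
  omni$responded <- TRUE
  acc <- condition_summaries(omni)$accuracy
  expect_true(all(acc$accuracy == 1))

  set.seed(82)
  rnd <- run_agent(sess, agent_spec("random"))
  acc_r <- condition_summaries(rnd)$accuracy
  expect_true(all(abs(acc_r$accuracy - 0.5) < 4 * sqrt(0.25 / 160)))

  post <- condition_summaries(omni)$post_reversal
  expect_setequal(unique(post$trial), c(9, 21, 33))
})

test_that("the 2x2 within-subject ANOVA matches textbook sums of squares", {
  # 4-subject fixture, cells (a1b1, a1b2, a2b1, a2b2) per subject
  y <- c(4, 6, 5, 9,
         3, 5, 6, 8,
         5, 7, 4, 9,
         4, 8, 5, 10)
  d <- data.frame(
    subj = rep(paste0("s", 1:4), each = 4),
    A = rep(rep(c("a1", "a2"), each = 2), 4),
    B = rep(c("b1", "b2"), 8),
    y = y
  )
  got <- anova_2x2_within(d, "y", "subj", "A", "B")

  # textbook oracle: marginal means and interaction sums of squares
  gm <- mean(y)
  m_a <- tapply(d$y, d$A, mean); m_b <- tapply(d$y, d$B, mean)
  m_s <- tapply(d$y, d$subj, mean)
  m_ab <- tapply(d$y, list(d$A, d$B), mean)
  m_as <- tapply(d$y, list(d$A, d$subj), mean)
  m_bs <- tapply(d$y, list(d$B, d$subj), mean)
  m_cell <- tapply(d$y, list(d$A, d$B, d$subj), mean)
  ss_a <- 8 * sum((m_a - gm)^2)
  ss_b <- 8 * sum((m_b - gm)^2)
  ss_ab <- 4 * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  ss_as <- 2 * sum((sweep(sweep(m_as, 1, m_a), 2, m_s) + gm)^2)
  ss_bs <- 2 * sum((sweep(sweep(m_bs, 1, m_b), 2, m_s) + gm)^2)
  resid <- m_cell
  for (a in 1:2) for (b in 1:2) for (s in 1:4) {
    resid[a, b, s] <- m_cell[a, b, s] - m_ab[a, b] - m_as[a, s] - m_bs[b, s] +
      m_a[a] + m_b[b] + m_s[s] - gm
  }
  ss_abs <- sum(resid^2)
  f_a <- (ss_a / 1) / (ss_as / 3)
  f_b <- (ss_b / 1) / (ss_bs / 3)
  f_ab <- (ss_ab / 1) / (ss_abs / 3)

  expect_equal(got$F[got$effect == "A"], f_a, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "B"], f_b, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "A:B"], f_ab, tolerance = 1e-10)
  expect_equal(got$df1, rep(1, 3))
  expect_equal(got$df2, rep(3, 3))
})

test_that("the paired t helper agrees with the closed form", {
  x <- c(4, 6, 5, 9); y <- c(3, 5, 6, 8)
  res <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (stats::sd(d) / sqrt(4))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_manual), 3), tolerance = 1e-12)
})
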