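# Reward schedules: per-trial probability that choosing red yields the high
# reward. The green probability is always its complement, so chance level of
# high reward is 50% for an indifferent chooser.

.run_length <- 40L
.hard_blocks <- c(0.2, 0.4, 0.6, 0.8, 0.6, 0.4, 0.2, 0.4, 0.6, 0.8)
.variants <- c("easy-0.2", "easy-0.8", "hard-ascending", "hard-descending")

#' Build one run's reward schedule
#'
#' Easy runs hold the red high-reward probability fixed at 0.2 or 0.8 for
#' all 40 trials. Hard runs step it every 4 trials through
#' 0.2, 0.4, 0.6, 0.8, 0.6, 0.4, 0.2, 0.4, 0.6, 0.8 (ascending variant) or
#' the reverse block order (descending variant), so the identity of the more
#' rewarding color reverses mid-run.
#'
#' @param condition `"easy"` or `"hard"`.
#' @param variant one of `"easy-0.2"`, `"easy-0.8"`, `"hard-ascending"`,
#'   `"hard-descending"`; must be compatible with `condition`.
#' @return A `run_schedule`: list with `condition`, `variant` and `p_red`
#'   (length-40 probability vector).
#' @export
#' @examples
#' make_schedule("hard", "hard-ascending")$p_red[1:8]
make_schedule <- function(condition = c("easy", "hard"), variant) {
  condition <- match.arg(condition)
  if (!variant %in% .variants) {
    stop("unknown variant: ", variant, call. = FALSE)
  }
  if (!startsWith(variant, condition)) {
    stop("variant ", variant, " incompatible with condition ", condition,
         call. = FALSE)
  }
  p_red <- switch(variant,
    "easy-0.2" = rep(0.2, .run_length),
    "easy-0.8" = rep(0.8, .run_length),
    "hard-ascending" = rep(.hard_blocks, each = 4L),
    "hard-descending" = rep(rev(.hard_blocks), each = 4L)
  )
  structure(list(condition = condition, variant = variant, p_red = p_red),
            class = "run_schedule")
}

# Inter-event jitters: truncated discrete geometric over {4, 4.5, 5, 5.5} s.
.sample_jitter <- function(n, decay = 0.5) {
  steps <- c(4, 4.5, 5, 5.5)
  pr <- decay^(0:3)
  sample(steps, n, replace = TRUE, prob = pr / sum(pr))
}

#' Build a counterbalanced 8-run session (schedules and onsets only)
#'
#' The default counterbalancing uses two runs of each schedule variant
#' (easy-0.2, easy-0.8, hard-ascending, hard-descending) in a seeded random
#' order, which makes the session-wide mean of the red high-reward
#' probability exactly 0.5. Event onsets are generated with exponentially
#' jittered (truncated discrete geometric over 4--5.5 s in 0.5 s steps)
#' pre-choice and inter-trial intervals and a 1 s feedback display.
#' Choices, rewards and outcomes are left `NA` until an agent is run with
#' [run_agent()].
#'
#' @param participant participant identifier string.
#' @param seed integer seed controlling run order, jitters and response
#'   times; `NULL` uses the current RNG state.
#' @param order_policy `"balanced"` (seeded permutation of the default
#'   variant multiset) or `"as-given"` (use `variants` in order).
#' @param variants optional character vector of 8 schedule variants
#'   overriding the default multiset.
#' @param jitter_decay decay parameter of the jitter distribution.
#' @return A tibble with 320 rows and columns `participant`, `run`, `trial`,
#'   `condition`, `variant`, `p_red_true`, `s`, `r`, `o`, `responded`,
#'   `onset_cue`, `onset_feedback`, `onset_response` (seconds within run).
#' @export
make_session <- function(participant = "p01", seed = NULL,
                         order_policy = c("balanced", "as-given"),
                         variants = NULL, jitter_decay = 0.5) {
  order_policy <- match.arg(order_policy)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(variants)) {
    variants <- rep(.variants, each = 2L)
  }
  if (length(variants) != 8L) stop("a session needs 8 runs", call. = FALSE)
  if (order_policy == "balanced") variants <- sample(variants)

  runs <- lapply(seq_along(variants), function(i) {
    v <- variants[i]
    cond <- if (startsWith(v, "easy")) "easy" else "hard"
    sched <- make_schedule(cond, v)
    n <- .run_length
    pre <- .sample_jitter(n, jitter_decay)   # cue display interval
    iti <- .sample_jitter(n, jitter_decay)   # post-feedback interval
    rt <- stats::runif(n, 0.3, 1.3)          # response latency within cue interval
    onset_cue <- numeric(n)
    for (t in seq_len(n)[-1]) {
      onset_cue[t] <- onset_cue[t - 1] + pre[t - 1] + 1 + iti[t - 1]
    }
    tibble::tibble(
      participant = participant,
      run = i,
      trial = seq_len(n),
      condition = cond,
      variant = v,
      p_red_true = sched$p_red,
      s = NA_integer_, r = NA_integer_, o = NA_integer_,
      responded = NA,
      onset_cue = onset_cue,
      onset_feedback = onset_cue + pre,
      onset_response = onset_cue + rt
    )
  })
  dplyr::bind_rows(runs)
}

#' Sample a binary reward for a choice
#'
#' Red (`s = 1`) yields the high reward with probability `p_red_true`;
#' green with the complementary probability, so the two probabilities always
#' sum to 1.
#'
#' @param s choice code(s), 0 = green, 1 = red.
#' @param p_red_true per-trial probability that red yields high reward.
#' @return Integer reward code(s), 1 = high (5 points), 0 = low (1 point).
#' @export
sample_reward <- function(s, p_red_true) {
  stopifnot(all(s %in% c(0, 1)), all(p_red_true >= 0 & p_red_true <= 1))
  p_win <- ifelse(s == 1, p_red_true, 1 - p_red_true)
  stats::rbinom(length(p_win), 1L, p_win)
}

#' Specify a simulated agent
#'
#' Three policies stand in for participants: `"random"` chooses uniformly;
#' `"rl_fixed"` tracks the outcome code with a fixed-rate delta rule and
#' chooses through a softmax; `"flexible"` runs the flexible learning
#' filter online and chooses through a softmax of its reward belief. The
#' flexible agent's learning rate is reward-modulated: after each trial
#' the posterior over alpha is tilted by `exp(reward_mod * (2 r - 1) *
#' alpha)` — up after a high reward, down after a low one — so that high
#' rewards weigh the latest observation more heavily in the next belief
#' update, producing the reward-dependent repetition structure seen in
#' human choice data. A choice-kernel `perseveration` bonus (logits added
#' toward repeating the previous choice, independent of reward) accounts
#' for the overall tendency to repeat; both default to values that
#' reproduce human-like repetition and accuracy patterns on this task.
#'
#' @param policy `"random"`, `"rl_fixed"` or `"flexible"`.
#' @param alpha fixed learning rate in (0, 1) (`rl_fixed` only).
#' @param beta1,beta2 softmax intercept and slope.
#' @param reward_mod strength of the reward tilt on the alpha posterior
#'   (`flexible` only; 0 disables).
#' @param perseveration choice-kernel strength in logits (`flexible`
#'   only; 0 disables).
#' @param reward_stick reward-asymmetric component of the choice kernel:
#'   the kernel strength becomes `perseveration + reward_stick / 2` after
#'   a high reward and `perseveration - reward_stick / 2` after a low one,
#'   giving agents individually different reward modulation of choice
#'   repetition (`flexible` only; 0 disables).
#' @param grid filter grid (`flexible` only).
#' @return An `agent_spec` list.
#' @export
agent_spec <- function(policy = c("random", "rl_fixed", "flexible"),
                       alpha = 0.3, beta1 = -3.5, beta2 = 7,
                       reward_mod = 2, perseveration = 1.2,
                       reward_stick = 0,
                       grid = make_grid()) {
  policy <- match.arg(policy)
  if (policy == "rl_fixed" && (alpha <= 0 || alpha >= 1)) {
    stop("learning rate must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(beta1) || !is.finite(beta2)) {
    stop("softmax parameters must be finite", call. = FALSE)
  }
  if (reward_mod < 0) stop("reward_mod must be non-negative", call. = FALSE)
  structure(list(policy = policy, alpha = alpha,
                 beta1 = beta1, beta2 = beta2, reward_mod = reward_mod,
                 perseveration = perseveration, reward_stick = reward_stick,
                 grid = grid),
            class = "agent_spec")
}

#' Simulate an agent's choices and rewards on a session
#'
#' Fills the `s`, `r`, `o` and `responded` columns of a [make_session()]
#' table. Flexible agents run the grid filter online: before each choice
#' the learning-rate transition, Beta propagation and outcome-driven drift
#' are applied (skipped before the first responded trial of a run), the
#' choice is sampled from the softmax of the belief E\[p\] (plus any
#' perseveration bonus), the reward is drawn from the schedule, and the
#' observation is folded back into the posterior. Non-responded trials
#' (produced at rate `nonresponse_rate`) carry no codes and are skipped by
#' the agent's own learning, mirroring their exclusion downstream.
#'
#' @param session a [make_session()] table.
#' @param agent an [agent_spec()].
#' @param seed optional integer seed.
#' @param nonresponse_rate probability that a trial goes unanswered
#'   (default 0; the original task reported under 0.3%).
#' @return The session tibble with behavior columns filled.
#' @export
run_agent <- function(session, agent, seed = NULL, nonresponse_rate = 0) {
  stopifnot(inherits(agent, "agent_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (nonresponse_rate < 0 || nonresponse_rate >= 1) {
    stop("nonresponse_rate must be in [0, 1)", call. = FALSE)
  }

  grid <- agent$grid
  kernels <- if (agent$policy == "flexible") .p_kernels(grid)
  drift <- if (agent$policy == "flexible") .drift_kernels(grid)
  params <- softmax_params(agent$beta1, agent$beta2)
  p_ax <- match("p", c("k", "alpha", "p"))

  out <- lapply(split(session, session$run), function(tr) {
    n <- nrow(tr)
    s <- r <- o <- rep(NA_integer_, n)
    responded <- rep(TRUE, n)
    # per-run learner state
    p_state <- 0.5
    mass <- if (agent$policy == "flexible") init_posterior(grid)$mass
    last_o <- NA_integer_
    last_s <- NA_integer_
    last_r <- NA_integer_
    for (i in seq_len(n)) {
      if (nonresponse_rate > 0 && stats::runif(1) < nonresponse_rate) {
        responded[i] <- FALSE
        next
      }
      ps <- switch(agent$policy,
        random = 0.5,
        rl_fixed = stats::plogis(agent$beta1 + agent$beta2 * p_state),
        flexible = {
          if (!is.na(last_o)) {
            mass <- .step_transition_alpha(mass, grid)
            mass <- .step_propagate_p(mass, grid, kernels)
            mass <- .step_rl_drift(mass, grid, drift, last_o)
          }
          p_mean <- sum(apply(mass, p_ax, sum) * grid$p)
          logit <- agent$beta1 + agent$beta2 * p_mean
          if (!is.na(last_s)) {
            # choice kernel: bias toward repeating the previous choice,
            # optionally stronger after a high than a low reward
            kern <- agent$perseveration +
              agent$reward_stick * (last_r - 0.5)
            logit <- logit + kern * (2 * last_s - 1)
          }
          stats::plogis(logit)
        }
      )
      s[i] <- stats::rbinom(1L, 1L, ps)
      r[i] <- sample_reward(s[i], tr$p_red_true[i])
      o[i] <- outcome_code(s[i], r[i])
      if (agent$policy == "rl_fixed") {
        p_state <- p_state + agent$alpha * (o[i] - p_state)
      } else if (agent$policy == "flexible") {
        mass <- .step_bayes(mass, grid, s[i], o[i], params, sp_identity = FALSE)
        if (agent$reward_mod > 0) {
          # reward-modulated learning rate: tilt the alpha posterior up
          # after a high reward and down after a low one
          tilt <- exp(agent$reward_mod * (2 * r[i] - 1) * grid$alpha)
          mass <- .renorm(sweep(mass, 2, tilt, `*`))
        }
      }
      last_o <- o[i]; last_s <- s[i]; last_r <- r[i]
    }
    tr$s <- s; tr$r <- r; tr$o <- o; tr$responded <- responded
    tr
  })
  dplyr::bind_rows(out)
}

# ---- trial table I/O --------------------------------------------------------

.trial_cols <- c("participant", "run", "trial", "condition", "variant",
                 "p_red_true", "s", "r", "o", "responded",
                 "onset_cue", "onset_feedback", "onset_response")

#' Write / read a session trial table as CSV
#'
#' One row per trial with a mandatory header; the round trip is lossless.
#' `read_trials()` validates the schema: all columns present, codes in
#' \{0, 1\} (or missing on non-responded rows), probabilities in \[0, 1\],
#' and the outcome code consistent with `o = 1` iff `s = r`.
#'
#' @param session a session trial table.
#' @param path file path.
#' @return `read_trials()` returns the validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(session, path) {
  missing <- setdiff(.trial_cols, names(session))
  if (length(missing)) {
    stop("session table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(session[, .trial_cols], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(),
    run = readr::col_integer(),
    trial = readr::col_integer(),
    condition = readr::col_character(),
    variant = readr::col_character(),
    p_red_true = readr::col_double(),
    s = readr::col_integer(),
    r = readr::col_integer(),
    o = readr::col_integer(),
    responded = readr::col_logical(),
    onset_cue = readr::col_double(),
    onset_feedback = readr::col_double(),
    onset_response = readr::col_double()
  ))
  missing <- setdiff(.trial_cols, names(x))
  if (length(missing)) {
    stop("trial file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  resp <- !is.na(x$responded) & x$responded
  codes <- c(x$s[resp], x$r[resp], x$o[resp])
  if (anyNA(codes) || !all(codes %in% c(0L, 1L))) {
    stop("choice/reward/outcome codes must be 0 or 1 on responded rows",
         call. = FALSE)
  }
  if (any(x$p_red_true < 0 | x$p_red_true > 1)) {
    stop("p_red_true out of [0, 1]", call. = FALSE)
  }
  if (!all(x$o[resp] == as.integer(x$s[resp] == x$r[resp]))) {
    stop("outcome code inconsistent with choice/reward pair", call. = FALSE)
  }
  x
}

#' Responded trials ready for analysis
#'
#' Drops non-responded trials (which carry no choice, reward or outcome) —
#' the analysis set used by every model and behavioral routine.
#'
#' @param trials a session trial table.
#' @return The filtered tibble.
#' @export
analysis_trials <- function(trials) {
  if ("responded" %in% names(trials)) {
    trials <- trials[is.na(trials$responded) | trials$responded, , drop = FALSE]
  }
  trials[!is.na(trials$s), , drop = FALSE]
}
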