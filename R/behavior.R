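# Behavioral analyses of reward-modulated learning. All routines work on
# responded trials only, never pair trials across run boundaries, and drop
# pairs interrupted by a non-responded trial.

# Consecutive responded trial pairs (prev, cur) within runs, per participant.
.trial_pairs <- function(trials) {
  trials <- analysis_trials(trials)
  trials <- trials[order(trials$participant, trials$run, trials$trial), ]
  same_block <- trials$participant == dplyr::lag(trials$participant) &
    trials$run == dplyr::lag(trials$run) &
    trials$trial == dplyr::lag(trials$trial) + 1
  idx <- which(!is.na(same_block) & same_block)
  tibble::tibble(
    participant = trials$participant[idx],
    run = trials$run[idx],
    trial = trials$trial[idx],
    condition = trials$condition[idx],
    s_prev = trials$s[idx - 1],
    r_prev = trials$r[idx - 1],
    s_cur = trials$s[idx],
    repeated = as.integer(trials$s[idx] == trials$s[idx - 1])
  )
}

#' Choice-repetition frequencies by previous reward and difficulty
#'
#' For every within-run pair of consecutive responded trials, scores
#' whether the color choice was repeated, and aggregates the repetition
#' frequency per participant in each cell of previous reward (high / low)
#' by run difficulty (easy / hard), plus an overall row per participant.
#' The first trial of each run has no predecessor and is excluded. Empty
#' cells yield `NA` frequency with `n = 0`.
#'
#' @param trials a session trial table (one or more participants).
#' @return A tibble: `participant`, `prev_reward` (`"high"`, `"low"` or
#'   `"all"`), `condition` (`"easy"`, `"hard"` or `"all"`), `n`, `freq`.
#' @export
repetition_table <- function(trials) {
  pairs <- .trial_pairs(trials)
  pairs$prev_reward <- ifelse(pairs$r_prev == 1, "high", "low")
  cells <- expand.grid(prev_reward = c("high", "low"),
                       condition = c("easy", "hard"),
                       stringsAsFactors = FALSE)
  out <- lapply(split(pairs, pairs$participant), function(pp) {
    per_cell <- lapply(seq_len(nrow(cells)), function(i) {
      sub <- pp[pp$prev_reward == cells$prev_reward[i] &
                pp$condition == cells$condition[i], ]
      tibble::tibble(participant = pp$participant[1],
                     prev_reward = cells$prev_reward[i],
                     condition = cells$condition[i],
                     n = nrow(sub),
                     freq = if (nrow(sub)) mean(sub$repeated) else NA_real_)
    })
    dplyr::bind_rows(c(per_cell, list(
      tibble::tibble(participant = pp$participant[1],
                     prev_reward = "all", condition = "all",
                     n = nrow(pp), freq = mean(pp$repeated))
    )))
  })
  dplyr::bind_rows(out)
}

#' Per-participant repetition and learning-rate contrasts by previous reward
#'
#' `repetition_deltas()` gives each participant's repetition frequency after
#' high and after low reward (pooled over difficulty) and their difference.
#' `reward_modulated_alpha()` does the same for the model's trial-wise
#' learning-rate estimate: mean E\[alpha\] on trials whose previous trial
#' brought a high vs. a low reward.
#'
#' @param trials a session trial table.
#' @param trace a model trace aligned with `trials` (e.g. from
#'   [filter_session()] or [em_fit()]), with `run`, `trial`, `alpha_mean`.
#' @return A tibble with one row per participant.
#' @export
repetition_deltas <- function(trials) {
  pairs <- .trial_pairs(trials)
  out <- lapply(split(pairs, pairs$participant), function(pp) {
    hi <- pp$repeated[pp$r_prev == 1]
    lo <- pp$repeated[pp$r_prev == 0]
    tibble::tibble(participant = pp$participant[1],
                   rep_after_high = mean(hi), rep_after_low = mean(lo),
                   delta_rep = mean(hi) - mean(lo))
  })
  dplyr::bind_rows(out)
}

#' @rdname repetition_deltas
#' @export
reward_modulated_alpha <- function(trials, trace) {
  trials <- analysis_trials(trials)
  merged <- dplyr::inner_join(
    trials[, c("participant", "run", "trial", "s", "r")],
    trace[, c("run", "trial", "alpha_mean")],
    by = c("run", "trial")
  )
  merged <- merged[order(merged$participant, merged$run, merged$trial), ]
  prev_ok <- merged$participant == dplyr::lag(merged$participant) &
    merged$run == dplyr::lag(merged$run) &
    merged$trial == dplyr::lag(merged$trial) + 1
  idx <- which(!is.na(prev_ok) & prev_ok)
  d <- tibble::tibble(participant = merged$participant[idx],
                      r_prev = merged$r[idx - 1],
                      alpha = merged$alpha_mean[idx])
  out <- lapply(split(d, d$participant), function(pp) {
    hi <- pp$alpha[pp$r_prev == 1]
    lo <- pp$alpha[pp$r_prev == 0]
    tibble::tibble(participant = pp$participant[1],
                   alpha_after_high = mean(hi), alpha_after_low = mean(lo),
                   delta_alpha = mean(hi) - mean(lo))
  })
  dplyr::bind_rows(out)
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Least squares via SVD pseudo-inverse (used when regressors are collinear).
.ols_pinv <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  d_inv <- ifelse(sv$d > tol * max(sv$d), 1 / sv$d, 0)
  drop(sv$v %*% (d_inv * crossprod(sv$u, y)))
}

#' Dynamic choice regression split by previous reward
#'
#' Recodes choices as red = 1, green = -1 and, separately for trials whose
#' previous trial yielded a high vs. a low reward, regresses the normalized
#' current choice on the normalized choices one and two trials back
#' (ordinary least squares, no intercept; all three vectors z-scored within
#' each reward set). Coefficients `c_n1` and `c_n2` measure reliance of the
#' current choice on the recent choice history. Triples spanning run
#' boundaries or interrupted by non-responses are excluded. Collinear
#' regressors fall back to the SVD pseudo-inverse and are flagged.
#'
#' @param trials a session trial table.
#' @return A tibble: `participant`, `prev_reward`, `c_n1`, `c_n2`, `n`,
#'   `flagged`.
#' @export
dynamic_analysis <- function(trials) {
  trials <- analysis_trials(trials)
  trials <- trials[order(trials$participant, trials$run, trials$trial), ]
  ok1 <- trials$participant == dplyr::lag(trials$participant) &
    trials$run == dplyr::lag(trials$run) &
    trials$trial == dplyr::lag(trials$trial) + 1
  ok2 <- dplyr::lag(ok1) & ok1
  idx <- which(!is.na(ok2) & ok2)
  x <- 2 * trials$s - 1
  d <- tibble::tibble(participant = trials$participant[idx],
                      y = x[idx], x1 = x[idx - 1], x2 = x[idx - 2],
                      r_prev = trials$r[idx - 1])
  d$prev_reward <- ifelse(d$r_prev == 1, "high", "low")
  out <- lapply(split(d, list(d$participant, d$prev_reward), drop = TRUE),
                function(set) {
    if (nrow(set) < 3) {
      stop("fewer than 3 usable trials in a reward condition", call. = FALSE)
    }
    y <- .zscore(set$y)
    X <- cbind(.zscore(set$x1), .zscore(set$x2))
    qr_x <- qr(X)
    flagged <- qr_x$rank < 2
    beta <- if (flagged) .ols_pinv(X, y) else qr.coef(qr_x, y)
    tibble::tibble(participant = set$participant[1],
                   prev_reward = set$prev_reward[1],
                   c_n1 = beta[1], c_n2 = beta[2],
                   n = nrow(set), flagged = flagged)
  })
  res <- dplyr::bind_rows(out)
  res[order(res$participant, res$prev_reward), ]
}

#' Correlation between learning-rate and repetition increases
#'
#' Across participants, Pearson correlation between the increase in the
#' learning-rate estimate following high vs. low reward (`delta_alpha`)
#' and the increase in choice-repetition frequency (`delta_rep`).
#'
#' @param cohort_fits tibble with `participant` and `delta_alpha` (see
#'   [reward_modulated_alpha()]).
#' @param cohort_behavior tibble with `participant` and `delta_rep` (see
#'   [repetition_deltas()]).
#' @return A one-row tibble: `r`, `p_value`, `n`, `flagged` (`TRUE` when a
#'   contrast has zero variance and the correlation is undefined).
#' @export
alpha_repetition_correlation <- function(cohort_fits, cohort_behavior) {
  d <- dplyr::inner_join(cohort_fits[, c("participant", "delta_alpha")],
                         cohort_behavior[, c("participant", "delta_rep")],
                         by = "participant")
  if (nrow(d) < 3) stop("need at least 3 participants", call. = FALSE)
  if (stats::sd(d$delta_alpha) < 1e-12 || stats::sd(d$delta_rep) < 1e-12) {
    warning("zero variance across participants: correlation undefined",
            call. = FALSE)
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = nrow(d),
                          flagged = TRUE))
  }
  ct <- stats::cor.test(d$delta_alpha, d$delta_rep, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d),
                 flagged = FALSE)
}

#' Variance in choice repetition explained by reward vs. prediction error
#'
#' Builds the binary repeat-next-trial vector (1 when the next responded
#' consecutive trial repeats the current choice) and compares how much of
#' its variance is explained by the trial's reward magnitude versus by the
#' model's signed prediction error, via two separate univariate linear
#' regressions: `delta_r2 = R2(r) - R2(pe)`.
#'
#' @param trials a session trial table.
#' @param trace an aligned model trace with `run`, `trial`, `pe`.
#' @return A tibble per participant: `r2_reward`, `r2_pe`, `delta_r2`, `n`.
#' @export
reward_vs_pe_variance <- function(trials, trace) {
  trials <- analysis_trials(trials)
  merged <- dplyr::inner_join(
    trials[, c("participant", "run", "trial", "s", "r")],
    trace[, c("run", "trial", "pe")],
    by = c("run", "trial")
  )
  merged <- merged[order(merged$participant, merged$run, merged$trial), ]
  nxt <- merged$participant == dplyr::lead(merged$participant) &
    merged$run == dplyr::lead(merged$run) &
    merged$trial == dplyr::lead(merged$trial) - 1
  idx <- which(!is.na(nxt) & nxt)
  d <- tibble::tibble(participant = merged$participant[idx],
                      y = as.integer(merged$s[idx + 1] == merged$s[idx]),
                      r = merged$r[idx], pe = merged$pe[idx])
  r2 <- function(y, x) {
    if (stats::sd(x) < 1e-12) stop("constant regressor", call. = FALSE)
    fit <- stats::lm.fit(cbind(1, x), y)
    sst <- sum((y - mean(y))^2)
    if (sst < 1e-12) return(0)
    1 - sum(fit$residuals^2) / sst
  }
  out <- lapply(split(d, d$participant), function(pp) {
    tibble::tibble(participant = pp$participant[1],
                   r2_reward = r2(pp$y, pp$r),
                   r2_pe = r2(pp$y, pp$pe),
                   n = nrow(pp))
  })
  res <- dplyr::bind_rows(out)
  res$delta_r2 <- res$r2_reward - res$r2_pe
  res
}

#' Accuracy summaries by condition, run and post-reversal trials
#'
#' "Accuracy" is choosing the per-trial more rewarding color (red when
#' `p_red_true > 0.5`). Returns per-participant accuracy by difficulty,
#' the trial-wise accuracy trajectory per condition, and accuracy at the
#' three hard-run trials (9, 21 and 33) that immediately follow a reversal
#' of the more rewarding color.
#'
#' @param trials a session trial table.
#' @return A list of tibbles: `accuracy`, `trajectory`, `post_reversal`.
#' @export
condition_summaries <- function(trials) {
  trials <- analysis_trials(trials)
  trials$correct <- as.integer(trials$s == as.integer(trials$p_red_true > 0.5))
  acc <- trials |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(accuracy = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop")
  traj <- trials |>
    dplyr::group_by(.data$condition, .data$trial) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  post <- trials[trials$condition == "hard" & trials$trial %in% c(9, 21, 33), ] |>
    dplyr::group_by(.data$participant, .data$trial) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  list(accuracy = acc, trajectory = traj, post_reversal = post)
}

#' Two-by-two within-subject ANOVA
#'
#' Repeated-measures ANOVA on subject-by-cell means for a 2 x 2
#' within-subject design, via `stats::aov()` with an
#' `Error(subject/(A * B))` stratification. Summary plumbing for the
#' behavioral tables, not a general ANOVA engine.
#'
#' @param data data frame of cell means, one row per subject x cell.
#' @param dv,subject,f1,f2 column names (strings) of the response, subject
#'   identifier and the two within-subject factors.
#' @return A tibble: `effect`, `df1`, `df2`, `F`, `p_value`.
#' @export
anova_2x2_within <- function(data, dv, subject, f1, f2) {
  d <- data.frame(y = data[[dv]],
                  subj = factor(data[[subject]]),
                  A = factor(data[[f1]]),
                  B = factor(data[[f2]]))
  fit <- stats::aov(y ~ A * B + Error(subj / (A * B)), data = d)
  sm <- summary(fit)
  rows <- lapply(sm[-1], function(stratum) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab)[1])
    tibble::tibble(effect = eff,
                   df1 = tab$Df[1], df2 = tab$Df[nrow(tab)],
                   F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1])
  })
  out <- dplyr::bind_rows(rows)
  out$effect <- sub("^A$", f1, out$effect)
  out$effect <- sub("^B$", f2, out$effect)
  out$effect <- sub("^A:B$", paste0(f1, ":", f2), out$effect)
  out
}

#' Paired two-tailed t test (tidy wrapper)
#'
#' @param x,y paired measurements.
#' @return A one-row tibble: `estimate`, `t`, `df`, `p_value`.
#' @export
paired_t <- function(x, y) {
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
}
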