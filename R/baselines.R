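# Fixed-rate reinforcement-learning baselines. All three learners track the
# outcome code o (evidence that red is the more rewarding color) with a
# delta rule on the belief p, resetting p = 0.5 at each run start; they
# differ only in the effective learning rate:
#   RL_1  : one rate for the whole session
#   RL_2  : one rate per difficulty condition
#   PE-M  : base rate scaled by the prediction-error magnitude |r - p_chosen|

.baseline_models <- c("RL_1", "RL_2", "PE-M")

#' Baseline learner parameters
#'
#' @param model `"RL_1"`, `"RL_2"` or `"PE-M"`.
#' @param alpha base learning rate(s) in \[0.01, 0.99\]: a single value for
#'   RL_1 / PE-M, or a vector named by difficulty condition (`easy`,
#'   `hard`) for RL_2 — one entry when fitting a single-difficulty fold.
#' @return An `rl_params` list.
#' @export
rl_params <- function(model = c("RL_1", "RL_2", "PE-M"), alpha) {
  model <- match.arg(model)
  if (model == "RL_2") {
    if (is.null(names(alpha)) || !all(names(alpha) %in% c("easy", "hard"))) {
      stop("RL_2 rates must be named by difficulty ('easy'/'hard')", call. = FALSE)
    }
  } else if (length(alpha) != 1) {
    stop(model, " takes a single learning rate", call. = FALSE)
  }
  if (any(alpha < 0.01 - 1e-12) || any(alpha > 0.99 + 1e-12)) {
    stop("learning rate outside the search range [0.01, 0.99]", call. = FALSE)
  }
  structure(list(model = model, alpha = alpha), class = "rl_params")
}

# Per-run belief sequence for one run of responded trials. Returns the
# prediction p_i *before* seeing trial i's outcome.
.rl_run <- function(o, s, r, model, alpha) {
  n <- length(o)
  p <- numeric(n)
  p_cur <- 0.5
  for (i in seq_len(n)) {
    p[i] <- p_cur
    a_eff <- if (model == "PE-M") {
      p_chosen <- if (s[i] == 1) p_cur else 1 - p_cur
      alpha * abs(r[i] - p_chosen)
    } else {
      alpha
    }
    p_cur <- p_cur + a_eff * (o[i] - p_cur)
    # keep the belief strictly interior (long one-sided streaks at high
    # rates would otherwise round onto the boundary)
    p_cur <- min(max(p_cur, 1e-12), 1 - 1e-12)
  }
  p
}

#' Per-trial belief sequence of a baseline learner
#'
#' Runs the delta rule over a trial table (belief reset to 0.5 at every run
#' start; non-responded trials dropped) and returns the prediction made at
#' each trial, i.e. the belief before that trial's outcome is seen.
#'
#' @param trials a session trial table with `run`, `s`, `r` columns.
#' @param params an [rl_params()] object.
#' @return A tibble with `run`, `trial` and the belief `p`.
#' @export
#' @examples
#' tr <- tibble::tibble(run = 1, trial = 1:2, condition = "easy",
#'                      s = c(1L, 1L), r = c(1L, 1L))
#' rl_predict(tr, rl_params("RL_1", 0.5))$p  # 0.5 then 0.75
rl_predict <- function(trials, params) {
  stopifnot(inherits(params, "rl_params"))
  trials <- analysis_trials(trials)
  o <- outcome_code(trials$s, trials$r)
  out <- lapply(split(seq_len(nrow(trials)), trials$run), function(idx) {
    alpha <- if (params$model == "RL_2") {
      params$alpha[[trials$condition[idx[1]]]]
    } else {
      params$alpha
    }
    tibble::tibble(
      run = trials$run[idx],
      trial = trials$trial[idx],
      p = .rl_run(o[idx], trials$s[idx], trials$r[idx], params$model, alpha)
    )
  })
  dplyr::bind_rows(out)
}

#' Exhaustive learning-rate search for a baseline learner
#'
#' Scans the rate grid 0.01, 0.02, ..., 0.99 and, for each candidate,
#' generates the belief sequence, fits the softmax choice model to the
#' observed choices and scores the mean squared error between the fitted
#' choice predictions and the binary choices. Returns the rate minimizing
#' that error variance, ties broken toward the smallest rate. For RL_2 the
#' two difficulty conditions are searched independently (their belief
#' sequences do not interact because the belief resets at run starts).
#'
#' @param trials training trials (one or more complete runs).
#' @param model `"RL_1"`, `"RL_2"` or `"PE-M"`.
#' @param step search grid step (default 0.01).
#' @return An [rl_params()] with the selected rate(s), plus attributes
#'   `sigma_e2` (training error variance at the optimum) and `softmax`
#'   (the softmax fit at the optimum).
#' @export
grid_search_alpha <- function(trials, model = c("RL_1", "RL_2", "PE-M"),
                              step = 0.01) {
  model <- match.arg(model)
  trials <- analysis_trials(trials)
  grid_a <- seq(0.01, 0.99, by = step)

  score_one <- function(sub, make_params) {
    best <- NULL
    for (a in grid_a) {
      pr <- rl_predict(sub, make_params(a))
      fit <- fit_softmax(pr$p, sub$s)
      ps <- softmax_choice(pr$p, fit)
      sse <- mean((sub$s - ps)^2)
      if (is.null(best) || sse < best$sse - 1e-15) {
        best <- list(alpha = a, sse = sse, fit = fit)
      }
    }
    best
  }

  if (model == "RL_2") {
    conds <- intersect(c("easy", "hard"), unique(trials$condition))
    if (length(conds) == 0) stop("no trials for RL_2", call. = FALSE)
    found <- lapply(conds, function(cond) {
      sub <- trials[trials$condition == cond, , drop = FALSE]
      score_one(sub, function(a) rl_params("RL_2", stats::setNames(a, cond)))
    })
    alpha <- stats::setNames(vapply(found, `[[`, numeric(1), "alpha"), conds)
    out <- rl_params("RL_2", alpha)
    attr(out, "sigma_e2") <- stats::setNames(vapply(found, `[[`, numeric(1), "sse"), conds)
    attr(out, "softmax") <- stats::setNames(lapply(found, `[[`, "fit"), conds)
  } else {
    found <- score_one(trials, function(a) rl_params(model, a))
    out <- rl_params(model, found$alpha)
    attr(out, "sigma_e2") <- found$sse
    attr(out, "softmax") <- found$fit
  }
  out
}
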