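#' Discretization grid for the flexible learning filter
#'
#' The flexible learning model tracks a joint probability mass over three
#' latent quantities: `k`, the probability that the learning rate stays at its
#' current value from one trial to the next; `alpha`, the trial-varying
#' learning rate; and `p`, the belief that the red option is the more
#' rewarding one. All three live in the open unit interval and are
#' discretized on evenly spaced bin centers `(j - 0.5) / m`, `j = 1..m`,
#' which keeps every grid point strictly interior (required for the Beta
#' propagation kernel to have positive shape parameters).
#'
#' @param m_k,m_alpha,m_p number of bins per axis (at least 2).
#' @param k_values,alpha_values,p_values optional explicit bin centers,
#'   overriding the corresponding `m_*`; must be strictly inside (0, 1) and
#'   sorted ascending.
#'
#' @return An object of class `flex_grid`: a list with numeric vectors
#'   `k`, `alpha`, `p`.
#' @export
#' @examples
#' g <- make_grid(10, 10, 10)
#' length(g$alpha)
make_grid <- function(m_k = 30, m_alpha = 30, m_p = 30,
                      k_values = NULL, alpha_values = NULL, p_values = NULL) {
  centers <- function(m) (seq_len(m) - 0.5) / m
  axis <- function(values, m, name) {
    v <- if (is.null(values)) centers(m) else as.numeric(values)
    if (length(v) < 2) stop(name, " axis needs at least 2 points", call. = FALSE)
    if (any(v <= 0) || any(v >= 1)) {
      stop(name, " values must lie strictly inside (0, 1)", call. = FALSE)
    }
    if (is.unsorted(v, strictly = TRUE)) {
      stop(name, " values must be sorted strictly ascending", call. = FALSE)
    }
    v
  }
  structure(
    list(
      k = axis(k_values, m_k, "k"),
      alpha = axis(alpha_values, m_alpha, "alpha"),
      p = axis(p_values, m_p, "p")
    ),
    class = "flex_grid"
  )
}

#' @export
print.flex_grid <- function(x, ...) {
  cat("<flex_grid> ", length(x$k), " x ", length(x$alpha), " x ", length(x$p),
      " (k x alpha x p)\n", sep = "")
  invisible(x)
}

# Normalization tolerance used by posterior validity checks.
.norm_tol <- 1e-10

.new_posterior <- function(grid, mass) {
  structure(list(grid = grid, mass = mass), class = "latent_posterior")
}

.check_posterior <- function(posterior) {
  if (!inherits(posterior, "latent_posterior")) {
    stop("expected a 'latent_posterior' object", call. = FALSE)
  }
  if (any(posterior$mass < 0)) stop("posterior mass has negative entries", call. = FALSE)
  if (abs(sum(posterior$mass) - 1) > .norm_tol) {
    stop("posterior mass does not sum to 1", call. = FALSE)
  }
  invisible(posterior)
}

.renorm <- function(mass) {
  z <- sum(mass)
  if (z <= 0) stop("degenerate posterior: total mass is zero", call. = FALSE)
  mass / z
}

#' Initialize the latent posterior as a uniform distribution
#'
#' The joint mass over (k, alpha, p) is re-initialized uniform at the start
#' of every run, reflecting that participants were told the more rewarding
#' color resets between runs.
#'
#' @param grid a [make_grid()] object.
#' @return A `latent_posterior`: list with elements `grid` and `mass`
#'   (3-d array indexed k x alpha x p summing to 1).
#' @export
init_posterior <- function(grid) {
  if (!inherits(grid, "flex_grid")) stop("grid must be a 'flex_grid'", call. = FALSE)
  d <- c(length(grid$k), length(grid$alpha), length(grid$p))
  .new_posterior(grid, array(1 / prod(d), dim = d))
}

#' @export
print.latent_posterior <- function(x, ...) {
  d <- dim(x$mass)
  cat("<latent_posterior> ", d[1], " x ", d[2], " x ", d[3],
      " (k x alpha x p), total mass ", format(sum(x$mass)), "\n", sep = "")
  cat("  E[alpha] = ", round(posterior_mean(x, "alpha"), 4),
      ", E[p] = ", round(posterior_mean(x, "p"), 4), "\n", sep = "")
  invisible(x)
}

#' Marginal distribution and posterior mean of one latent variable
#'
#' @param posterior a `latent_posterior`.
#' @param which one of `"k"`, `"alpha"`, `"p"`.
#' @return `posterior_marginal()`: a numeric vector of marginal masses named
#'   by grid value; `posterior_mean()`: a scalar expectation.
#' @export
posterior_marginal <- function(posterior, which = c("k", "alpha", "p")) {
  which <- match.arg(which)
  dim_i <- match(which, c("k", "alpha", "p"))
  m <- apply(posterior$mass, dim_i, sum)
  names(m) <- posterior$grid[[which]]
  m
}

#' @rdname posterior_marginal
#' @export
posterior_mean <- function(posterior, which = c("k", "alpha", "p")) {
  which <- match.arg(which)
  sum(posterior_marginal(posterior, which) * posterior$grid[[which]])
}

# ---- transition kernels -----------------------------------------------------

# Learning-rate transition: with probability k the learning rate keeps its
# value; with probability 1 - k it jumps to a value drawn uniformly over the
# alpha grid (the uniform draw includes the current bin). On the discrete
# grid this is the mixture  new[a] = k * old[a] + (1 - k) * mean_a(old).
.step_transition_alpha <- function(mass, grid) {
  kv <- grid$k
  m_a <- length(grid$alpha)
  # mean over the alpha axis, kept as an array broadcastable back
  avg <- apply(mass, c(1, 3), mean)                  # m_k x m_p
  out <- mass * rep(kv, times = length(mass) / length(kv))
  add <- sweep(array(rep(avg, times = m_a), dim = c(dim(mass)[1], dim(mass)[3], m_a)),
               1, 1 - kv, `*`)
  out <- out + aperm(add, c(1, 3, 2))
  .renorm(out)
}

# Beta propagation kernels, one m_p x m_p row-stochastic matrix per alpha
# value: row i is the Beta(p_i * v + 1, v - p_i * v + 1) density with
# v = 1/alpha - 2, evaluated at the p bin centers and normalized. At
# alpha = 0.5, v = 0 and every row is uniform.
.p_kernels <- function(grid) {
  p <- grid$p
  lapply(grid$alpha, function(a) {
    v <- 1 / a - 2
    shape1 <- p * v + 1
    shape2 <- v - p * v + 1
    if (any(shape1 <= 0) || any(shape2 <= 0)) {
      stop("Beta propagation kernel has non-positive shape; grid must be interior",
           call. = FALSE)
    }
    K <- t(vapply(seq_along(p),
                  function(i) stats::dbeta(p, shape1[i], shape2[i]),
                  numeric(length(p))))
    K / rowSums(K)
  })
}

.step_propagate_p <- function(mass, grid, kernels) {
  for (a in seq_along(grid$alpha)) {
    mass[, a, ] <- mass[, a, , drop = TRUE] %*% kernels[[a]]
  }
  .renorm(mass)
}

# Deterministic shift-and-rebin matrices for the reinforcement-learning
# drift p -> p + alpha * (o - p), one m_p x m_p matrix per (alpha, o).
# Each source bin's mass is split linearly between the two bins flanking
# its shifted position; positions beyond the grid go to the end bin.
.drift_matrix <- function(alpha, o, p) {
  m <- length(p)
  target <- p + alpha * (o - p)
  R <- matrix(0, m, m)
  for (i in seq_len(m)) {
    t_i <- target[i]
    if (t_i <= p[1]) {
      R[i, 1] <- 1
    } else if (t_i >= p[m]) {
      R[i, m] <- 1
    } else {
      j <- findInterval(t_i, p)
      w <- (t_i - p[j]) / (p[j + 1] - p[j])
      R[i, j] <- 1 - w
      R[i, j + 1] <- w
    }
  }
  R
}

.drift_kernels <- function(grid) {
  list(
    o0 = lapply(grid$alpha, .drift_matrix, o = 0, p = grid$p),
    o1 = lapply(grid$alpha, .drift_matrix, o = 1, p = grid$p)
  )
}

.step_rl_drift <- function(mass, grid, drift, o_prev) {
  Rs <- if (o_prev == 1) drift$o1 else drift$o0
  for (a in seq_along(grid$alpha)) {
    mass[, a, ] <- mass[, a, , drop = TRUE] %*% Rs[[a]]
  }
  .renorm(mass)
}

.step_bayes <- function(mass, grid, s, o, params, sp_identity) {
  p <- grid$p
  sp <- if (sp_identity) p else softmax_choice(p, params)
  lik <- obs_likelihood(s, o, p, sp)
  mass <- sweep(mass, 3, lik, `*`)
  if (sum(mass) <= 0) {
    stop("Bayes update annihilated all posterior mass", call. = FALSE)
  }
  .renorm(mass)
}

# ---- exported single-step operations ---------------------------------------

#' One step of the learning-rate transition kernel
#'
#' Applies, within each k slice, the sticky/jump mixture: the learning rate
#' keeps its value with probability k and otherwise resamples uniformly over
#' the alpha grid.
#'
#' @param posterior a normalized `latent_posterior`.
#' @return The updated, renormalized `latent_posterior`.
#' @export
transition_alpha <- function(posterior) {
  .check_posterior(posterior)
  .new_posterior(posterior$grid, .step_transition_alpha(posterior$mass, posterior$grid))
}

#' Beta-kernel propagation (smoothing) of the reward belief
#'
#' For each (k, alpha) slice the conditional mass over p is pushed through a
#' Beta kernel with concentration `v = 1/alpha - 2`: each source value p is
#' smeared as Beta(p v + 1, v - p v + 1) over the p grid. Small learning
#' rates give large v (little smoothing: beliefs persist); alpha = 0.5 gives
#' v = 0, a uniform kernel that forgets the belief entirely. Mass within
#' each slice is conserved.
#'
#' @inheritParams transition_alpha
#' @return The updated `latent_posterior`.
#' @export
propagate_p <- function(posterior) {
  .check_posterior(posterior)
  kernels <- .p_kernels(posterior$grid)
  .new_posterior(posterior$grid,
                 .step_propagate_p(posterior$mass, posterior$grid, kernels))
}

#' Reinforcement-learning drift of the reward belief
#'
#' Shifts each grid point's p coordinate to `p + alpha * (o_prev - p)` —
#' the delta-rule update driven by the previous trial's outcome code — and
#' re-bins the mass onto the p grid by linear interpolation between the two
#' flanking bins. Mass is conserved.
#'
#' @inheritParams transition_alpha
#' @param o_prev outcome code (0 or 1) of the previous trial.
#' @return The updated `latent_posterior`.
#' @export
rl_drift <- function(posterior, o_prev) {
  .check_posterior(posterior)
  stopifnot(o_prev %in% c(0, 1))
  drift <- .drift_kernels(posterior$grid)
  .new_posterior(posterior$grid,
                 .step_rl_drift(posterior$mass, posterior$grid, drift, o_prev))
}

#' Outcome code of a choice/reward pair
#'
#' The outcome `o` is 1 when the observation supports "red is the more
#' rewarding color": the chosen color was red and the reward high, or the
#' chosen color was green and the reward low. Otherwise 0. On the 0/1
#' coding (red = 1, high = 1) this is simply `o = 1` iff `s == r`.
#'
#' @param s choice code: 0 = green, 1 = red (vectorized).
#' @param r reward code: 0 = low (1 point), 1 = high (5 points).
#' @return Integer vector of outcome codes.
#' @export
#' @examples
#' outcome_code(c(1, 0, 1, 0), c(1, 0, 0, 1))
outcome_code <- function(s, r) {
  stopifnot(all(s %in% c(0, 1)), all(r %in% c(0, 1)))
  as.integer(s == r)
}

#' Observation likelihood of a choice and outcome
#'
#' `p(s, o | p) = (1 - |o - p|) (1 - |s - sp|)`: the product of the outcome
#' likelihood under the reward belief p and the choice likelihood under the
#' softmax-predicted choice probability sp.
#'
#' @param s,o observed choice and outcome codes (0/1).
#' @param p candidate reward-belief value(s) in (0, 1).
#' @param sp predicted probability of choosing red for those p values.
#' @return Numeric likelihood value(s).
#' @export
#' @examples
#' obs_likelihood(1, 1, 0.7, 0.6)  # 0.7 * 0.6
obs_likelihood <- function(s, o, p, sp) {
  (1 - abs(o - p)) * (1 - abs(s - sp))
}

#' Bayesian observation update of the latent posterior
#'
#' Multiplies the joint mass cellwise by the observation likelihood of the
#' trial's choice and outcome (which depends only on each cell's p value)
#' and renormalizes. The choice-prediction term sp is computed from the
#' candidate p value through the softmax; on the first EM iteration, before
#' any softmax parameters exist, `sp_identity = TRUE` uses sp = p.
#'
#' @inheritParams transition_alpha
#' @param s,o observed choice and outcome codes (0/1).
#' @param params a [softmax_params()] object (ignored if `sp_identity`).
#' @param sp_identity logical; use sp = p instead of the softmax.
#' @return The updated `latent_posterior`.
#' @export
bayes_update <- function(posterior, s, o, params = NULL, sp_identity = FALSE) {
  .check_posterior(posterior)
  stopifnot(s %in% c(0, 1), o %in% c(0, 1))
  if (!sp_identity && is.null(params)) {
    stop("softmax params required unless sp_identity = TRUE", call. = FALSE)
  }
  .new_posterior(posterior$grid,
                 .step_bayes(posterior$mass, posterior$grid, s, o, params, sp_identity))
}

#' Signed reward prediction error
#'
#' `pe = r - p` if red was chosen, `pe = r - (1 - p)` if green was chosen,
#' i.e. reward minus the predicted reward probability of the chosen color.
#'
#' @param s choice code (0/1), vectorized.
#' @param r reward code (0/1).
#' @param p_mean belief that red is the more rewarding color.
#' @return Numeric prediction error(s) in \[-1, 1\].
#' @export
#' @examples
#' prediction_error(1, 1, 0.8)  # 0.2
#' prediction_error(0, 1, 0.8)  # 0.8
prediction_error <- function(s, r, p_mean) {
  ifelse(s == 1, r - p_mean, r - (1 - p_mean))
}

# ---- trial-by-trial filtering ----------------------------------------------

#' Run the flexible learning filter over one run of trials
#'
#' At each trial the filter (a) applies the learning-rate transition, the
#' Beta propagation and the reinforcement-learning drift driven by the
#' previous trial's outcome — all three skipped on the first trial, where
#' the freshly initialized uniform prior is used as-is; (b) records the
#' posterior means E\[alpha\], E\[p\], the softmax choice prediction ps and,
#' once the choice and reward are observed, the outcome code and signed
#' prediction error; and (c) folds the observation into the posterior via
#' the Bayes update. The posterior starts uniform at the beginning of the
#' run.
#'
#' @param trials data frame of one run's responded trials, in order, with
#'   columns `s` and `r` (0/1 codes).
#' @param params a [softmax_params()] object (may be `NULL` when
#'   `sp_identity = TRUE`; then `ps` is reported as `p_mean`).
#' @param grid a [make_grid()] object.
#' @param sp_identity logical; first-EM-iteration mode with sp = p.
#' @return A tibble with one row per trial: `trial`, `alpha_mean`, `p_mean`,
#'   `ps`, `o`, `pe`.
#' @export
filter_run <- function(trials, params = NULL, grid = make_grid(),
                       sp_identity = FALSE) {
  n <- nrow(trials)
  if (is.null(n) || n == 0) stop("empty run", call. = FALSE)
  s <- trials$s
  r <- trials$r
  stopifnot(all(s %in% c(0, 1)), all(r %in% c(0, 1)))
  if (!sp_identity && is.null(params)) {
    stop("softmax params required unless sp_identity = TRUE", call. = FALSE)
  }

  kernels <- .p_kernels(grid)
  drift <- .drift_kernels(grid)
  mass <- init_posterior(grid)$mass
  a_ax <- match("alpha", c("k", "alpha", "p"))
  p_ax <- match("p", c("k", "alpha", "p"))

  alpha_mean <- p_mean <- ps <- pe <- numeric(n)
  o <- integer(n)
  for (i in seq_len(n)) {
    if (i > 1) {
      mass <- .step_transition_alpha(mass, grid)
      mass <- .step_propagate_p(mass, grid, kernels)
      mass <- .step_rl_drift(mass, grid, drift, o[i - 1])
    }
    alpha_mean[i] <- sum(apply(mass, a_ax, sum) * grid$alpha)
    p_mean[i] <- sum(apply(mass, p_ax, sum) * grid$p)
    ps[i] <- if (sp_identity && is.null(params)) p_mean[i] else softmax_choice(p_mean[i], params)
    o[i] <- outcome_code(s[i], r[i])
    pe[i] <- prediction_error(s[i], r[i], p_mean[i])
    mass <- .step_bayes(mass, grid, s[i], o[i], params, sp_identity)
  }
  tibble::tibble(
    trial = if ("trial" %in% names(trials)) trials$trial else seq_len(n),
    alpha_mean = alpha_mean, p_mean = p_mean, ps = ps, o = o, pe = pe
  )
}

#' Run the flexible learning filter over a whole session
#'
#' Applies [filter_run()] run by run (the posterior is re-initialized
#' uniform at each run start), dropping non-responded trials, and returns
#' the stacked trace.
#'
#' @param trials a session trial table (see [make_session()]), possibly for
#'   several runs; must contain `run`, `trial`, `s`, `r` and (optionally)
#'   `responded`.
#' @inheritParams filter_run
#' @return A tibble with columns `run`, `trial`, `alpha_mean`, `p_mean`,
#'   `ps`, `o`, `pe`.
#' @export
filter_session <- function(trials, params = NULL, grid = make_grid(),
                           sp_identity = FALSE) {
  trials <- analysis_trials(trials)
  runs <- split(trials, trials$run)
  out <- lapply(runs, function(tr) {
    tb <- filter_run(tr, params = params, grid = grid, sp_identity = sp_identity)
    tb$run <- tr$run[1]
    tb
  })
  dplyr::bind_rows(out)[, c("run", "trial", "alpha_mean", "p_mean", "ps", "o", "pe")]
}
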