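#' Softmax (logistic) choice model
#'
#' Maps a reward belief p to the predicted probability of choosing red:
#' `ps = 1 / (1 + exp(-(beta1 + beta2 * p)))`. `beta2 > 0` means higher
#' belief that red is more rewarding translates into a higher probability
#' of choosing red.
#'
#' @param beta1 intercept (real).
#' @param beta2 slope (real).
#' @return A `softmax_params` list.
#' @export
softmax_params <- function(beta1, beta2) {
  if (!is.finite(beta1) || !is.finite(beta2)) {
    stop("softmax parameters must be finite", call. = FALSE)
  }
  structure(list(beta1 = beta1, beta2 = beta2), class = "softmax_params")
}

#' @rdname softmax_params
#' @param p reward belief(s) in (0, 1).
#' @param params a `softmax_params` object.
#' @export
#' @examples
#' softmax_choice(0.5, softmax_params(0, 2))  # plogis(1)
softmax_choice <- function(p, params) {
  stopifnot(inherits(params, "softmax_params"))
  stats::plogis(params$beta1 + params$beta2 * p)
}

#' Fit the softmax choice model to observed choices
#'
#' Maximum-likelihood logistic regression of the binary choices on the
#' belief sequence (Bernoulli likelihood; deterministic IRLS from a fixed
#' (0, 0) start), i.e. the M step of the EM procedure. Degenerate designs
#' are handled explicitly: a constant belief sequence leaves the slope
#' unidentifiable (returned as 0 with `degenerate = TRUE`), and perfectly
#' separated data are returned with coefficients capped at |beta| = 50 and
#' a warning.
#'
#' @param p belief sequence in (0, 1).
#' @param choices binary choice vector aligned with `p`.
#' @param objective `"likelihood"` (default) or `"ls"` (least squares on
#'   the choice indicator, matching the squared-error criterion used in
#'   model comparison).
#' @return A [softmax_params()] with attributes `degenerate` and
#'   `converged`.
#' @export
fit_softmax <- function(p, choices, objective = c("likelihood", "ls")) {
  objective <- match.arg(objective)
  stopifnot(length(p) == length(choices), all(choices %in% c(0, 1)))
  degenerate <- stats::sd(p) < 1e-12
  if (degenerate) {
    b1 <- stats::qlogis(max(min(mean(choices), 1 - 1e-8), 1e-8))
    out <- softmax_params(min(max(b1, -50), 50), 0)
    attr(out, "degenerate") <- TRUE
    attr(out, "converged") <- TRUE
    warning("constant belief sequence: slope unidentifiable", call. = FALSE)
    return(out)
  }
  cap <- 50
  if (objective == "likelihood") {
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(1, p), choices, family = stats::binomial(),
                     start = c(0, 0)),
      warning = function(w) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    beta <- fit$coefficients
    converged <- fit$converged && !separated
  } else {
    obj <- function(b) mean((choices - stats::plogis(b[1] + b[2] * p))^2)
    opt <- stats::optim(c(0, 0), obj, method = "BFGS")
    beta <- opt$par
    converged <- opt$convergence == 0
  }
  if (any(abs(beta) > cap)) {
    beta <- pmin(pmax(beta, -cap), cap)
    warning("softmax coefficients capped at |beta| = 50 (separation?)",
            call. = FALSE)
  }
  out <- softmax_params(beta[1], beta[2])
  attr(out, "degenerate") <- FALSE
  attr(out, "converged") <- converged
  out
}

#' EM estimation of the flexible learning model's softmax hyperparameters
#'
#' Alternates an E step — running the grid filter over the session to
#' produce trial-wise belief means — and an M step — refitting the softmax
#' of the observed choices on those means. The first E step runs before any
#' softmax parameters exist and uses the identity choice prediction
#' (sp = p) inside the observation likelihood; later E steps use the
#' current softmax iterate. Iteration stops when both coefficients move by
#' less than `tol` or after `max_iter` iterations (then flagged
#' unconverged).
#'
#' @param trials one participant's trial table (complete runs).
#' @param grid a [make_grid()] object.
#' @param tol convergence tolerance on max |delta beta| (default 1e-3).
#' @param max_iter iteration cap (default 50).
#' @param objective M-step objective passed to [fit_softmax()].
#' @return A list of class `em_fit`: `params` (final [softmax_params()]),
#'   `trace` (final [filter_session()] trace with `ps` from the final
#'   parameters), `loglik` (per-iteration Bernoulli log-likelihood),
#'   `iterations`, `converged`.
#' @export
em_fit <- function(trials, grid = make_grid(), tol = 1e-3, max_iter = 50,
                   objective = "likelihood") {
  trials <- analysis_trials(trials)
  s <- trials$s
  params <- NULL
  loglik <- numeric(0)
  converged <- FALSE
  trace <- NULL
  for (it in seq_len(max_iter)) {
    trace <- filter_session(trials, params = params, grid = grid,
                            sp_identity = is.null(params))
    new_params <- fit_softmax(trace$p_mean, s, objective = objective)
    ps <- softmax_choice(trace$p_mean, new_params)
    ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
    loglik <- c(loglik, sum(s * log(ps) + (1 - s) * log(1 - ps)))
    if (!is.null(params) &&
        max(abs(c(new_params$beta1 - params$beta1,
                  new_params$beta2 - params$beta2))) < tol) {
      params <- new_params
      converged <- TRUE
      break
    }
    params <- new_params
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter, " iterations",
            call. = FALSE)
  }
  trace$ps <- softmax_choice(trace$p_mean, params)
  structure(list(params = params, trace = trace, loglik = loglik,
                 iterations = length(loglik), converged = converged),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat("<em_fit> beta1 = ", round(x$params$beta1, 3),
      ", beta2 = ", round(x$params$beta2, 3),
      " (", x$iterations, " iterations, ",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

# Seeded split of run indices into two folds of equal size.
.two_folds <- function(runs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- sort(sample(runs, length(runs) / 2))
  list(a, setdiff(runs, a))
}

#' Two-fold cross-validated BIC of a learning model
#'
#' Splits the 8 runs into two folds — for the flexible, RL_1 and PE-M
#' models each fold holds two easy and two hard runs; for RL_2 the two
#' difficulty conditions are cross-validated separately so each fold holds
#' two runs of the same difficulty. Free parameters (softmax coefficients,
#' plus the learning rate(s) for the baselines) are estimated on the
#' training fold, applied to the held-out fold to produce trial-wise choice
#' predictions, and the squared prediction errors are pooled over both
#' swaps: `sigma_e2 = mean((s - ps)^2)` over all held-out trials, and
#' `BIC = n * ln(sigma_e2)` with no free-parameter penalty.
#'
#' @param trials one participant's 8-run trial table.
#' @param model `"flexible"`, `"RL_1"`, `"RL_2"` or `"PE-M"`.
#' @param grid filter grid (flexible model only).
#' @param seed seed for the fold assignment (runs are paired at random
#'   within the difficulty constraints).
#' @param ... further arguments passed to [em_fit()] for the flexible
#'   model.
#' @return A tibble row: `model`, `sigma_e2`, `bic`, `n`.
#' @export
crossval_bic <- function(trials, model = c("flexible", "RL_1", "RL_2", "PE-M"),
                         grid = make_grid(), seed = NULL, ...) {
  model <- match.arg(model)
  trials <- analysis_trials(trials)
  run_cond <- unique(trials[, c("run", "condition")])
  if (nrow(run_cond) < 8) stop("cross-validation needs 8 runs", call. = FALSE)
  easy_runs <- run_cond$run[run_cond$condition == "easy"]
  hard_runs <- run_cond$run[run_cond$condition == "hard"]
  if (!is.null(seed)) set.seed(seed)

  take <- function(runs) trials[trials$run %in% runs, , drop = FALSE]
  preds <- NULL
  obs <- NULL

  predict_fold <- function(train, test) {
    if (model == "flexible") {
      fit <- em_fit(train, grid = grid, ...)
      trace <- filter_session(test, params = fit$params, grid = grid)
      trace$ps
    } else {
      sm <- if (model == "RL_2") "RL_2" else model
      pars <- grid_search_alpha(train, model = sm)
      fit <- attr(pars, "softmax")
      pr <- rl_predict(test, pars)
      if (model == "RL_2") {
        cond <- test$condition[1]
        softmax_choice(pr$p, fit[[cond]])
      } else {
        softmax_choice(pr$p, fit)
      }
    }
  }

  if (model == "RL_2") {
    # folds within each difficulty condition
    for (cond_runs in list(easy_runs, hard_runs)) {
      folds <- .two_folds(cond_runs)
      for (sw in 1:2) {
        train <- take(folds[[sw]]); test <- take(folds[[3 - sw]])
        preds <- c(preds, predict_fold(train, test))
        obs <- c(obs, test$s)
      }
    }
  } else {
    fe <- .two_folds(easy_runs)
    fh <- .two_folds(hard_runs)
    folds <- list(c(fe[[1]], fh[[1]]), c(fe[[2]], fh[[2]]))
    for (sw in 1:2) {
      train <- take(folds[[sw]]); test <- take(folds[[3 - sw]])
      preds <- c(preds, predict_fold(train, test))
      obs <- c(obs, test$s)
    }
  }
  sigma_e2 <- mean((obs - preds)^2)
  n <- length(obs)
  tibble::tibble(model = model, sigma_e2 = sigma_e2,
                 bic = n * log(sigma_e2), n = n)
}

#' Cross-validated model comparison over all four learners
#'
#' Convenience wrapper running [crossval_bic()] for the flexible model and
#' the three baselines on one participant's data.
#'
#' @inheritParams crossval_bic
#' @return A four-row tibble sorted by BIC (best first).
#' @export
compare_models <- function(trials, grid = make_grid(), seed = NULL, ...) {
  out <- lapply(c("flexible", "RL_1", "RL_2", "PE-M"), function(m) {
    crossval_bic(trials, model = m, grid = grid, seed = seed, ...)
  })
  out <- dplyr::bind_rows(out)
  out[order(out$bic), ]
}
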