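# Model-based fMRI design machinery, exercised on synthetic BOLD: the three
# onset-locked regressor groups, within-group orthogonalization at the trial
# level, canonical HRF convolution at TR = 2 s, nuisance columns, per-voxel
# OLS and group t-tests. "Voxels" are independent columns; there is no
# spatial model.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak parameter 6 s,
#' undershoot 16 s, peak-to-undershoot ratio 6, unit dispersions) — the
#' standard canonical parameterization.
#'
#' @param t time(s) in seconds since the event.
#' @param peak,undershoot,ratio gamma shape parameters and amplitude ratio.
#' @return HRF value(s); zero for `t < 0`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  ifelse(t < 0, 0,
         stats::dgamma(t, shape = peak, rate = 1) -
           stats::dgamma(t, shape = undershoot, rate = 1) / ratio)
}

#' Convolve event amplitudes with the canonical HRF
#'
#' Places zero-duration stick events of the given amplitudes at the onset
#' times on a fine time grid (`dt`), convolves with the canonical HRF
#' (normalized to unit sum over a 32 s support) and resamples at the volume
#' acquisition times `0, TR, 2 TR, ...`.
#'
#' @param values per-event amplitudes (1 for a stick regressor).
#' @param onsets event onset times in seconds within the run.
#' @param TR repetition time in seconds (default 2).
#' @param n_volumes number of volumes in the run.
#' @param dt microtime resolution in seconds.
#' @return Numeric column of length `n_volumes`.
#' @export
convolve_hrf <- function(values, onsets, TR = 2, n_volumes, dt = 0.1) {
  stopifnot(length(values) == length(onsets))
  run_len <- n_volumes * TR
  if (any(onsets < 0) || any(onsets >= run_len)) {
    stop("onsets beyond run length", call. = FALSE)
  }
  n_hi <- ceiling(run_len / dt)
  stick <- numeric(n_hi)
  pos <- pmin(floor(onsets / dt) + 1L, n_hi)
  for (i in seq_along(pos)) stick[pos[i]] <- stick[pos[i]] + values[i]
  h <- canonical_hrf(seq(0, 32, by = dt))
  h <- h / sum(h)
  conv <- stats::convolve(stick, rev(h), type = "open")[seq_len(n_hi)]
  conv[pmin(floor((seq_len(n_volumes) - 1) * TR / dt) + 1L, n_hi)]
}

.group_defs <- function() {
  list(
    cue = list(onset_col = "onset_cue",
               parametric = c("alpha", "p_chosen")),
    feedback = list(onset_col = "onset_feedback",
                    parametric = c("r", "pe", "alpha_pe", "alpha_r")),
    response = list(onset_col = "onset_response",
                    parametric = "side")
  )
}

#' Build the three onset-locked regressor groups
#'
#' Cue group (square onset): stick; the learning rate `alpha`; the
#' predicted reward probability of the (later) chosen color (`p` when red
#' was chosen, `1 - p` when green). Feedback group: stick; the reward `r`;
#' the signed prediction error `pe`; the learning update `alpha x pe`; the
#' `alpha x r` interaction. Response group: stick and response side (the
#' chosen color's side, red = +1 / green = -1). Interaction columns are
#' elementwise products of the raw (pre-normalization) series. All
#' parametric regressors are z-scored (`normalize = "session"` pools the
#' concatenated runs; `"run"` normalizes per run); a constant series
#' normalizes to an all-zero column with a warning.
#'
#' @param trace model trace aligned with `trials` (`run`, `trial`,
#'   `alpha_mean`, `p_mean`, `pe`).
#' @param trials one participant's responded trials with onset columns.
#' @param normalize `"session"` or `"run"`.
#' @return A named list of three `regressor_group`s, each holding `run`,
#'   `onset` and the named per-trial value series.
#' @export
build_groups <- function(trace, trials, normalize = c("session", "run")) {
  normalize <- match.arg(normalize)
  trials <- analysis_trials(trials)
  d <- dplyr::inner_join(
    trials[, c("run", "trial", "s", "r",
               "onset_cue", "onset_feedback", "onset_response")],
    trace[, c("run", "trial", "alpha_mean", "p_mean", "pe")],
    by = c("run", "trial")
  )
  if (nrow(d) != nrow(trials)) stop("trace does not align with trials", call. = FALSE)
  if (anyNA(d$onset_cue) || anyNA(d$onset_feedback) || anyNA(d$onset_response)) {
    stop("missing onsets", call. = FALSE)
  }
  raw <- list(
    alpha = d$alpha_mean,
    p_chosen = ifelse(d$s == 1, d$p_mean, 1 - d$p_mean),
    r = as.numeric(d$r),
    pe = d$pe,
    alpha_pe = d$alpha_mean * d$pe,
    alpha_r = d$alpha_mean * d$r,
    side = 2 * as.numeric(d$s) - 1
  )
  norm <- function(x) {
    zs <- function(v) {
      if (stats::sd(v) < 1e-12) {
        warning("constant parametric regressor normalized to zeros", call. = FALSE)
        return(rep(0, length(v)))
      }
      (v - mean(v)) / stats::sd(v)
    }
    if (normalize == "session") zs(x)
    else unsplit(lapply(split(x, d$run), zs), d$run)
  }
  defs <- .group_defs()
  out <- lapply(names(defs), function(g) {
    regs <- c(list(stick = rep(1, nrow(d))),
              lapply(raw[defs[[g]]$parametric], norm))
    structure(list(onset_type = g, run = d$run,
                   onset = d[[defs[[g]]$onset_col]],
                   regressors = regs),
              class = "regressor_group")
  })
  stats::setNames(out, names(defs))
}

#' Orthogonalize one regressor within its group
#'
#' Replaces the target series by the residual of its least-squares
#' projection onto the other members of the same group (at the trial
#' level, before HRF convolution), so GLM results can be uniquely
#' attributed to the target. The residual is numerically orthogonal to
#' every other member. If the others span the target exactly the residual
#' is the zero vector and the group is flagged.
#'
#' @param group a `regressor_group` from [build_groups()].
#' @param target name of the member to orthogonalize.
#' @return The group with the target replaced; attribute `flagged` is
#'   `TRUE` when the residual collapsed to zero.
#' @export
orthogonalize_within_group <- function(group, target) {
  stopifnot(inherits(group, "regressor_group"))
  if (!target %in% names(group$regressors)) {
    stop("target is not a member of the group", call. = FALSE)
  }
  others <- setdiff(names(group$regressors), target)
  y <- group$regressors[[target]]
  X <- do.call(cbind, group$regressors[others])
  beta <- .ols_pinv(X, y)
  resid <- y - drop(X %*% beta)
  flagged <- sqrt(sum(resid^2)) < 1e-10 * max(1, sqrt(sum(y^2)))
  if (flagged) {
    warning("target is collinear with the rest of its group; residual is zero",
            call. = FALSE)
    resid <- rep(0, length(y))
  }
  group$regressors[[target]] <- resid
  attr(group, "flagged") <- flagged
  group
}

#' Volumes needed to cover a run's events
#'
#' @param onsets all event onsets of the run (seconds).
#' @param TR repetition time.
#' @param pad post-event padding in seconds to let the HRF return to
#'   baseline.
#' @return Integer volume count.
#' @export
run_volumes <- function(onsets, TR = 2, pad = 30) {
  as.integer(ceiling((max(onsets) + pad) / TR))
}

#' Assemble the session design matrix
#'
#' Convolves every group regressor with the canonical HRF run by run,
#' concatenates runs, mean-centers the task columns, and appends six
#' motion nuisance columns (supplied, or generated as a seeded
#' random walk) and one grand-mean indicator column per run. Full column
#' rank is verified.
#'
#' @param groups list of `regressor_group`s (see [build_groups()], possibly
#'   after [orthogonalize_within_group()]).
#' @param TR repetition time in seconds.
#' @param n_volumes optional named-by-run integer vector; defaults to
#'   [run_volumes()] per run.
#' @param motion optional matrix (total volumes x 6); generated if `NULL`.
#' @param seed seed for generated motion parameters.
#' @return A `design_matrix` list: `X` (volumes x columns, with column
#'   names), `task_cols`, `n_volumes` (per run), `TR`.
#' @export
build_design_matrix <- function(groups, TR = 2, n_volumes = NULL,
                                motion = NULL, seed = NULL) {
  runs <- sort(unique(unlist(lapply(groups, `[[`, "run"))))
  if (is.null(n_volumes)) {
    n_volumes <- vapply(runs, function(rr) {
      run_volumes(unlist(lapply(groups, function(g) g$onset[g$run == rr])), TR)
    }, integer(1))
    names(n_volumes) <- runs
  }
  prefix <- c(cue = "cue", feedback = "fb", response = "resp")
  task_cols <- list()
  for (g in groups) {
    for (nm in names(g$regressors)) {
      col_name <- paste0(prefix[[g$onset_type]], "_", nm)
      col <- unlist(lapply(seq_along(runs), function(ri) {
        rr <- runs[ri]
        sel <- g$run == rr
        convolve_hrf(g$regressors[[nm]][sel], g$onset[sel],
                     TR = TR, n_volumes = n_volumes[[ri]])
      }))
      task_cols[[col_name]] <- col - mean(col)
    }
  }
  X_task <- do.call(cbind, task_cols)

  total <- sum(n_volumes)
  if (is.null(motion)) {
    if (!is.null(seed)) set.seed(seed)
    motion <- apply(matrix(stats::rnorm(total * 6, sd = 0.02), total, 6), 2, cumsum)
  }
  stopifnot(nrow(motion) == total, ncol(motion) == 6)
  colnames(motion) <- paste0("motion_", 1:6)
  motion <- sweep(motion, 2, colMeans(motion))

  run_means <- matrix(0, total, length(runs))
  offs <- c(0, cumsum(n_volumes))
  for (ri in seq_along(runs)) {
    run_means[(offs[ri] + 1):offs[ri + 1], ri] <- 1
  }
  colnames(run_means) <- paste0("run_mean_", runs)

  X <- cbind(X_task, motion, run_means)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  structure(list(X = X, task_cols = names(task_cols),
                 n_volumes = n_volumes, TR = TR),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " volumes x ", ncol(x$X), " columns (",
      length(x$task_cols), " task), TR = ", x$TR, " s\n", sep = "")
  invisible(x)
}

#' Simulate voxel time series from a design
#'
#' Generates `bold = X w + noise` per voxel from planted encoding weights
#' on named design columns, with white or AR(1) Gaussian noise. With
#' `snr` given, each voxel's noise standard deviation is its planted
#' signal's standard deviation divided by `snr` (voxels with no planted
#' signal use the mean sd of the planted ones); alternatively pass `sigma`
#' directly. `sigma = 0` yields noiseless data.
#'
#' @param design a [build_design_matrix()] object.
#' @param weights voxels x columns matrix of encoding weights; column
#'   names must be design columns.
#' @param sigma noise standard deviation (scalar or per voxel).
#' @param snr signal-to-noise ratio, overriding `sigma` when non-`NULL`.
#' @param noise `"white"` or `"ar1"`.
#' @param ar AR(1) coefficient.
#' @param seed optional seed.
#' @return A `synthetic_bold` list: `bold` (volumes x voxels), `weights`,
#'   `sigma` (per voxel).
#' @export
simulate_bold <- function(design, weights, sigma = 0, snr = NULL,
                          noise = c("white", "ar1"), ar = 0.4, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(design, "design_matrix"))
  if (is.null(colnames(weights)) ||
      !all(colnames(weights) %in% colnames(design$X))) {
    stop("weight columns must name design columns", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  X <- design$X[, colnames(weights), drop = FALSE]
  signal <- X %*% t(weights)              # volumes x voxels
  n_vox <- nrow(weights)
  if (!is.null(snr)) {
    sd_sig <- apply(signal, 2, stats::sd)
    ref <- mean(sd_sig[sd_sig > 0])
    if (!is.finite(ref)) ref <- 0
    sigma <- ifelse(sd_sig > 0, sd_sig / snr, ref / snr)
  } else if (length(sigma) == 1) {
    sigma <- rep(sigma, n_vox)
  }
  n_t <- nrow(signal)
  eps <- matrix(stats::rnorm(n_t * n_vox), n_t, n_vox)
  if (noise == "ar1") {
    eps <- apply(eps, 2, function(e) {
      stats::filter(e, ar, method = "recursive") * sqrt(1 - ar^2)
    })
  }
  bold <- signal + sweep(eps, 2, sigma, `*`)
  structure(list(bold = bold, weights = weights, sigma = sigma),
            class = "synthetic_bold")
}

#' Per-voxel GLM coefficient of a regressor of interest
#'
#' Ordinary least squares of every voxel's time series on the full design;
#' returns the estimated coefficient of the named column — the voxel's
#' encoding strength of that (orthogonalized) regressor.
#'
#' @param bold volumes x voxels matrix, or a `synthetic_bold`.
#' @param design a [build_design_matrix()] object.
#' @param column design column of interest.
#' @return Numeric vector of per-voxel betas.
#' @export
fit_glm <- function(bold, design, column) {
  if (inherits(bold, "synthetic_bold")) bold <- bold$bold
  stopifnot(inherits(design, "design_matrix"))
  if (!column %in% colnames(design$X)) stop("unknown design column", call. = FALSE)
  qr_x <- qr(design$X)
  if (qr_x$rank < ncol(design$X)) stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qr_x, bold)
  beta[match(column, colnames(design$X)), ]
}

#' Group-level one-sample t-test across participants
#'
#' One-sample t statistic of the per-participant encoding strengths
#' against zero, per voxel. Voxels with zero variance across participants
#' are masked (`NA`).
#'
#' @param beta_maps participants x voxels matrix of betas.
#' @return A tibble: `voxel`, `mean`, `t`, `df`, `p_value`, `masked`.
#' @export
group_ttest <- function(beta_maps) {
  beta_maps <- as.matrix(beta_maps)
  n <- nrow(beta_maps)
  if (n < 3) stop("need at least 3 participant maps", call. = FALSE)
  m <- colMeans(beta_maps)
  s <- apply(beta_maps, 2, stats::sd)
  masked <- s < 1e-12
  t_stat <- ifelse(masked, NA_real_, m / (s / sqrt(n)))
  tibble::tibble(
    voxel = seq_along(m), mean = m, t = t_stat, df = n - 1,
    p_value = ifelse(masked, NA_real_, 2 * stats::pt(-abs(t_stat), n - 1)),
    masked = masked
  )
}
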